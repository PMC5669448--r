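#' Read a gene-set collection from a GMT file
#'
#' GMT is tab-separated: set id, description, then one gene per field.
#'
#' @param path GMT file path.
#' @return Tibble with columns `set_id`, `name`, `genes` (list-column).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    warning(sum(bad), " GMT line(s) with fewer than 3 fields dropped",
            call. = FALSE)
    parts <- parts[!bad]
  }
  if (length(parts) == 0L) stop("no gene sets in '", path, "'",
                                call. = FALSE)
  tibble::tibble(
    set_id = vapply(parts, `[`, character(1), 1L),
    name = vapply(parts, `[`, character(1), 2L),
    genes = lapply(parts, function(p) unique(p[-(1:2)])))
}

#' Genes behind one spot
#'
#' A spot's gene set is the union of the member genes of the sink nodes
#' whose sinks are assigned to the spot's units.
#'
#' @param spot_map A [detect_spots()] result.
#' @param label Spot label (e.g. `"A"`).
#' @param som The trained [train_som()] model carrying the sink-to-unit
#'   assignment.
#' @param pathways The pathway collection (list of [pathway_graph()]).
#' @return Character vector of gene ids (sorted, unique).
#' @export
spot_gene_set <- function(spot_map, label, som, pathways) {
  stopifnot(inherits(spot_map, "spot_map"), inherits(som, "psf_som"))
  units <- spot_map$spots$unit[spot_map$spots$label == label]
  sinks <- som$sinks[som$sinks$unit %in% units, ]
  if (nrow(sinks) == 0L) return(character(0))
  pids <- vapply(pathways, function(g) g$pathway_id, character(1))
  genes <- purrr::map2(sinks$pathway_id, sinks$sink, function(pid, node) {
    g <- pathways[[match(pid, pids)]]
    g$node_genes$gene[g$node_genes$node == node]
  })
  sort(unique(unlist(genes, use.names = FALSE)))
}

#' Hypergeometric overrepresentation p-value
#'
#' Probability of observing at least the seen overlap between a query
#' gene set and an annotated set, drawing `|query|` genes without
#' replacement from the universe (the upper tail of the hypergeometric
#' distribution; identical to a one-sided Fisher test).
#'
#' @param query,gene_set Character vectors of gene ids, both subsets of
#'   `universe`.
#' @param universe Character vector: the reference gene population.
#' @return Raw p-value in (0, 1].
#' @export
hypergeom_test <- function(query, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- intersect(unique(query), universe)
  gene_set <- intersect(unique(gene_set), universe)
  k <- length(intersect(query, gene_set))
  stats::phyper(k - 1, length(gene_set),
                length(universe) - length(gene_set),
                length(query), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at
#' 1), preserving the input order.
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Adjusted p-values in the same order.
#' @export
bh_adjust <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Overrepresentation analysis of a query gene set
#'
#' Tests the query against every set in the collection (after restricting
#' sets to the universe and discarding sets smaller than `min_set`),
#' adjusts with Benjamini-Hochberg and flags rows significant at
#' `adj_p < alpha`.
#'
#' @param query Character vector of gene ids.
#' @param collection A [read_gmt()] tibble (`set_id`, `name`, `genes`).
#' @param universe Reference population; defaults to the union of all
#'   collection genes and the query.
#' @param min_set Minimum set size after universe restriction.
#' @param alpha Significance level on the adjusted p-value.
#' @return Tibble sorted by adjusted p: `set_id`, `name`, `overlap`,
#'   `set_size`, `query_size`, `universe_size`, `p`, `adj_p`,
#'   `significant`.
#' @export
enrich <- function(query, collection, universe = NULL, min_set = 5,
                   alpha = 0.05) {
  collection <- tibble::as_tibble(collection)
  stopifnot(all(c("set_id", "name", "genes") %in% names(collection)))
  if (is.null(universe)) {
    universe <- unique(c(unlist(collection$genes, use.names = FALSE), query))
  }
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  sets <- lapply(collection$genes, intersect, y = universe)
  keep <- lengths(sets) >= min_set
  if (!any(keep)) {
    return(tibble::tibble(
      set_id = character(), name = character(), overlap = integer(),
      set_size = integer(), query_size = integer(),
      universe_size = integer(), p = numeric(), adj_p = numeric(),
      significant = logical()))
  }
  sets <- sets[keep]
  out <- tibble::tibble(
    set_id = collection$set_id[keep],
    name = collection$name[keep],
    overlap = vapply(sets, function(s) length(intersect(query, s)),
                     integer(1)),
    set_size = lengths(sets),
    query_size = length(query),
    universe_size = length(universe),
    p = vapply(sets, function(s) hypergeom_test(query, s, universe),
               numeric(1)))
  out$adj_p <- bh_adjust(out$p)
  out$significant <- out$adj_p < alpha
  dplyr::arrange(out, .data$adj_p, .data$p, .data$set_id)
}
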