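#' Assign fold-change values to pathway nodes
#'
#' Each node's value aggregates the linear fold changes of its member
#' genes that are present in the fold-change table; the default
#' aggregation is the geometric mean (FCs are ratios, and the geometric
#' mean treats a doubling and a halving symmetrically). Nodes with no
#' measured member genes — including gene-less relay/compound nodes —
#' receive the neutral value 1.
#'
#' @param graph A [pathway_graph()].
#' @param fc_df Fold-change tibble as returned by [fold_changes()].
#' @param sample Sample id (column of `fc_df`), or `NULL` for all samples.
#' @param gene_agg `"geometric"` (default) or `"arithmetic"` mean over a
#'   node's measured member genes.
#' @return Tibble with column `node` and one value column per requested
#'   sample; all values strictly positive.
#' @export
assign_node_values <- function(graph, fc_df, sample = NULL,
                               gene_agg = c("geometric", "arithmetic")) {
  gene_agg <- match.arg(gene_agg)
  fc_df <- tibble::as_tibble(fc_df)
  samples <- setdiff(names(fc_df), names(fc_df)[1L])
  if (!is.null(sample)) {
    if (!all(sample %in% samples)) {
      stop("sample(s) not found in fold-change table", call. = FALSE)
    }
    samples <- sample
  }
  v <- .node_value_matrix(graph, fc_df, samples, gene_agg)
  dplyr::bind_cols(tibble::tibble(node = rownames(v)), tibble::as_tibble(v))
}

# nodes x samples matrix of aggregated member-gene fold changes
.node_value_matrix <- function(graph, fc_df, samples, gene_agg) {
  genes <- as.character(fc_df[[1L]])
  x <- as.matrix(fc_df[, samples, drop = FALSE])
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("fold changes must be finite and strictly positive", call. = FALSE)
  }
  rownames(x) <- genes
  v <- matrix(1, nrow = length(graph$nodes), ncol = length(samples),
              dimnames = list(graph$nodes, samples))
  gl <- split(graph$node_genes$gene, graph$node_genes$node)
  for (n in names(gl)) {
    g <- intersect(gl[[n]], genes)
    if (length(g) == 0L) next
    sub <- x[g, , drop = FALSE]
    v[n, ] <- if (gene_agg == "geometric") {
      2^colMeans(log2(sub))
    } else {
      colMeans(sub)
    }
  }
  v
}

#' Propagate node fold changes to pathway sinks
#'
#' Signal values are computed in topological order, starting from the
#' input nodes and finishing at the sinks. An input node's signal equals
#' its own fold-change value. For any other node `v` with value `E(v)`,
#' incoming edges contribute `S(u)` when the edge `u -> v` is an
#' activation and `1/S(u)` when it is an inhibition; the contributions
#' are combined across parents (arithmetic mean by default) and the
#' node's signal is `S(v) = E(v) * combined`. A larger source signal thus
#' raises the target under activation and lowers it under inhibition,
#' and a fold-change field of all ones propagates to sink values of
#' exactly 1.
#'
#' @param graph An acyclic [pathway_graph()] (see [resolve_cycles()]).
#' @param node_values Tibble with columns `node`, `value` (or a named
#'   numeric vector), strictly positive, covering every graph node.
#' @param agg Parent aggregation rule: `"mean"` (default), `"sum"` or
#'   `"product"`.
#' @return Tibble with columns `sink`, `psf`.
#' @export
propagate <- function(graph, node_values, agg = c("mean", "sum", "product")) {
  agg <- match.arg(agg)
  stopifnot(inherits(graph, "pathway_graph"))
  if (!.is_acyclic(graph)) {
    stop("graph contains cycles; run resolve_cycles() first", call. = FALSE)
  }
  if (is.data.frame(node_values)) {
    v <- stats::setNames(node_values$value, node_values$node)
  } else {
    v <- node_values
  }
  missing <- setdiff(graph$nodes, names(v))
  if (length(missing) > 0L) {
    stop("node value(s) missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- matrix(v[graph$nodes], ncol = 1, dimnames = list(graph$nodes, "s"))
  s <- .propagate_matrix(graph, m, agg)
  tibble::tibble(sink = rownames(s), psf = as.numeric(s[, 1L]))
}

# vectorized propagation: values is nodes x samples, returns sinks x samples
.propagate_matrix <- function(graph, values, agg = "mean") {
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("node values must be finite and strictly positive", call. = FALSE)
  }
  order <- .topo_order(graph)
  if (is.null(order)) {
    stop("graph contains cycles; run resolve_cycles() first", call. = FALSE)
  }
  e <- graph$edges
  parents <- split(seq_len(nrow(e)), e$to)
  s <- values[order, , drop = FALSE]
  s <- s[graph$nodes, , drop = FALSE] # keep canonical row order
  for (n in order) {
    idx <- parents[[n]]
    if (is.null(idx)) next # input node: S = E
    w <- s[e$from[idx], , drop = FALSE]
    inh <- e$sign[idx] == "inhibition"
    if (any(inh)) w[inh, ] <- 1 / w[inh, , drop = FALSE]
    comb <- switch(agg,
      mean = colMeans(w),
      sum = colSums(w),
      product = apply(w, 2, prod))
    s[n, ] <- values[n, ] * comb
  }
  sinks <- sort(setdiff(graph$nodes, unique(e$from)))
  s[sinks, , drop = FALSE]
}

#' Pathway signal flow matrix for a pathway collection
#'
#' Runs node-value assignment and propagation for every case sample and
#' every pathway in the collection, giving one activity value per sink
#' (pathway branch) and sample. Values of 1 mean unchanged versus
#' controls; values above/below 1 indicate branch activation and
#' de-activation.
#'
#' @param fc_df Fold-change tibble ([fold_changes()]); columns beyond the
#'   first are case samples.
#' @param pathways List of [pathway_graph()] objects (cycles are resolved
#'   internally).
#' @inheritParams assign_node_values
#' @inheritParams propagate
#' @return Tibble with columns `pathway_id`, `sink`, `sink_id` and one
#'   numeric column per sample, rows ordered by (pathway_id, sink).
#' @export
psf_scores <- function(fc_df, pathways,
                       gene_agg = c("geometric", "arithmetic"),
                       agg = c("mean", "sum", "product")) {
  gene_agg <- match.arg(gene_agg)
  agg <- match.arg(agg)
  stopifnot(length(pathways) > 0L)
  fc_df <- tibble::as_tibble(fc_df)
  samples <- setdiff(names(fc_df), names(fc_df)[1L])
  rows <- purrr::map(pathways, function(g) {
    rg <- resolve_cycles(g)
    v <- .node_value_matrix(rg, fc_df, samples, gene_agg)
    s <- .propagate_matrix(rg, v, agg)
    dplyr::bind_cols(
      tibble::tibble(pathway_id = rg$pathway_id, sink = rownames(s),
                     sink_id = paste(rg$pathway_id, rownames(s), sep = ":")),
      tibble::as_tibble(s))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$pathway_id, .data$sink)
  if (anyDuplicated(out$sink_id) > 0L) {
    stop("duplicated sink_id across the pathway collection", call. = FALSE)
  }
  out
}

# sinks x samples numeric matrix from a psf_scores() tibble
.psf_as_matrix <- function(psf_df) {
  meta <- c("pathway_id", "sink", "sink_id")
  samples <- setdiff(names(psf_df), meta)
  m <- as.matrix(psf_df[, samples, drop = FALSE])
  rownames(m) <- psf_df$sink_id
  m
}
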