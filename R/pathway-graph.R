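#' Construct a signed pathway graph
#'
#' A pathway is modelled as a directed graph whose nodes are gene groups and
#' whose edges are signed interactions: `"activation"` or `"inhibition"`.
#' Input nodes (in-degree zero after cycle resolution) receive the raw
#' fold-change signal; sink nodes (out-degree zero) are the endpoints of
#' pathway branches and carry the propagated activity values.
#'
#' @param edges Data frame with columns `from`, `to`, `sign`
#'   (`"activation"` or `"inhibition"`). May have zero rows for an
#'   edge-less pathway.
#' @param node_genes Optional data frame with columns `node`, `gene`
#'   (one row per node-gene pair). Nodes without genes (e.g. compounds)
#'   act as neutral relay nodes during propagation.
#' @param pathway_id Identifier used to build globally unique sink ids.
#' @param nodes Optional character vector of extra (possibly isolated)
#'   node ids to include beyond those seen in `edges`/`node_genes`.
#' @return An object of class `pathway_graph`: a list with `pathway_id`,
#'   `nodes` (character), `edges` (tibble) and `node_genes` (tibble).
#' @examples
#' g <- pathway_graph(
#'   data.frame(from = c("A", "B"), to = c("B", "C"),
#'              sign = c("activation", "inhibition")),
#'   pathway_id = "toy")
#' pathway_sinks(g)
#' @export
pathway_graph <- function(edges, node_genes = NULL, pathway_id = "pathway",
                          nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) == 0L) {
    edges <- tibble::tibble(from = character(), to = character(),
                            sign = character())
  }
  stopifnot(all(c("from", "to", "sign") %in% names(edges)))
  edges <- dplyr::mutate(edges,
                         from = as.character(.data$from),
                         to = as.character(.data$to),
                         sign = as.character(.data$sign))
  bad <- setdiff(unique(edges$sign), c("activation", "inhibition"))
  if (length(bad) > 0L) {
    stop("unknown edge sign(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(node_genes)) {
    node_genes <- tibble::tibble(node = character(), gene = character())
  } else {
    node_genes <- tibble::as_tibble(node_genes)
    stopifnot(all(c("node", "gene") %in% names(node_genes)))
    node_genes <- dplyr::distinct(dplyr::mutate(
      node_genes, node = as.character(.data$node),
      gene = as.character(.data$gene)))
  }
  all_nodes <- sort(unique(c(edges$from, edges$to, node_genes$node,
                             as.character(nodes))))
  if (length(all_nodes) == 0L) {
    stop("pathway has no nodes", call. = FALSE)
  }
  edges <- dplyr::arrange(edges, .data$from, .data$to, .data$sign)
  structure(
    list(pathway_id = as.character(pathway_id), nodes = all_nodes,
         edges = edges, node_genes = node_genes),
    class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %s: %d nodes, %d edges (%d inhibition)\n",
              x$pathway_id, length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "inhibition")))
  rg <- resolve_cycles(x)
  cat(sprintf("  inputs: %s\n  sinks:  %s\n",
              paste(pathway_inputs(rg), collapse = ", "),
              paste(pathway_sinks(rg), collapse = ", ")))
  invisible(x)
}

# adjacency list with neighbours in canonical (sorted) order
.adjacency <- function(graph, reverse = FALSE) {
  adj <- stats::setNames(vector("list", length(graph$nodes)), graph$nodes)
  e <- graph$edges
  src <- if (reverse) e$to else e$from
  dst <- if (reverse) e$from else e$to
  for (nm in names(adj)) adj[[nm]] <- character()
  if (nrow(e) > 0L) {
    sp <- split(dst, src)
    for (nm in names(sp)) adj[[nm]] <- sort(unique(sp[[nm]]))
  }
  adj
}

.is_acyclic <- function(graph) {
  !is.null(.topo_order(graph))
}

# Kahn's algorithm; NULL when the graph has a cycle
.topo_order <- function(graph) {
  nodes <- graph$nodes
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(graph$edges) > 0L) {
    tab <- table(graph$edges$to)
    indeg[names(tab)] <- as.integer(tab)
  }
  adj <- .adjacency(graph)
  queue <- sort(names(indeg)[indeg == 0L])
  order <- character(0)
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    order <- c(order, v)
    for (w in adj[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- sort(c(queue, w))
    }
  }
  if (length(order) < length(nodes)) NULL else order
}

#' Resolve feedback cycles in a pathway graph
#'
#' Pathway maps routinely contain feedback edges, but signal propagation
#' needs an evaluable (acyclic) order. Cycles are resolved by a
#' depth-first search started from the canonically sorted input nodes
#' (in-degree zero); any edge that closes a cycle on the DFS stack is
#' removed. The result is acyclic, its edges are a subset of the input's,
#' and the removal is deterministic given the canonical node ordering.
#' Acyclic graphs are returned unchanged (idempotent).
#'
#' @param graph A [pathway_graph()].
#' @return A `pathway_graph` with the same nodes and a (possibly) reduced
#'   edge set, carrying attribute `"removed_edges"` with the dropped rows.
#' @export
resolve_cycles <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (.is_acyclic(graph)) {
    attr(graph, "removed_edges") <- graph$edges[0, ]
    return(graph)
  }
  indeg <- stats::setNames(integer(length(graph$nodes)), graph$nodes)
  tab <- table(graph$edges$to)
  indeg[names(tab)] <- as.integer(tab)
  roots <- sort(names(indeg)[indeg == 0L])
  if (length(roots) == 0L) {
    stop("every node lies on a cycle; designate entry nodes by removing ",
         "an incoming edge of the intended input", call. = FALSE)
  }
  adj <- .adjacency(graph)
  state <- stats::setNames(rep(0L, length(graph$nodes)), graph$nodes) # 0 white 1 grey 2 black
  drop_from <- character(0)
  drop_to <- character(0)
  visit <- function(v) {
    state[[v]] <<- 1L
    for (w in adj[[v]]) {
      if (state[[w]] == 1L) {
        drop_from <<- c(drop_from, v)
        drop_to <<- c(drop_to, w)
      } else if (state[[w]] == 0L) {
        visit(w)
      }
    }
    state[[v]] <<- 2L
  }
  for (r in roots) if (state[[r]] == 0L) visit(r)
  # cycle components unreachable from any input: continue in canonical order
  for (r in graph$nodes) if (state[[r]] == 0L) visit(r)
  keep <- rep(TRUE, nrow(graph$edges))
  for (i in seq_along(drop_from)) {
    hit <- which(graph$edges$from == drop_from[i] &
                   graph$edges$to == drop_to[i] & keep)
    if (length(hit) > 0L) keep[hit] <- FALSE
  }
  out <- pathway_graph(graph$edges[keep, ], graph$node_genes,
                       graph$pathway_id, nodes = graph$nodes)
  attr(out, "removed_edges") <- graph$edges[!keep, ]
  out
}

#' Input and sink nodes of a pathway graph
#'
#' Inputs are nodes with in-degree zero and sinks nodes with out-degree
#' zero, both taken on the cycle-resolved graph (see [resolve_cycles()]).
#' An isolated node is both an input and a sink.
#'
#' @param graph A [pathway_graph()].
#' @return Character vector of node ids, canonically sorted.
#' @export
pathway_sinks <- function(graph) {
  g <- resolve_cycles(graph)
  sinks <- sort(setdiff(g$nodes, unique(g$edges$from)))
  if (length(sinks) == 0L) {
    stop("cycle-resolved pathway has no sink nodes", call. = FALSE)
  }
  sinks
}

#' @rdname pathway_sinks
#' @export
pathway_inputs <- function(graph) {
  g <- resolve_cycles(graph)
  inputs <- sort(setdiff(g$nodes, unique(g$edges$to)))
  if (length(inputs) == 0L) {
    stop("cycle-resolved pathway has no input nodes", call. = FALSE)
  }
  inputs
}

#' Enumerate pathway branches
#'
#' A branch is the subnetwork of interactions terminating in a single
#' sink: one branch per sink, whose member set is the reverse-reachability
#' set of that sink. Branches of the same pathway overlap wherever their
#' sinks share upstream nodes. Sink ids (`pathway_id:sink`) are globally
#' unique across a pathway collection.
#'
#' @param graph A [pathway_graph()] (cycles resolved internally).
#' @return Tibble with one row per sink: `pathway_id`, `sink`, `sink_id`,
#'   `members` (list-column of node ids), `n_nodes`.
#' @export
enumerate_branches <- function(graph) {
  g <- resolve_cycles(graph)
  sinks <- pathway_sinks(g)
  radj <- .adjacency(g, reverse = TRUE)
  members <- lapply(sinks, function(s) {
    seen <- s
    frontier <- s
    while (length(frontier) > 0L) {
      nxt <- setdiff(unique(unlist(radj[frontier], use.names = FALSE)), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    sort(seen)
  })
  tibble::tibble(
    pathway_id = g$pathway_id,
    sink = sinks,
    sink_id = paste(g$pathway_id, sinks, sep = ":"),
    members = members,
    n_nodes = lengths(members))
}

# ---- KGML -------------------------------------------------------------------

.kgml_activating <- c("activation", "expression")
.kgml_inhibiting <- c("inhibition", "repression")

.kgml_sign <- function(subtypes, unsigned) {
  if (any(subtypes %in% .kgml_inhibiting)) return("inhibition")
  if (any(subtypes %in% .kgml_activating)) return("activation")
  if (unsigned == "activation") "activation" else NA_character_
}

#' Parse a KGML pathway file
#'
#' Reads a KEGG KGML (XML) pathway description into a [pathway_graph()].
#' Entries of type `gene`, `group` and `compound` become nodes (group
#' entries are flattened into a single node whose gene set is the union of
#' their components; compound entries carry no genes and act as neutral
#' relays). `map` and other entry types are dropped. Relation subtypes are
#' mapped to signs: activation/expression (and phosphorylation combined
#' with activation) give activation; inhibition/repression (and
#' dephosphorylation combined with inhibition) give inhibition. Subtypes
#' with no inherent sign (binding/association, indirect effect, bare
#' phosphorylation) default to activation, or are dropped when
#' `unsigned = "drop"`.
#'
#' @param path Path to a KGML file.
#' @param unsigned How to treat relations whose subtypes carry no sign:
#'   `"activation"` (default) or `"drop"`.
#' @return A [pathway_graph()]; its `pathway_id` is taken from the file's
#'   `name`/`title` attributes.
#' @export
parse_kgml <- function(path, unsigned = c("activation", "drop")) {
  unsigned <- match.arg(unsigned)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed KGML in '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(root)) stop("'", path, "' is not a KGML pathway file",
                        call. = FALSE)
  pid <- xml2::xml_attr(root, "name")
  if (is.na(pid) || pid == "") pid <- xml2::xml_attr(root, "title")
  pid <- sub("^path:", "", pid)

  entries <- xml2::xml_find_all(doc, "/pathway/entry")
  ids <- xml2::xml_attr(entries, "id")
  types <- xml2::xml_attr(entries, "type")
  names_attr <- xml2::xml_attr(entries, "name")
  keep_type <- types %in% c("gene", "group", "compound")
  entry_genes <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    if (!keep_type[i]) next
    if (types[i] == "gene") {
      entry_genes[[ids[i]]] <- strsplit(names_attr[i], "\\s+")[[1]]
    } else if (types[i] == "group") {
      comp <- xml2::xml_attr(
        xml2::xml_find_all(entries[[i]], "./component"), "id")
      genes <- unlist(lapply(comp, function(cid) {
        j <- match(cid, ids)
        if (!is.na(j) && types[j] == "gene") {
          strsplit(names_attr[j], "\\s+")[[1]]
        } else character()
      }), use.names = FALSE)
      entry_genes[[ids[i]]] <- unique(genes)
    } else {
      entry_genes[[ids[i]]] <- character()
    }
  }
  kept_ids <- ids[keep_type]
  if (length(kept_ids) == 0L) {
    stop("KGML '", path, "' contains no gene/group/compound entries",
         call. = FALSE)
  }

  relations <- xml2::xml_find_all(doc, "/pathway/relation")
  from <- to <- sgn <- character(0)
  n_dropped <- 0L
  for (rel in relations) {
    e1 <- xml2::xml_attr(rel, "entry1")
    e2 <- xml2::xml_attr(rel, "entry2")
    if (!(e1 %in% kept_ids) || !(e2 %in% kept_ids)) {
      n_dropped <- n_dropped + 1L
      next
    }
    subtypes <- xml2::xml_attr(xml2::xml_find_all(rel, "./subtype"), "name")
    s <- .kgml_sign(subtypes, unsigned)
    if (is.na(s)) {
      n_dropped <- n_dropped + 1L
      next
    }
    from <- c(from, e1)
    to <- c(to, e2)
    sgn <- c(sgn, s)
  }
  if (n_dropped > 0L) {
    warning(n_dropped, " relation(s) dropped in '", pid,
            "' (unretained endpoints or unmapped subtype)", call. = FALSE)
  }
  if (length(from) == 0L) {
    stop("pathway '", pid, "' has no signed interactions", call. = FALSE)
  }
  ng <- tibble::tibble(
    node = rep(kept_ids, lengths(entry_genes[kept_ids])),
    gene = unlist(entry_genes[kept_ids], use.names = FALSE))
  g <- pathway_graph(tibble::tibble(from = from, to = to, sign = sgn),
                     node_genes = ng, pathway_id = pid, nodes = kept_ids)
  # curated pathway maps normally have several inputs and several sinks;
  # fewer than two of either usually signals a truncated file
  if (length(pathway_inputs(g)) < 2L || length(pathway_sinks(g)) < 2L) {
    warning("pathway '", pid, "' has fewer than 2 inputs or sinks",
            call. = FALSE)
  }
  g
}

# ---- plain-graph TSV dialect ------------------------------------------------

#' Read and write pathway collections as plain TSV
#'
#' The plain-graph dialect stores a pathway collection in two TSV files:
#' an edge table (`pathway_id`, `source`, `target`, `sign`) and a
#' node-gene table (`pathway_id`, `node`, `genes` with comma-separated
#' gene ids; empty for gene-less relay nodes). Both are written in
#' canonical sort order so that write/read round-trips are exact.
#'
#' @param pathways List of [pathway_graph()] objects.
#' @param edges_path,genes_path File paths for the two tables.
#' @return `read_pathway_collection()` returns a named list of
#'   `pathway_graph` objects; `write_pathway_collection()` returns the
#'   paths invisibly.
#' @export
write_pathway_collection <- function(pathways, edges_path, genes_path) {
  stopifnot(length(pathways) > 0L)
  edges <- purrr::map_dfr(pathways, function(g) {
    tibble::tibble(pathway_id = g$pathway_id, source = g$edges$from,
                   target = g$edges$to, sign = g$edges$sign)
  })
  edges <- dplyr::arrange(edges, .data$pathway_id, .data$source,
                          .data$target, .data$sign)
  genes <- purrr::map_dfr(pathways, function(g) {
    gl <- split(g$node_genes$gene, g$node_genes$node)
    tibble::tibble(
      pathway_id = g$pathway_id,
      node = g$nodes,
      genes = vapply(g$nodes, function(n) {
        paste(sort(gl[[n]]), collapse = ",")
      }, character(1)))
  })
  genes <- dplyr::arrange(genes, .data$pathway_id, .data$node)
  readr::write_tsv(edges, edges_path)
  readr::write_tsv(genes, genes_path)
  invisible(c(edges_path, genes_path))
}

#' @rdname write_pathway_collection
#' @export
read_pathway_collection <- function(edges_path, genes_path) {
  edges <- readr::read_tsv(edges_path, col_types = "cccc")
  genes <- readr::read_tsv(genes_path, col_types = "ccc")
  genes$genes[is.na(genes$genes)] <- ""
  pids <- sort(unique(c(edges$pathway_id, genes$pathway_id)))
  out <- lapply(pids, function(pid) {
    e <- edges[edges$pathway_id == pid, ]
    gn <- genes[genes$pathway_id == pid, ]
    gene_list <- strsplit(gn$genes, ",", fixed = TRUE)
    ng <- tibble::tibble(
      node = rep(gn$node, lengths(gene_list)),
      gene = unlist(gene_list, use.names = FALSE))
    pathway_graph(
      tibble::tibble(from = e$source, to = e$target, sign = e$sign),
      node_genes = ng, pathway_id = pid, nodes = gn$node)
  })
  stats::setNames(out, pids)
}
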