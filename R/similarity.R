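#' Number of spots shared by two disease call profiles
#'
#' Two diseases share a spot when both call it with the same nonzero
#' sign (default), or — with `sign_aware = FALSE` — when both call it
#' nonzero regardless of direction. The count is symmetric and bounded
#' by the number of spot labels.
#'
#' @param a,b Named character vectors of calls (`"+"`, `"-"`, `"0"`),
#'   named by spot label.
#' @param sign_aware Require equal signs (default `TRUE`)?
#' @return Integer shared-spot count over the common labels.
#' @export
shared_spot_count <- function(a, b, sign_aware = TRUE) {
  labels <- intersect(names(a), names(b))
  a <- a[labels]
  b <- b[labels]
  nz <- a != "0" & b != "0"
  if (sign_aware) sum(nz & a == b) else sum(nz)
}

#' Build the spot-sharing disease similarity graph
#'
#' For every disease the shared-spot count to each other disease is
#' computed; an edge is drawn from the disease to every disease achieving
#' its maximum count (ties introduce several edges). Edges proposed from
#' both endpoints, or repeatedly through ties, are merged with their
#' multiplicity recorded and later used as the edge weight for community
#' detection. Diseases whose counts are all zero remain isolated (with a
#' warning).
#'
#' @param calls_df Tibble with columns `disease`, `spot`, `call` as
#'   returned by [spot_calls()].
#' @inheritParams shared_spot_count
#' @return A `disease_graph`: list with `graph` (an igraph object whose
#'   edges carry `weight` = multiplicity), `edges` (tibble `from`, `to`,
#'   `multiplicity`), `nodes` and the pairwise `counts` tibble.
#' @export
build_similarity_graph <- function(calls_df, sign_aware = TRUE) {
  calls_df <- tibble::as_tibble(calls_df)
  stopifnot(all(c("disease", "spot", "call") %in% names(calls_df)))
  diseases <- sort(unique(calls_df$disease))
  if (length(diseases) < 2L) stop("need at least 2 diseases", call. = FALSE)
  profs <- lapply(diseases, function(d) {
    sub <- calls_df[calls_df$disease == d, ]
    stats::setNames(sub$call, sub$spot)
  })
  names(profs) <- diseases

  pairs <- utils::combn(diseases, 2)
  counts <- tibble::tibble(
    a = pairs[1, ], b = pairs[2, ],
    shared = purrr::map2_int(pairs[1, ], pairs[2, ], function(x, y) {
      as.integer(shared_spot_count(profs[[x]], profs[[y]], sign_aware))
    }))

  count_of <- function(x, y) {
    hit <- (counts$a == x & counts$b == y) | (counts$a == y & counts$b == x)
    counts$shared[hit]
  }
  from <- to <- character(0)
  isolated <- character(0)
  for (d in diseases) {
    others <- setdiff(diseases, d)
    cs <- vapply(others, function(o) count_of(d, o), integer(1))
    mx <- max(cs)
    if (mx == 0L) {
      isolated <- c(isolated, d)
      next
    }
    for (o in others[cs == mx]) {
      from <- c(from, d)
      to <- c(to, o)
    }
  }
  if (length(isolated) > 0L) {
    warning("disease(s) share no spot with any other: ",
            paste(isolated, collapse = ", "), call. = FALSE)
  }
  if (length(from) > 0L) {
    key <- ifelse(from < to, paste(from, to, sep = "\r"),
                  paste(to, from, sep = "\r"))
    mult <- table(key)
    parts <- strsplit(names(mult), "\r", fixed = TRUE)
    edges <- tibble::tibble(
      from = vapply(parts, `[`, character(1), 1L),
      to = vapply(parts, `[`, character(1), 2L),
      multiplicity = as.integer(mult))
    edges <- dplyr::arrange(edges, .data$from, .data$to)
  } else {
    edges <- tibble::tibble(from = character(), to = character(),
                            multiplicity = integer())
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = diseases))
  igraph::E(g)$weight <- edges$multiplicity
  structure(
    list(graph = g, edges = edges, nodes = diseases, counts = counts,
         sign_aware = sign_aware),
    class = "disease_graph")
}

#' @export
print.disease_graph <- function(x, ...) {
  cat(sprintf("<disease_graph> %d diseases, %d merged edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
tidy.disease_graph <- function(x, ...) x$edges

#' @export
glance.disease_graph <- function(x, ...) {
  tibble::tibble(n_diseases = length(x$nodes), n_edges = nrow(x$edges),
                 sign_aware = x$sign_aware)
}

#' Random-walk community detection on the disease graph
#'
#' Runs the walktrap algorithm (random-walk agglomeration, walk length
#' `steps`) with edge multiplicities as weights and cuts the merge tree
#' at maximal modularity. Deterministic given the graph.
#'
#' @param graph A [build_similarity_graph()] result (or an igraph object).
#' @param steps Random-walk length.
#' @return Tibble with columns `disease`, `community` (integer ids).
#' @export
detect_communities <- function(graph, steps = 4) {
  g <- if (inherits(graph, "disease_graph")) graph$graph else graph
  if (igraph::vcount(g) == 0L) stop("empty graph", call. = FALSE)
  wt <- igraph::cluster_walktrap(g, steps = steps)
  tibble::tibble(
    disease = igraph::V(g)$name,
    community = as.integer(igraph::membership(wt))) |>
    dplyr::arrange(.data$disease)
}

#' Write a disease graph as GraphML and edge-list TSV
#'
#' @param graph A [build_similarity_graph()] result.
#' @param graphml_path,edges_path Output file paths (either may be NULL
#'   to skip).
#' @return The written paths, invisibly.
#' @export
write_disease_graph <- function(graph, graphml_path = NULL,
                                edges_path = NULL) {
  stopifnot(inherits(graph, "disease_graph"))
  if (!is.null(graphml_path)) {
    igraph::write_graph(graph$graph, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    readr::write_tsv(graph$edges, edges_path)
  }
  invisible(c(graphml_path, edges_path))
}
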