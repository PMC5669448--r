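# small constructors shared across test files

chain_graph <- function(nodes = c("A", "B", "C"), sign = "activation",
                        pathway_id = "chain") {
  n <- length(nodes)
  pathway_graph(
    tibble::tibble(from = nodes[-n], to = nodes[-1],
                   sign = rep_len(sign, n - 1L)),
    pathway_id = pathway_id)
}

# random DAG on node labels n01..nN via topological-order edge sampling
random_dag <- function(n, p, inhibition = 0.3, pathway_id = "rnd") {
  nodes <- sprintf("n%02d", seq_len(n))
  from <- to <- character(0)
  for (i in seq_len(n - 1L)) {
    tgt <- which(stats::runif(n - i) < p) + i
    from <- c(from, rep(nodes[i], length(tgt)))
    to <- c(to, nodes[tgt])
  }
  sgn <- ifelse(stats::runif(length(from)) < inhibition,
                "inhibition", "activation")
  pathway_graph(tibble::tibble(from = from, to = to, sign = sgn),
                pathway_id = pathway_id, nodes = nodes)
}

# independent memoized recursive evaluator of the propagation rule;
# deliberately written as plain recursion over parents, not topological
# sweep, to serve as an oracle for propagate()
recursive_psf <- function(graph, values, agg = "mean") {
  memo <- new.env(parent = emptyenv())
  e <- graph$edges
  eval_node <- function(v) {
    if (!is.null(memo[[v]])) return(memo[[v]])
    idx <- which(e$to == v)
    out <- if (length(idx) == 0L) {
      values[[v]]
    } else {
      w <- vapply(idx, function(i) {
        s <- eval_node(e$from[i])
        if (e$sign[i] == "inhibition") 1 / s else s
      }, numeric(1))
      comb <- switch(agg, mean = mean(w), sum = sum(w), product = prod(w))
      values[[v]] * comb
    }
    memo[[v]] <- out
    out
  }
  sinks <- sort(setdiff(graph$nodes, unique(e$from)))
  vapply(sinks, eval_node, numeric(1))
}

gauss_blob <- function(rows, cols, center, amp = 1, sigma = 2) {
  r <- rep(seq_len(rows), each = cols)
  cc <- rep(seq_len(cols), times = rows)
  amp * exp(-((r - center[1])^2 + (cc - center[2])^2) / (2 * sigma^2))
}

# portrait tibble built directly on a grid (bypasses SOM training)
make_portrait <- function(values, rows, cols, owner = "p") {
  out <- tibble::tibble(
    unit = seq_len(rows * cols),
    row = rep(seq_len(rows), each = cols),
    col = rep(seq_len(cols), times = rows),
    value = as.numeric(values),
    n_sinks = 1L,
    interpolated = FALSE)
  attr(out, "owner") <- owner
  attr(out, "rows") <- rows
  attr(out, "cols") <- cols
  class(out) <- c("psf_portrait", class(out))
  out
}
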