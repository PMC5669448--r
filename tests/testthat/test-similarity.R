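test_that("shared-spot counts are sign-aware, symmetric and bounded", {
  a <- c(A = "+", B = "+", C = "-")
  b <- c(A = "+", B = "-", C = "-")
  expect_equal(shared_spot_count(a, b), 2)
  expect_equal(shared_spot_count(b, a), 2)
  expect_equal(shared_spot_count(a, b, sign_aware = FALSE), 3)
  expect_equal(shared_spot_count(a, a), 3)
  expect_lte(shared_spot_count(a, b), length(a))
  # disjoint support
  expect_equal(shared_spot_count(c(A = "+", B = "0"),
                                 c(A = "0", B = "-")), 0)
})

calls_tbl <- function(profiles) {
  purrr::imap_dfr(profiles, function(p, d) {
    tibble::tibble(disease = d, spot = names(p), call = unname(p))
  })
}

test_that("each disease links to all diseases achieving its maximum count", {
  # pairwise shares: XY = 3, XZ = 1, YZ = 1; Z's max (1) is tied -> Z
  # connects to both, giving edge multiplicities XY:2, XZ:1, YZ:1
  profiles <- list(
    X = c(A = "+", B = "+", C = "+", D = "0", E = "0"),
    Y = c(A = "+", B = "+", C = "+", D = "-", E = "0"),
    Z = c(A = "+", B = "-", C = "0", D = "+", E = "-"))
  expect_equal(shared_spot_count(profiles$X, profiles$Y), 3)
  expect_equal(shared_spot_count(profiles$X, profiles$Z), 1)
  expect_equal(shared_spot_count(profiles$Y, profiles$Z), 1)
  g <- build_similarity_graph(calls_tbl(profiles))
  e <- tidy(g)
  expect_equal(e$multiplicity[e$from == "X" & e$to == "Y"], 2L)
  expect_equal(e$multiplicity[e$from == "X" & e$to == "Z"], 1L)
  expect_equal(e$multiplicity[e$from == "Y" & e$to == "Z"], 1L)

  # two diseases: a single edge
  g2 <- build_similarity_graph(calls_tbl(profiles[1:2]))
  expect_equal(nrow(tidy(g2)), 1L)

  # all-zero sharing: isolated nodes with a warning
  z <- list(P = c(A = "+", B = "0"), Q = c(A = "-", B = "0"))
  expect_warning(gz <- build_similarity_graph(calls_tbl(z)), "no spot")
  expect_equal(nrow(tidy(gz)), 0L)
  expect_equal(igraph::vcount(gz$graph), 2L)
})

test_that("edge set equals a brute-force argmax oracle on random profiles", {
  withr::with_seed(55, {
    for (rep in 1:20) {
      n <- sample(4:8, 1)
      diseases <- sprintf("d%02d", seq_len(n))
      spots <- LETTERS[1:6]
      profiles <- lapply(stats::setNames(diseases, diseases), function(d) {
        stats::setNames(sample(c("+", "-", "0"), 6, replace = TRUE), spots)
      })
      g <- build_similarity_graph(calls_tbl(profiles)) |> suppressWarnings()
      # oracle: directed argmax edges, then merged with multiplicity
      cnt <- outer(diseases, diseases, Vectorize(function(x, y) {
        shared_spot_count(profiles[[x]], profiles[[y]])
      }))
      dimnames(cnt) <- list(diseases, diseases)
      exp_from <- exp_to <- character(0)
      for (d in diseases) {
        cs <- cnt[d, setdiff(diseases, d)]
        if (max(cs) == 0) next
        for (o in names(cs)[cs == max(cs)]) {
          exp_from <- c(exp_from, min(d, o))
          exp_to <- c(exp_to, max(d, o))
        }
      }
      want <- table(paste(exp_from, exp_to))
      e <- tidy(g)
      got <- stats::setNames(e$multiplicity, paste(e$from, e$to))
      expect_equal(got[order(names(got))],
                   stats::setNames(as.integer(want), names(want)),
                   ignore_attr = TRUE)
    }
  })
})

test_that("graph construction is invariant to disease order", {
  profiles <- list(
    X = c(A = "+", B = "+"), Y = c(A = "+", B = "-"),
    Z = c(A = "-", B = "-"))
  tbl <- calls_tbl(profiles)
  g1 <- build_similarity_graph(tbl)
  g2 <- build_similarity_graph(tbl[sample(nrow(tbl)), ])
  expect_identical(tidy(g1), tidy(g2))
})

test_that("walktrap separates planted community structure", {
  # two 3-cliques joined by one edge
  g <- igraph::make_graph(~ a - b, a - c, b - c, d - e, d - f, e - f,
                          c - d)
  igraph::E(g)$weight <- 1
  com <- detect_communities(g)
  expect_equal(length(unique(com$community)), 2L)
  expect_equal(length(unique(com$community[com$disease %in%
                                             c("a", "b", "c")])), 1L)

  # complete graph: one community
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  igraph::E(k5)$weight <- 1
  expect_equal(length(unique(detect_communities(k5)$community)), 1L)

  expect_error(detect_communities(igraph::make_empty_graph()), "empty")
})

test_that("planted two-block graphs are recovered in >= 90% of seeds", {
  hits <- vapply(1:100, function(s) {
    withr::with_seed(2000 + s, {
      n <- 12
      block <- rep(1:2, each = n / 2)
      m <- matrix(0L, n, n)
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        p <- if (block[i] == block[j]) 0.9 else 0.1
        if (stats::runif(1) < p) m[i, j] <- 1L
      }
      g <- igraph::graph_from_adjacency_matrix(m + t(m), mode = "undirected")
      igraph::V(g)$name <- sprintf("v%02d", 1:n)
      igraph::E(g)$weight <- 1
      com <- detect_communities(g)
      length(unique(com$community)) == 2 &&
        all(tapply(com$community, block,
                   function(x) length(unique(x))) == 1)
    })
  }, logical(1))
  expect_gte(sum(hits), 90)
})
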