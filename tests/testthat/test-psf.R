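test_that("node values aggregate member-gene fold changes", {
  g <- chain_graph(c("A", "B"))
  g$node_genes <- tibble::tibble(node = c("A", "A", "B"),
                                 gene = c("g1", "g2", "g3"))
  fc <- tibble::tibble(gene = c("g1", "g2"), s1 = c(2, 0.5))
  nv <- assign_node_values(g, fc, "s1")
  # geometric mean of a doubling and a halving is neutral
  expect_equal(nv$s1[nv$node == "A"], 1)
  # no measured genes -> neutral value
  expect_equal(nv$s1[nv$node == "B"], 1)

  fc3 <- tibble::tibble(gene = "g1", s1 = 3)
  expect_equal(assign_node_values(g, fc3, "s1")$s1[1], 3)

  # arithmetic alternative
  nv2 <- assign_node_values(g, fc, "s1", gene_agg = "arithmetic")
  expect_equal(nv2$s1[nv2$node == "A"], 1.25)
})

test_that("propagation applies the signed multiplicative update rule", {
  act <- chain_graph(c("A", "B"))
  out <- propagate(act, c(A = 2, B = 1))
  expect_equal(out$psf, 2)

  inh <- chain_graph(c("A", "B"), sign = "inhibition")
  expect_equal(propagate(inh, c(A = 2, B = 1))$psf, 0.5)

  # neutral field propagates to neutral sinks
  g <- random_dag(8, 0.4)
  ones <- stats::setNames(rep(1, 8), g$nodes)
  expect_true(all(propagate(g, ones)$psf == 1))

  expect_error(propagate(act, c(A = -1, B = 1)), "positive")
  cyc <- pathway_graph(tibble::tibble(from = c("X", "A", "B"),
                                      to = c("A", "B", "A"),
                                      sign = "activation"))
  expect_error(propagate(cyc, c(X = 1, A = 1, B = 1)), "resolve_cycles")
})

test_that("propagation agrees exactly with a memoized recursive oracle", {
  withr::with_seed(123, {
    for (i in 1:100) {
      n <- sample(3:10, 1)
      g <- random_dag(n, stats::runif(1, 0.2, 0.6))
      v <- stats::setNames(stats::runif(n, 0.25, 4), g$nodes)
      for (agg in c("mean", "sum", "product")) {
        got <- propagate(g, v, agg = agg)
        want <- recursive_psf(g, v, agg = agg)
        expect_equal(stats::setNames(got$psf, got$sink), want,
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("activation paths are monotone and one inhibition reverses the direction", {
  withr::with_seed(77, {
    for (i in 1:50) {
      n <- sample(3:8, 1)
      g <- chain_graph(sprintf("n%d", 1:n))
      v <- stats::setNames(stats::runif(n, 0.5, 2), g$nodes)
      base <- propagate(g, v)$psf
      j <- sample(n - 1L, 1)
      v2 <- v
      v2[j] <- v2[j] * 2
      expect_gte(propagate(g, v2)$psf, base)

      # flip one edge: nodes upstream of the flip now act inversely
      gi <- g
      k <- sample(n - 1L, 1)
      gi$edges$sign[k] <- "inhibition"
      bi <- propagate(gi, v)$psf
      v3 <- v
      v3[k] <- v3[k] * 2  # upstream endpoint of the flipped edge
      expect_lte(propagate(gi, v3)$psf, bi)
    }
  })
})

test_that("inverting all node values on an activation graph inverts sink PSF", {
  # exact under product aggregation (and under any rule on single-parent
  # chains); arithmetic parent averaging is not reciprocal-symmetric for
  # multi-parent nodes
  withr::with_seed(31, {
    for (i in 1:20) {
      g <- random_dag(7, 0.4, inhibition = 0)
      v <- stats::setNames(stats::runif(7, 0.25, 4), g$nodes)
      s <- propagate(g, v, agg = "product")
      s_inv <- propagate(g, 1 / v, agg = "product")
      expect_equal(s_inv$psf, 1 / s$psf, tolerance = 1e-12)

      ch <- chain_graph(sprintf("c%d", 1:5))
      vc <- stats::setNames(stats::runif(5, 0.25, 4), ch$nodes)
      expect_equal(propagate(ch, 1 / vc)$psf, 1 / propagate(ch, vc)$psf,
                   tolerance = 1e-12)
    }
  })
})

test_that("psf_scores builds the sink-by-sample activity table", {
  withr::with_seed(2, {
    pws <- list(p1 = random_dag(6, 0.5, pathway_id = "p1"),
                p2 = random_dag(6, 0.5, pathway_id = "p2"))
  })
  genes <- sprintf("g%d", 1:12)
  for (nm in names(pws)) {
    pws[[nm]]$node_genes <- tibble::tibble(
      node = pws[[nm]]$nodes,
      gene = paste0(nm, "_", pws[[nm]]$nodes))
  }
  all_genes <- unlist(lapply(pws, function(g) g$node_genes$gene))
  fc <- dplyr::bind_cols(
    tibble::tibble(gene = all_genes),
    tibble::as_tibble(matrix(1, length(all_genes), 4,
                             dimnames = list(NULL, sprintf("s%d", 1:4)))))
  out <- psf_scores(fc, pws)
  n_sinks <- sum(vapply(pws, function(g) length(pathway_sinks(g)),
                        integer(1)))
  expect_equal(nrow(out), n_sinks)
  expect_equal(setdiff(names(out), c("pathway_id", "sink", "sink_id")),
               sprintf("s%d", 1:4))
  # neutrality: all-ones FC gives all-ones PSF, exactly
  expect_true(all(as.matrix(out[, sprintf("s%d", 1:4)]) == 1))
  # rows ordered by (pathway_id, sink)
  expect_identical(out$sink_id,
                   out$sink_id[order(out$pathway_id, out$sink)])

  # duplicated pathway ids give duplicated sink ids -> error
  expect_error(psf_scores(fc, c(pws, pws[1])), "duplicated sink_id")
})

test_that("a planted all-activation up-pathway yields sink PSF above 1", {
  g <- chain_graph(sprintf("n%d", 1:5), pathway_id = "up")
  g$node_genes <- tibble::tibble(node = g$nodes, gene = paste0("g", 1:5))
  fc <- tibble::tibble(gene = paste0("g", 1:5), s1 = 2, s2 = 2)
  out <- psf_scores(fc, list(g))
  expect_true(all(out$s1 > 1))
  expect_true(all(out$s2 > 1))
})
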