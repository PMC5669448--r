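#' Design of a synthetic multi-cohort benchmark
#'
#' Describes a collection of random signed pathway graphs and a set of
#' case/control expression datasets (one per disease) with planted
#' pathway activations. Diseases fall into two groups; each disease
#' up-regulates the genes of the pathways shared by all diseases plus
#' the pathways specific to its group, leaving the remaining pathways
#' null. Pathway ids are assigned in order: first the shared block, then
#' group 1, then group 2, then the null block.
#'
#' @param n_pathways Total number of pathways.
#' @param nodes_per_pathway,genes_per_node Pathway size parameters.
#' @param p_edge Edge probability between topologically ordered node
#'   pairs.
#' @param inhibition_fraction Probability that an edge is an inhibition.
#' @param diseases Tibble with columns `disease`, `group` (1 or 2),
#'   `n_cases`; default 12 diseases in two groups of 6 with 15 cases.
#' @param n_controls Controls per dataset.
#' @param n_shared Pathways planted up-regulated in every disease.
#' @param n_group Pathways planted up-regulated per group.
#' @param effect_logfc Planted effect size in log2 units.
#' @param noise_sd I.i.d. Gaussian noise s.d. in log2 units.
#' @param seed Integer seed.
#' @return A `synthetic_design` list; see [generate_pathways()],
#'   [generate_expression()] and [benchmark_suite()].
#' @export
synthetic_design <- function(n_pathways = 20, nodes_per_pathway = 12,
                             genes_per_node = 3, p_edge = 0.25,
                             inhibition_fraction = 0.2,
                             diseases = NULL, n_controls = 15,
                             n_shared = 4, n_group = 4,
                             effect_logfc = 1.0, noise_sd = 0.3,
                             seed = 1L) {
  if (is.null(diseases)) {
    diseases <- tibble::tibble(
      disease = sprintf("D%02d", 1:12),
      group = rep(1:2, each = 6),
      n_cases = 15L)
  }
  diseases <- tibble::as_tibble(diseases)
  stopifnot(all(c("disease", "group", "n_cases") %in% names(diseases)),
            all(diseases$group %in% 1:2),
            n_shared + 2 * n_group <= n_pathways)
  pids <- sprintf("P%02d", seq_len(n_pathways))
  shared <- pids[seq_len(n_shared)]
  group1 <- pids[n_shared + seq_len(n_group)]
  group2 <- pids[n_shared + n_group + seq_len(n_group)]
  structure(
    list(n_pathways = n_pathways, nodes_per_pathway = nodes_per_pathway,
         genes_per_node = genes_per_node, p_edge = p_edge,
         inhibition_fraction = inhibition_fraction,
         diseases = diseases, n_controls = n_controls,
         pathway_ids = pids,
         shared_pathways = shared,
         group_pathways = list(`1` = group1, `2` = group2),
         null_pathways = setdiff(pids, c(shared, group1, group2)),
         effect_logfc = effect_logfc, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_design")
}

#' Generate random signed pathway graphs
#'
#' Each pathway is a random DAG built by sampling edges between
#' topologically ordered nodes with probability `p_edge` (so the result
#' is acyclic by construction); each edge is an inhibition with
#' probability `inhibition_fraction`. Every node carries its own unique
#' gene identifiers, so planted expression effects can be targeted at
#' whole pathways.
#'
#' @param design A [synthetic_design()].
#' @return Named list of [pathway_graph()] objects.
#' @export
generate_pathways <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  withr::with_seed(design$seed, {
    lapply(stats::setNames(design$pathway_ids, design$pathway_ids),
           function(pid) {
      n <- design$nodes_per_pathway
      nodes <- sprintf("N%02d", seq_len(n))
      from <- to <- character(0)
      if (n >= 2L) {
        for (i in seq_len(n - 1L)) {
          tgt <- which(stats::runif(n - i) < design$p_edge) + i
          from <- c(from, rep(nodes[i], length(tgt)))
          to <- c(to, nodes[tgt])
        }
      }
      sign <- ifelse(
        stats::runif(length(from)) < design$inhibition_fraction,
        "inhibition", "activation")
      ng <- tibble::tibble(
        node = rep(nodes, each = design$genes_per_node),
        gene = sprintf("g_%s_%s_%d", pid,
                       rep(nodes, each = design$genes_per_node),
                       rep(seq_len(design$genes_per_node), times = n)))
      pathway_graph(tibble::tibble(from = from, to = to, sign = sign),
                    node_genes = ng, pathway_id = pid, nodes = nodes)
    })
  })
}

#' Generate per-disease case/control expression datasets
#'
#' One dataset per disease: gene baselines are drawn per dataset from
#' Normal(8, 1) on the log2 scale (emulating cross-platform baseline
#' heterogeneity, which control-relative fold changes must remove);
#' case samples of a disease add `effect_logfc` to all genes of its
#' planted pathways (the shared block plus its group's block); i.i.d.
#' Normal(0, noise_sd) noise is added everywhere; controls are
#' unperturbed.
#'
#' @param design A [synthetic_design()].
#' @param pathways Output of [generate_pathways()] for the same design.
#' @return Named list (per disease) of lists with elements `expr`
#'   (tibble: `gene` + sample columns, log2 scale), `labels` (tibble:
#'   `sample`, `label`), `disease`, `group`.
#' @export
generate_expression <- function(design, pathways) {
  stopifnot(inherits(design, "synthetic_design"))
  all_genes <- sort(unique(unlist(
    lapply(pathways, function(g) g$node_genes$gene), use.names = FALSE)))
  genes_of <- function(pids) {
    unique(unlist(lapply(pathways[pids], function(g) g$node_genes$gene),
                  use.names = FALSE))
  }
  withr::with_seed(design$seed + 1L, {
    out <- lapply(seq_len(nrow(design$diseases)), function(i) {
      d <- design$diseases$disease[i]
      grp <- design$diseases$group[i]
      n_cases <- design$diseases$n_cases[i]
      n_ctrl <- design$n_controls
      perturbed <- genes_of(c(design$shared_pathways,
                              design$group_pathways[[as.character(grp)]]))
      baseline <- stats::rnorm(length(all_genes), mean = 8, sd = 1)
      n_samp <- n_cases + n_ctrl
      x <- matrix(baseline, length(all_genes), n_samp) +
        matrix(stats::rnorm(length(all_genes) * n_samp,
                            sd = design$noise_sd),
               length(all_genes), n_samp)
      hit <- all_genes %in% perturbed
      if (n_cases > 0L && any(hit)) {
        x[hit, seq_len(n_cases)] <- x[hit, seq_len(n_cases)] +
          design$effect_logfc
      }
      samples <- c(sprintf("%s_case%02d", d, seq_len(n_cases)),
                   sprintf("%s_ctrl%02d", d, seq_len(n_ctrl)))
      colnames(x) <- samples
      expr <- dplyr::bind_cols(tibble::tibble(gene = all_genes),
                               tibble::as_tibble(x))
      list(expr = expr,
           labels = tibble::tibble(
             sample = samples,
             label = rep(c("case", "control"), c(n_cases, n_ctrl))),
           disease = d, group = grp)
    })
    stats::setNames(out, design$diseases$disease)
  })
}

#' Canonical synthetic benchmark
#'
#' The benchmark the package's end-to-end properties are assessed on:
#' 12 diseases in two groups of 6; 20 pathways of 12 nodes with 3 genes
#' per node (4 planted up in all diseases, 4 per group, 8 null); 15
#' cases and 15 controls per dataset; planted effect 1.0 log2 units with
#' noise s.d. 0.3. Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [synthetic_design()].
#' @return List with elements `design`, `pathways`, `datasets` and
#'   `truth` (per-disease perturbed pathways and planted group labels).
#' @export
benchmark_suite <- function(seed = 1L, ...) {
  design <- synthetic_design(seed = seed, ...)
  pathways <- generate_pathways(design)
  datasets <- generate_expression(design, pathways)
  truth <- list(
    groups = stats::setNames(design$diseases$group,
                             design$diseases$disease),
    perturbed = lapply(
      stats::setNames(seq_len(nrow(design$diseases)),
                      design$diseases$disease),
      function(i) {
        grp <- design$diseases$group[i]
        c(design$shared_pathways,
          design$group_pathways[[as.character(grp)]])
      }),
    shared_pathways = design$shared_pathways,
    group_pathways = design$group_pathways,
    null_pathways = design$null_pathways)
  list(design = design, pathways = pathways, datasets = datasets,
       truth = truth)
}
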