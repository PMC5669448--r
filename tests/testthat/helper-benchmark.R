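# benchmark pipeline settings used by the end-to-end tests: 16x16 grid,
# detection percentile 75, minimum spot size 3, call threshold 0.25
benchmark_run <- function(seed, out_dir = NULL) {
  bench <- benchmark_suite(seed = seed)
  res <- run_pipeline(pipeline_config(
    bench$pathways, bench$datasets, out_dir = out_dir, seed = seed,
    som_rows = 16, som_cols = 16, percentile = 75, min_size = 3,
    call_threshold = 0.25, write_sample_portraits = FALSE))
  list(bench = bench, res = res)
}

# the 20-seed benchmark collection is shared by several test blocks;
# computed once on first use
.bench_cache <- new.env(parent = emptyenv())
benchmark_runs <- function(seeds = 1:20) {
  key <- paste(seeds, collapse = ",")
  if (is.null(.bench_cache[[key]])) {
    .bench_cache[[key]] <- lapply(seeds, benchmark_run)
  }
  .bench_cache[[key]]
}

# does the walktrap partition equal the planted two-group split?
matches_planted_groups <- function(communities, groups) {
  com <- communities$community[match(names(groups), communities$disease)]
  length(unique(com)) == 2L &&
    all(tapply(com, groups, function(x) length(unique(x)) == 1L))
}

# classify pathways of a benchmark by their planted role
pathway_category <- function(pids, truth) {
  vapply(pids, function(p) {
    if (p %in% truth$shared_pathways) "shared"
    else if (p %in% truth$group_pathways[["1"]]) "group1"
    else if (p %in% truth$group_pathways[["2"]]) "group2"
    else "null"
  }, character(1))
}
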