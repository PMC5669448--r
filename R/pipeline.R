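#' Configure a full portrait-and-similarity pipeline run
#'
#' Bundles every tunable parameter of the pipeline in one object. All
#' parameters not fixed by the modelling choices (grid size, detection
#' percentile, minimum spot size, call threshold, aggregation rules,
#' walktrap length, enrichment cutoffs) are surfaced here; the seed is
#' mandatory so that repeated runs are byte-identical.
#'
#' @param pathways A named list of [pathway_graph()] objects, or a
#'   character vector `c(edges = ..., genes = ...)` of plain-graph TSV
#'   paths (see [read_pathway_collection()]).
#' @param datasets A named list of datasets (each a list with `expr`,
#'   `labels`, `disease` as produced by [generate_expression()]), or a
#'   data frame with columns `disease`, `expr_path`, `labels_path`.
#' @param gene_sets Optional GMT path or [read_gmt()] tibble for spot
#'   enrichment.
#' @param out_dir Output directory, or `NULL` to run in memory only.
#' @param seed Integer seed (controls SOM training).
#' @param gene_agg,agg Aggregation rules of [assign_node_values()] and
#'   [propagate()].
#' @param log2_input Are the expression matrices log2-scale?
#' @param som_rows,som_cols SOM grid size.
#' @param percentile,min_size,include_interpolated,split_profiles Spot
#'   detection parameters ([detect_spots()]).
#' @param call_threshold Spot call threshold ([spot_call()]).
#' @param sign_aware Sign-aware spot sharing ([shared_spot_count()]).
#' @param walktrap_steps Walk length for [detect_communities()].
#' @param min_set,alpha Enrichment parameters ([enrich()]).
#' @param write_sample_portraits Also write one TSV per sample portrait?
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(pathways, datasets, gene_sets = NULL,
                            out_dir = NULL, seed = 1L,
                            gene_agg = "geometric", agg = "mean",
                            log2_input = TRUE,
                            som_rows = 35, som_cols = 35,
                            percentile = 98, min_size = 3,
                            include_interpolated = TRUE,
                            split_profiles = TRUE,
                            call_threshold = 0.25, sign_aware = TRUE,
                            walktrap_steps = 4, min_set = 5, alpha = 0.05,
                            write_sample_portraits = TRUE) {
  structure(
    list(pathways = pathways, datasets = datasets, gene_sets = gene_sets,
         out_dir = out_dir, seed = as.integer(seed), gene_agg = gene_agg,
         agg = agg, log2_input = log2_input, som_rows = som_rows,
         som_cols = som_cols, percentile = percentile,
         min_size = min_size,
         include_interpolated = include_interpolated,
         split_profiles = split_profiles,
         call_threshold = call_threshold,
         sign_aware = sign_aware, walktrap_steps = walktrap_steps,
         min_set = min_set, alpha = alpha,
         write_sample_portraits = write_sample_portraits),
    class = "pipeline_config")
}

.portrait_tsv <- function(portrait, path) {
  readr::write_tsv(tibble::as_tibble(portrait), path)
}

#' Run the full pipeline
#'
#' Executes, in order: fold-change computation per dataset, pathway
#' signal flow for every case sample, SOM training, per-sample and
#' per-disease portraits, summary-map spot detection, per-disease spot
#' calls, the spot-sharing similarity graph with walktrap communities,
#' and (when gene sets are supplied) per-spot overrepresentation
#' analysis. With an `out_dir`, every stage's result is written
#' (TSV/GraphML/JSON) together with a manifest carrying the seed and a
#' configuration hash; re-running an identical configuration reproduces
#' identical outputs. A stage failure aborts with the stage name, leaving
#' partial outputs plus a `FAILED` marker file.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly when writing) a list with elements `fold_changes`,
#'   `psf`, `som`, `sample_portraits`, `disease_portraits`, `spot_map`,
#'   `spot_calls`, `similarity`, `communities`, `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  writing <- !is.null(out_dir)
  if (writing) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (writing) {
        writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      }
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  pathways <- stage("load_pathways", {
    if (is.character(config$pathways)) {
      read_pathway_collection(config$pathways[["edges"]],
                              config$pathways[["genes"]])
    } else config$pathways
  })
  datasets <- stage("load_datasets", {
    ds <- config$datasets
    if (is.data.frame(ds)) {
      ds <- lapply(seq_len(nrow(ds)), function(i) {
        list(expr = read_expression(ds$expr_path[i]),
             labels = read_labels(ds$labels_path[i]),
             disease = ds$disease[i])
      })
      names(ds) <- config$datasets$disease
    }
    ds
  })

  fcs <- stage("fold_changes", {
    lapply(datasets, function(d) {
      fold_changes(d$expr, d$labels, log2_input = config$log2_input)
    })
  })
  if (writing) {
    dir.create(file.path(out_dir, "fc"), showWarnings = FALSE)
    for (nm in names(fcs)) {
      readr::write_tsv(fcs[[nm]], file.path(out_dir, "fc",
                                            paste0(nm, ".tsv")))
    }
  }

  psf <- stage("psf", {
    per_ds <- lapply(fcs, psf_scores, pathways = pathways,
                     gene_agg = config$gene_agg, agg = config$agg)
    combined <- per_ds[[1L]][, c("pathway_id", "sink", "sink_id")]
    for (p in per_ds) {
      stopifnot(identical(p$sink_id, combined$sink_id))
      combined <- dplyr::bind_cols(
        combined, p[, setdiff(names(p),
                              c("pathway_id", "sink", "sink_id"))])
    }
    combined
  })
  if (writing) readr::write_tsv(psf, file.path(out_dir, "psf_matrix.tsv"))

  som <- stage("som", {
    train_som(psf, rows = config$som_rows, cols = config$som_cols,
              seed = config$seed)
  })
  if (writing) {
    readr::write_tsv(tidy(som), file.path(out_dir, "som_assignment.tsv"))
  }

  sample_to_disease <- unlist(unname(lapply(datasets, function(d) {
    cases <- d$labels$sample[d$labels$label == "case"]
    stats::setNames(rep(d$disease, length(cases)), cases)
  })))

  sportraits <- stage("sample_portraits", {
    smps <- som$samples
    stats::setNames(lapply(smps, function(s) sample_portrait(som, psf, s)),
                    smps)
  })
  dportraits <- stage("disease_portraits", {
    diseases <- unique(unname(sample_to_disease))
    stats::setNames(lapply(diseases, function(d) {
      smps <- names(sample_to_disease)[sample_to_disease == d]
      disease_portrait(sportraits[smps], owner = d)
    }), diseases)
  })
  if (writing) {
    dir.create(file.path(out_dir, "portraits"), showWarnings = FALSE)
    if (isTRUE(config$write_sample_portraits)) {
      for (nm in names(sportraits)) {
        .portrait_tsv(sportraits[[nm]],
                      file.path(out_dir, "portraits",
                                paste0("sample_", nm, ".tsv")))
      }
    }
    for (nm in names(dportraits)) {
      .portrait_tsv(dportraits[[nm]],
                    file.path(out_dir, "portraits",
                              paste0("disease_", nm, ".tsv")))
    }
  }

  spot_map <- stage("spots", {
    detect_spots(dportraits, percentile = config$percentile,
                 min_size = config$min_size,
                 include_interpolated = config$include_interpolated,
                 split_profiles = config$split_profiles)
  })
  calls <- stage("spot_calls", {
    spot_calls(dportraits, spot_map,
               call_threshold = config$call_threshold)
  })
  if (writing) {
    sm <- lapply(split(spot_map$spots, spot_map$spots$label), function(s) {
      list(label = s$label[1L], polarity = s$polarity[1L],
           units = s$unit, row = s$row, col = s$col)
    })
    jsonlite::write_json(
      list(spots = unname(sm), up_threshold = spot_map$up_threshold,
           down_threshold = spot_map$down_threshold,
           rows = spot_map$rows, cols = spot_map$cols,
           percentile = spot_map$percentile,
           min_size = spot_map$min_size),
      file.path(out_dir, "spot_map.json"), auto_unbox = TRUE, digits = NA)
    readr::write_tsv(calls, file.path(out_dir, "spot_calls.tsv"))
  }

  similarity <- stage("similarity", {
    build_similarity_graph(calls, sign_aware = config$sign_aware)
  })
  communities <- stage("communities", {
    detect_communities(similarity, steps = config$walktrap_steps)
  })
  if (writing) {
    write_disease_graph(similarity,
                        edges_path = file.path(out_dir,
                                               "similarity_edges.tsv"))
    igraph::write_graph(similarity$graph,
                        file.path(out_dir, "similarity.graphml"),
                        format = "graphml")
    readr::write_tsv(communities, file.path(out_dir, "communities.tsv"))
  }

  enrichment <- NULL
  if (!is.null(config$gene_sets)) {
    enrichment <- stage("enrichment", {
      gs <- config$gene_sets
      if (is.character(gs)) gs <- read_gmt(gs)
      universe <- unique(unlist(
        lapply(pathways, function(g) g$node_genes$gene),
        use.names = FALSE))
      labels <- unique(spot_map$spots$label)
      stats::setNames(lapply(labels, function(lb) {
        enrich(spot_gene_set(spot_map, lb, som, pathways), gs,
               universe = universe, min_set = config$min_set,
               alpha = config$alpha)
      }), labels)
    })
    if (writing && length(enrichment) > 0L) {
      dir.create(file.path(out_dir, "enrichment"), showWarnings = FALSE)
      for (nm in names(enrichment)) {
        readr::write_tsv(enrichment[[nm]],
                         file.path(out_dir, "enrichment",
                                   paste0("spot_", nm, ".tsv")))
      }
    }
  }

  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_pathways = length(pathways),
    n_sinks = nrow(psf),
    n_samples = length(som$samples),
    n_spots = length(unique(spot_map$spots$label)),
    n_communities = length(unique(communities$community)))
  if (writing) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  res <- list(fold_changes = fcs, psf = psf, som = som,
              sample_portraits = sportraits,
              disease_portraits = dportraits, spot_map = spot_map,
              spot_calls = calls, similarity = similarity,
              communities = communities, enrichment = enrichment,
              manifest = manifest)
  if (writing) invisible(res) else res
}
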