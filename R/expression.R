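#' Collapse probe-level expression to gene level
#'
#' Probes mapping to the same gene are averaged per sample (arithmetic
#' mean on the stored scale); probes without a gene mapping are dropped.
#' Each retained probe must map to exactly one gene.
#'
#' @param probe_df Data frame whose first column holds probe ids and
#'   whose remaining columns are numeric sample values.
#' @param probe_map Data frame with columns `probe`, `gene`.
#' @return Tibble with first column `gene` and one column per sample.
#' @examples
#' probes <- data.frame(probe = c("p1", "p2"), s1 = c(4, 6))
#' average_probes(probes, data.frame(probe = c("p1", "p2"), gene = "G"))
#' @export
average_probes <- function(probe_df, probe_map) {
  probe_df <- tibble::as_tibble(probe_df)
  probe_map <- tibble::as_tibble(probe_map)
  stopifnot(all(c("probe", "gene") %in% names(probe_map)))
  probe_map <- dplyr::distinct(probe_map, .data$probe, .data$gene)
  if (nrow(probe_map) == 0L) stop("probe-to-gene mapping is empty",
                                  call. = FALSE)
  multi <- probe_map$probe[duplicated(probe_map$probe)]
  if (length(multi) > 0L) {
    stop("probe(s) mapped to more than one gene: ",
         paste(utils::head(unique(multi), 5), collapse = ", "),
         call. = FALSE)
  }
  id_col <- names(probe_df)[1L]
  out <- probe_df |>
    dplyr::rename(probe = dplyr::all_of(id_col)) |>
    dplyr::mutate(probe = as.character(.data$probe)) |>
    dplyr::inner_join(probe_map, by = "probe") |>
    dplyr::select(-"probe") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean),
                     .groups = "drop") |>
    dplyr::arrange(.data$gene)
  if (nrow(out) == 0L) stop("no probe matched the mapping", call. = FALSE)
  out
}

#' Linear fold changes of cases against the within-dataset control mean
#'
#' For each gene the mean log2 expression over the dataset's control
#' samples is the reference; each case sample's log fold change is
#' anti-logged to the linear scale: `FC = 2^(x_case - mean(x_controls))`.
#' Control columns are excluded from the output. Values of 1 mean
#' "unchanged versus controls".
#'
#' @param expr_df Data frame whose first column holds gene ids and whose
#'   remaining columns are per-sample expression values.
#' @param labels Data frame with columns `sample`, `label` where `label`
#'   is `"case"` or `"control"`.
#' @param log2_input Is `expr_df` on the log2 scale (the default, as for
#'   RMA output)? If `FALSE`, linear intensities are floored at
#'   `intensity_floor` and log2-transformed first (MAS5-style input).
#' @param intensity_floor Positive floor applied to linear intensities
#'   before the log transform (only used when `log2_input = FALSE`).
#' @return Tibble with first column `gene` and one column of strictly
#'   positive linear fold changes per case sample.
#' @export
fold_changes <- function(expr_df, labels, log2_input = TRUE,
                         intensity_floor = 1) {
  expr_df <- tibble::as_tibble(expr_df)
  labels <- tibble::as_tibble(labels)
  stopifnot(all(c("sample", "label") %in% names(labels)))
  bad <- setdiff(unique(labels$label), c("case", "control"))
  if (length(bad) > 0L) stop("labels must be 'case' or 'control'",
                             call. = FALSE)
  id_col <- names(expr_df)[1L]
  samples <- setdiff(names(expr_df), id_col)
  labels <- labels[labels$sample %in% samples, ]
  controls <- labels$sample[labels$label == "control"]
  cases <- labels$sample[labels$label == "case"]
  if (length(controls) == 0L) {
    stop("dataset has no control samples", call. = FALSE)
  }
  if (length(cases) == 0L) stop("dataset has no case samples", call. = FALSE)
  x <- as.matrix(expr_df[, c(controls, cases)])
  if (!log2_input) {
    stopifnot(intensity_floor > 0)
    x <- log2(pmax(x, intensity_floor))
  }
  ctrl_mean <- rowMeans(x[, controls, drop = FALSE])
  fc <- 2^(x[, cases, drop = FALSE] - ctrl_mean)
  out <- tibble::as_tibble(fc)
  out <- dplyr::bind_cols(
    tibble::tibble(gene = as.character(expr_df[[id_col]])), out)
  out
}

#' Read an expression or fold-change matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene (or
#' probe) identifiers.
#'
#' @param path TSV file path.
#' @return Tibble; first column named `gene`.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()))
  names(x)[1L] <- "gene"
  x
}

#' Read case/control sample labels from a two-column TSV
#'
#' @param path TSV with columns `sample` and `label` (`case`/`control`).
#' @return Tibble with columns `sample`, `label`.
#' @export
read_labels <- function(path) {
  readr::read_tsv(path, col_types = "cc")
}
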