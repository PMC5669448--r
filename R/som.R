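#' Train a self-organizing map on sink-wise activity profiles
#'
#' Aggregates pathway sinks with correlated PSF profiles into meta-sinks
#' arranged on a 2-D grid, so that correlated sinks land on nearby units.
#' Activities are log2-transformed before training (0 = unchanged, up and
#' down symmetric). Training is the classic online Kohonen procedure with
#' a Gaussian neighborhood in two phases: an ordering phase in which the
#' learning rate and neighborhood radius decay linearly from their
#' initial values down to 1, followed by a fine-tuning phase at radius 1
#' with a small decaying rate. Unit weights are initialized from randomly
#' drawn sink profiles with slight jitter; the whole procedure is
#' deterministic given `seed`.
#'
#' @param psf_df Activity tibble from [psf_scores()] (columns
#'   `pathway_id`, `sink`, `sink_id`, then one column per sample).
#' @param rows,cols Grid dimensions; `rows * cols >= 4` is required.
#' @param seed Integer seed controlling initialization and presentation
#'   order (mandatory for reproducible maps).
#' @param epochs Passes over the sink set per phase.
#' @param alpha Length-2 learning-rate bounds for the ordering phase; the
#'   fine-tuning phase decays from `alpha[2]` to `alpha[2]/10`.
#' @param radius Initial neighborhood radius (Gaussian sigma, in grid
#'   units); default `max(rows, cols) / 2`.
#' @return An object of class `psf_som`: unit weights, the sink-to-unit
#'   assignment (best-matching, i.e. minimum Euclidean distance, unit per
#'   sink), grid geometry and training parameters. Use [tidy()] for the
#'   assignment table and [glance()] for a one-row model summary.
#' @export
train_som <- function(psf_df, rows = 35, cols = 35, seed = 1L,
                      epochs = 10L, alpha = c(0.1, 0.01), radius = NULL) {
  if (rows * cols < 4L) stop("SOM grid must have at least 2x2 units",
                             call. = FALSE)
  x <- log2(.psf_as_matrix(psf_df))
  n <- nrow(x)
  d <- ncol(x)
  if (n < 1L) stop("no sinks to train on", call. = FALSE)
  nu <- as.integer(rows * cols)
  gr <- rep(seq_len(rows), each = cols) # unit -> grid row
  gc <- rep(seq_len(cols), times = rows) # unit -> grid col
  if (is.null(radius)) radius <- max(rows, cols) / 2

  w <- withr::with_seed(as.integer(seed), {
    init <- x[sample.int(n, nu, replace = TRUE), , drop = FALSE] +
      matrix(stats::rnorm(nu * d, sd = 0.01), nu, d)
    # presentation schedule: a fresh permutation per epoch, both phases
    sched1 <- as.vector(replicate(epochs, sample.int(n)))
    sched2 <- as.vector(replicate(epochs, sample.int(n)))
    steps1 <- length(sched1)
    steps2 <- length(sched2)
    train_phase <- function(w, sched, a0, a1, r0, r1) {
      steps <- length(sched)
      for (t in seq_len(steps)) {
        frac <- if (steps > 1L) (t - 1) / (steps - 1) else 0
        a <- a0 + frac * (a1 - a0)
        r <- r0 + frac * (r1 - r0)
        xi <- x[sched[t], ]
        bmu <- which.min(rowSums(sweep(w, 2, xi)^2))
        d2 <- (gr - gr[bmu])^2 + (gc - gc[bmu])^2
        h <- a * exp(-d2 / (2 * r^2))
        w <- w + h * (matrix(xi, nu, d, byrow = TRUE) - w)
      }
      w
    }
    init <- train_phase(init, sched1, alpha[1], alpha[2], radius, 1)
    train_phase(init, sched2, alpha[2], alpha[2] / 10, 1, 1)
  })

  assign_unit <- .bmu(w, x)
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         unit_weights = w, unit_row = gr, unit_col = gc,
         sinks = tibble::tibble(
           pathway_id = psf_df$pathway_id, sink = psf_df$sink,
           sink_id = psf_df$sink_id, unit = assign_unit,
           row = gr[assign_unit], col = gc[assign_unit]),
         samples = colnames(x), seed = as.integer(seed),
         params = list(epochs = epochs, alpha = alpha, radius = radius)),
    class = "psf_som")
}

# best-matching unit per row of x
.bmu <- function(w, x) {
  # squared distances via ||w||^2 - 2 w x' (the ||x||^2 term is constant per sink)
  cross <- w %*% t(x)
  d2 <- rowSums(w^2) - 2 * cross
  apply(d2, 2, which.min)
}

#' @export
print.psf_som <- function(x, ...) {
  cat(sprintf("<psf_som> %dx%d grid, %d sinks over %d samples (seed %d)\n",
              x$rows, x$cols, nrow(x$sinks), length(x$samples), x$seed))
  cat(sprintf("  occupied units: %d / %d\n",
              length(unique(x$sinks$unit)), x$rows * x$cols))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname train_som
#' @param x A `psf_som` object.
#' @param ... Unused.
#' @export
tidy.psf_som <- function(x, ...) x$sinks

#' @rdname train_som
#' @export
glance.psf_som <- function(x, ...) {
  tibble::tibble(
    rows = x$rows, cols = x$cols, n_sinks = nrow(x$sinks),
    n_samples = length(x$samples),
    n_occupied = length(unique(x$sinks$unit)), seed = x$seed)
}

#' Per-sample and per-disease portraits
#'
#' A portrait maps one owner (a sample, or a disease after averaging) onto
#' the trained grid: each unit's value is the mean log2 activity of the
#' sinks assigned to it. Units with no assigned sinks are filled by
#' nearest-neighbor interpolation from the closest occupied unit (ties
#' broken by the lowest unit index) and flagged `interpolated` so the
#' synthetic values can be excluded from exact summaries. The weighted
#' mean of non-interpolated unit values, weighted by `n_sinks`, equals
#' the owner's overall mean log2 activity (conservation).
#'
#' @param som A [train_som()] model.
#' @param psf_df The activity tibble the portraits are computed from
#'   (same sinks as the model was trained on).
#' @param sample Sample id (a value column of `psf_df`).
#' @return A `psf_portrait`: tibble with columns `unit`, `row`, `col`,
#'   `value`, `n_sinks`, `interpolated`, with attributes `owner`, `rows`,
#'   `cols`.
#' @export
sample_portrait <- function(som, psf_df, sample) {
  stopifnot(inherits(som, "psf_som"))
  if (!sample %in% names(psf_df)) {
    stop("sample '", sample, "' not found in activity table", call. = FALSE)
  }
  key <- match(som$sinks$sink_id, psf_df$sink_id)
  if (anyNA(key)) stop("activity table is missing sinks the map was trained on",
                       call. = FALSE)
  vals <- log2(psf_df[[sample]][key])
  nu <- som$rows * som$cols
  unit_of <- som$sinks$unit
  sums <- tapply(vals, factor(unit_of, levels = seq_len(nu)), sum)
  counts <- tabulate(unit_of, nbins = nu)
  value <- ifelse(counts > 0, as.numeric(sums) / pmax(counts, 1L), NA_real_)
  interpolated <- counts == 0L
  if (any(interpolated) && any(!interpolated)) {
    occ <- which(!interpolated)
    for (u in which(interpolated)) {
      d2 <- (som$unit_row[occ] - som$unit_row[u])^2 +
        (som$unit_col[occ] - som$unit_col[u])^2
      value[u] <- value[occ[which.min(d2)]]
    }
  }
  out <- tibble::tibble(
    unit = seq_len(nu), row = som$unit_row, col = som$unit_col,
    value = value, n_sinks = counts, interpolated = interpolated)
  attr(out, "owner") <- sample
  attr(out, "rows") <- som$rows
  attr(out, "cols") <- som$cols
  class(out) <- c("psf_portrait", class(out))
  out
}

#' Average sample portraits into a disease portrait
#'
#' Element-wise mean of the case-sample portraits of one disease; the
#' grid, sink counts and interpolation flags are shared by construction.
#'
#' @param portraits List of [sample_portrait()] results on the same grid.
#' @param owner Identifier for the averaged portrait (e.g. disease id).
#' @return A `psf_portrait` tibble.
#' @export
disease_portrait <- function(portraits, owner = "disease") {
  stopifnot(length(portraits) > 0L)
  base <- portraits[[1L]]
  vals <- rowMeans(vapply(portraits, function(p) p$value,
                          numeric(nrow(base))))
  out <- base
  out$value <- vals
  attr(out, "owner") <- owner
  out
}

#' @export
print.psf_portrait <- function(x, ...) {
  cat(sprintf("<psf_portrait> %s: %dx%d grid, value range [%.3f, %.3f]\n",
              attr(x, "owner"), attr(x, "rows"), attr(x, "cols"),
              min(x$value), max(x$value)))
  invisible(x)
}
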