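#' Detect co-regulated spots on the summary map
#'
#' Individual disease portraits are combined into a global summary map:
#' the element-wise maximum across portraits on the up side and the
#' element-wise minimum on the down side, so that a spot present in any
#' single disease survives summarization. The up-threshold is the given
#' percentile of the summary-up values; the down-threshold is the
#' symmetric (100 - percentile) percentile of the summary-down values.
#' Units beyond a threshold are grouped into 8-connected components;
#' components with at least `min_size` units become spots, labelled
#' `A`, `B`, `C`, ... in decreasing size (ties: up before down, then the
#' smallest unit index). Detecting no spot is a valid (empty) result.
#'
#' @param portraits List of disease portraits ([disease_portrait()]) on a
#'   common grid.
#' @param percentile Detection percentile, strictly between 50 and 100.
#' @param min_size Minimum number of units per spot.
#' @param include_interpolated Also let interpolation-filled (empty)
#'   units form spots (default `TRUE`)? With `FALSE`, only units with
#'   assigned sinks are eligible; this avoids interpolated values
#'   bridging separate regions on very sparse grids, at the price of
#'   fragmenting spots whose member sinks do not tile contiguously.
#' @param split_profiles Split connected components by their
#'   cross-disease activation profile (default `TRUE`)? A spot is a
#'   cluster of *co-regulated* units; two abutting regions that are both
#'   extreme on the summary map but extreme in different disease subsets
#'   are not co-regulated, and the max/min summary alone cannot separate
#'   them (there is no valley between equally high neighbours). Each
#'   unit is profiled by which diseases push it past half the detection
#'   threshold, and components are re-partitioned into 8-connected runs
#'   of equal profile.
#' @return A `spot_map`: list with `spots` (tibble `label`, `polarity`,
#'   `unit`, `row`, `col`), `up_threshold`, `down_threshold`, grid
#'   geometry and the parameters used.
#' @export
detect_spots <- function(portraits, percentile = 98, min_size = 3,
                         include_interpolated = TRUE,
                         split_profiles = TRUE) {
  stopifnot(length(portraits) > 0L)
  if (percentile <= 50 || percentile >= 100) {
    stop("percentile must be strictly between 50 and 100", call. = FALSE)
  }
  rows <- as.integer(attr(portraits[[1L]], "rows"))
  cols <- as.integer(attr(portraits[[1L]], "cols"))
  vals <- vapply(portraits, function(p) p$value,
                 numeric(rows * cols))
  vals <- matrix(vals, nrow = rows * cols)
  eligible <- if (include_interpolated ||
                    is.null(portraits[[1L]]$interpolated)) {
    rep(TRUE, rows * cols)
  } else {
    !portraits[[1L]]$interpolated
  }
  up <- apply(vals, 1, max)
  down <- apply(vals, 1, min)
  up_thr <- stats::quantile(up[eligible], percentile / 100, names = FALSE)
  down_thr <- stats::quantile(down[eligible], 1 - percentile / 100,
                              names = FALSE)

  comp_tbl <- function(units, polarity, thr) {
    comps <- .grid_components(units, rows, cols)
    if (split_profiles && length(portraits) > 0L) {
      # profile = which diseases push the unit past half the threshold
      hit <- if (polarity == "up") vals > thr / 2 else vals < thr / 2
      key <- apply(hit, 1, function(b) paste(as.integer(b), collapse = ""))
      comps <- unlist(lapply(comps, function(u) {
        unlist(lapply(split(u, key[u]), .grid_components,
                      rows = rows, cols = cols),
               recursive = FALSE, use.names = FALSE)
      }), recursive = FALSE, use.names = FALSE)
    }
    comps <- comps[lengths(comps) >= min_size]
    purrr::map(comps, function(u) {
      tibble::tibble(polarity = polarity, unit = as.integer(sort(u)))
    })
  }
  parts <- c(comp_tbl(which(up > up_thr & eligible), "up", up_thr),
             comp_tbl(which(down < down_thr & eligible), "down", down_thr))
  if (length(parts) > 0L) {
    ord <- order(-vapply(parts, nrow, integer(1)),
                 vapply(parts, function(p) p$polarity[1] == "down",
                        logical(1)),
                 vapply(parts, function(p) min(p$unit), integer(1)))
    parts <- parts[ord]
    spots <- dplyr::bind_rows(
      purrr::imap(parts, function(p, i) {
        p$label <- .spot_label(i)
        p
      }))
    spots <- dplyr::mutate(spots,
                           row = (spots$unit - 1L) %/% cols + 1L,
                           col = (spots$unit - 1L) %% cols + 1L)
    spots <- spots[, c("label", "polarity", "unit", "row", "col")]
  } else {
    spots <- tibble::tibble(label = character(), polarity = character(),
                            unit = integer(), row = integer(),
                            col = integer())
  }
  structure(
    list(spots = spots, up_threshold = up_thr, down_threshold = down_thr,
         rows = rows, cols = cols, percentile = percentile,
         min_size = min_size),
    class = "spot_map")
}

# A..Z then AA, AB, ...
.spot_label <- function(i) {
  if (i <= 26L) return(LETTERS[i])
  paste0(LETTERS[(i - 1L) %/% 26L], LETTERS[(i - 1L) %% 26L + 1L])
}

# 8-connected components of a unit set on a rows x cols grid;
# unit index u maps to row (u-1) %/% cols + 1, col (u-1) %% cols + 1
.grid_components <- function(units, rows, cols) {
  if (length(units) == 0L) return(list())
  in_set <- logical(rows * cols)
  in_set[units] <- TRUE
  seen <- logical(rows * cols)
  comps <- list()
  for (u in sort(units)) {
    if (seen[u]) next
    comp <- integer(0)
    frontier <- u
    seen[u] <- TRUE
    while (length(frontier) > 0L) {
      comp <- c(comp, frontier)
      nxt <- integer(0)
      for (v in frontier) {
        r <- (v - 1L) %/% cols + 1L
        cc <- (v - 1L) %% cols + 1L
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0L && dc == 0L) next
          nr <- r + dr
          nc <- cc + dc
          if (nr < 1L || nr > rows || nc < 1L || nc > cols) next
          w <- (nr - 1L) * cols + nc
          if (in_set[w] && !seen[w]) {
            seen[w] <- TRUE
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    comps <- c(comps, list(sort(comp)))
  }
  comps
}

#' @export
print.spot_map <- function(x, ...) {
  n_up <- length(unique(x$spots$label[x$spots$polarity == "up"]))
  n_down <- length(unique(x$spots$label[x$spots$polarity == "down"]))
  cat(sprintf(
    "<spot_map> %dx%d grid: %d up / %d down spot(s) at percentile %g\n",
    x$rows, x$cols, n_up, n_down, x$percentile))
  if (nrow(x$spots) > 0L) {
    sizes <- dplyr::count(x$spots, .data$label, .data$polarity)
    for (i in seq_len(nrow(sizes))) {
      cat(sprintf("  %s (%s): %d units\n", sizes$label[i],
                  sizes$polarity[i], sizes$n[i]))
    }
  }
  invisible(x)
}

#' @export
tidy.spot_map <- function(x, ...) x$spots

#' Call a spot up, down or unchanged in one portrait
#'
#' The call is based on the mean portrait value over the spot's units:
#' above `+call_threshold` gives `"+"`, below `-call_threshold` gives
#' `"-"`, otherwise `"0"`.
#'
#' @param portrait A [sample_portrait()]/[disease_portrait()] result.
#' @param spot_units Integer unit indices of one spot.
#' @param call_threshold Positive threshold on mean log2 activity.
#' @return `"+"`, `"-"` or `"0"`.
#' @export
spot_call <- function(portrait, spot_units, call_threshold = 0.25) {
  stopifnot(call_threshold > 0, length(spot_units) > 0L)
  m <- mean(portrait$value[spot_units])
  if (m > call_threshold) "+" else if (m < -call_threshold) "-" else "0"
}

#' Per-disease calls for every detected spot
#'
#' @param portraits Named list of disease portraits.
#' @param spot_map A [detect_spots()] result.
#' @inheritParams spot_call
#' @return Tibble with columns `disease`, `spot`, `call` — the +/−/0
#'   profile matrix underlying spot-sharing similarity.
#' @export
spot_calls <- function(portraits, spot_map, call_threshold = 0.25) {
  stopifnot(inherits(spot_map, "spot_map"))
  labels <- unique(spot_map$spots$label)
  owners <- names(portraits)
  if (is.null(owners)) {
    owners <- vapply(portraits, function(p) attr(p, "owner"), character(1))
  }
  tidyr::expand_grid(disease = owners, spot = labels) |>
    dplyr::mutate(call = purrr::map2_chr(
      .data$disease, .data$spot, function(d, s) {
        units <- spot_map$spots$unit[spot_map$spots$label == s]
        spot_call(portraits[[match(d, owners)]], units, call_threshold)
      }))
}
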