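#' Build per-axis directional histograms for one sensor window
#'
#' Bins the arcsine-transformed values of each axis into `n_bins` equal-width
#' bins spanning `bin_range`. All histograms share the transform's full range
#' by default so that histograms from different windows, users and devices
#' are directly comparable. Bins are half-open `[lo, hi)` except the last,
#' which is closed so the upper range boundary is counted.
#'
#' @param signal A [transform_window()] result (`directional_signal`).
#' @param n_bins Number of bins per axis (>= 2). Default 20, roughly a sixth
#'   of the 125 readings in a 5-s window at 25 Hz.
#' @param bin_range Length-2 numeric interval covering all signal values.
#'   Default: the transform's full range `1 + c(-pi/2, pi/2)`.
#'
#' @return A `gait_histogram` tibble with columns `bin`, `lo`, `hi` and
#'   per-axis integer counts `x`, `y`, `z`; attributes `sensor_kind`,
#'   `n_bins`, `bin_range`.
#' @examples
#' w <- sensor_window(data.frame(x = rnorm(125), y = rnorm(125),
#'                               z = rnorm(125) + 9.81), "accelerometer", 25)
#' h <- build_histogram(transform_window(w), n_bins = 20)
#' colSums(h[, c("x", "y", "z")])  # each equals the retained sample count
#' @export
build_histogram <- function(signal, n_bins = 20L,
                            bin_range = transform_range()) {
  if (!inherits(signal, "directional_signal")) {
    abort("`signal` must be a directional_signal (see transform_window()).")
  }
  if (nrow(signal) == 0L) abort("cannot histogram an empty signal.")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) abort("`n_bins` must be an integer >= 2.")
  if (length(bin_range) != 2L || !all(is.finite(bin_range)) ||
      bin_range[2L] <= bin_range[1L]) {
    abort("`bin_range` must be a finite interval c(lo, hi) with lo < hi.")
  }
  lo <- bin_range[1L]; hi <- bin_range[2L]
  width <- (hi - lo) / n_bins
  edges <- lo + width * (0:n_bins)
  bin_axis <- function(v) {
    if (any(v < lo | v > hi)) {
      abort(sprintf(
        "signal value outside bin_range [%g, %g]: histogram range is misconfigured.",
        lo, hi))
    }
    idx <- floor((v - lo) / width) + 1
    idx[idx > n_bins] <- n_bins  # closed last bin
    tabulate(idx, nbins = n_bins)
  }
  out <- tibble::tibble(bin = seq_len(n_bins),
                        lo = edges[seq_len(n_bins)],
                        hi = edges[seq_len(n_bins) + 1L],
                        x = bin_axis(signal$x),
                        y = bin_axis(signal$y),
                        z = bin_axis(signal$z))
  structure(out,
            class = c("gait_histogram", class(out)),
            sensor_kind = attr(signal, "sensor_kind"),
            n_bins = n_bins,
            bin_range = c(lo, hi))
}

#' @export
print.gait_histogram <- function(x, ...) {
  cat(sprintf("<gait_histogram: %s, %d bins on [%.4f, %.4f], %d values/axis>\n",
              attr(x, "sensor_kind"), attr(x, "n_bins"),
              attr(x, "bin_range")[1L], attr(x, "bin_range")[2L],
              sum(x$x)))
  NextMethod()
}

check_compatible <- function(a, b) {
  if (!inherits(a, "gait_histogram") || !inherits(b, "gait_histogram")) {
    abort("both arguments must be gait_histogram objects.")
  }
  if (!identical(attr(a, "sensor_kind"), attr(b, "sensor_kind"))) {
    abort("incompatible histograms: different sensor kinds.")
  }
  if (!identical(attr(a, "n_bins"), attr(b, "n_bins")) ||
      !isTRUE(all.equal(attr(a, "bin_range"), attr(b, "bin_range")))) {
    abort("incompatible histograms: different binning.")
  }
  invisible(TRUE)
}

#' Histogram intersection similarity between two gait histograms
#'
#' For each axis, the intersection of a query histogram \eqn{H_1} with a
#' reference (enrolled/database) histogram \eqn{H_2} is
#' \deqn{\mathrm{similarity} = \frac{\sum_{i=1}^{n} \min(H_{1i}, H_{2i})}
#'                                  {\sum_{i=1}^{n} H_{2i}},}
#' the mass the two distributions share, normalised by the reference total.
#' The reported `value` is the mean of the three per-axis scores. The
#' formula is asymmetric in general; by convention the enrolled histogram is
#' always the denominator and the orientation is recorded in the result.
#' When the two histograms hold different numbers of retained samples, both
#' are rescaled to a common per-axis total before the formula is applied, so
#' scores stay in \[0, 1\].
#'
#' @param query The incoming (probe) `gait_histogram`.
#' @param reference The enrolled/database `gait_histogram` (denominator).
#'
#' @return A `similarity_score`: list with `value` (mean of axes),
#'   `per_axis` (named x/y/z scores) and `orientation = "reference"`.
#' @examples
#' w <- sensor_window(data.frame(x = rnorm(50), y = rnorm(50), z = rnorm(50)),
#'                    "accelerometer", 25)
#' h <- build_histogram(transform_window(w))
#' intersection_similarity(h, h)$value  # 1
#' @export
intersection_similarity <- function(query, reference) {
  check_compatible(query, reference)
  q <- as.matrix(query[, c("x", "y", "z")])
  r <- as.matrix(reference[, c("x", "y", "z")])
  qt <- colSums(q); rt <- colSums(r)
  if (any(rt <= 0)) abort("reference histogram has a zero-total axis.")
  if (!all(qt == rt)) {
    # differing retained lengths: rescale both to a common (unit) total
    q <- sweep(q, 2L, qt, "/")
    r <- sweep(r, 2L, rt, "/")
    rt <- c(x = 1, y = 1, z = 1)
  }
  per_axis <- colSums(pmin(q, r)) / rt
  names(per_axis) <- c("x", "y", "z")
  structure(list(value = mean(per_axis),
                 per_axis = per_axis,
                 orientation = "reference"),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("<similarity_score: %.4f (x %.4f, y %.4f, z %.4f)>\n",
              x$value, x$per_axis[["x"]], x$per_axis[["y"]],
              x$per_axis[["z"]]))
  invisible(x)
}

score_value <- function(s) {
  if (inherits(s, "similarity_score")) s$value
  else if (is.numeric(s) && length(s) == 1L) s
  else abort("expected a similarity_score or a single number.")
}

#' Fuse accelerometer and gyroscope similarity scores
#'
#' Combines the two per-sensor similarity scores into one, by default their
#' plain average. A weight pair of `c(1, 0)` degenerates to
#' accelerometer-only matching.
#'
#' @param accel_score,gyro_score Similarity scores in \[0, 1\]
#'   (`similarity_score` objects or bare numbers).
#' @param weights Two non-negative weights summing to 1. Default
#'   `c(0.5, 0.5)`.
#'
#' @return The fused score, a number in \[0, 1\].
#' @examples
#' fuse_scores(0.8, 0.6)           # 0.7
#' fuse_scores(0.9, 0.3, c(1, 0))  # 0.9
#' @export
fuse_scores <- function(accel_score, gyro_score, weights = c(0.5, 0.5)) {
  a <- score_value(accel_score); g <- score_value(gyro_score)
  if (length(weights) != 2L || any(!is.finite(weights)) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-12) {
    abort("`weights` must be two non-negative numbers summing to 1.")
  }
  if (a < -1e-12 || a > 1 + 1e-12 || g < -1e-12 || g > 1 + 1e-12) {
    abort("similarity scores must lie in [0, 1].")
  }
  weights[1L] * a + weights[2L] * g
}

#' Serialise a gait histogram to a JSON record
#'
#' Writes sensor kind, bin edges and per-axis counts as a single JSON
#' object, the plain-text form used when persisting enrolment data.
#'
#' @param hist A `gait_histogram`.
#' @return A JSON string.
#' @seealso [histogram_from_json()]
#' @export
histogram_to_json <- function(hist) {
  if (!inherits(hist, "gait_histogram")) abort("`hist` must be a gait_histogram.")
  rec <- list(sensor_kind = attr(hist, "sensor_kind"),
              n_bins = attr(hist, "n_bins"),
              bin_range = attr(hist, "bin_range"),
              counts = list(x = hist$x, y = hist$y, z = hist$z))
  as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
}

#' Rebuild a gait histogram from its JSON record
#' @param json A string produced by [histogram_to_json()].
#' @return A `gait_histogram`.
#' @export
histogram_from_json <- function(json) {
  rec <- jsonlite::fromJSON(json)
  n_bins <- as.integer(rec$n_bins)
  lo <- rec$bin_range[1L]; hi <- rec$bin_range[2L]
  width <- (hi - lo) / n_bins
  edges <- lo + width * (0:n_bins)
  out <- tibble::tibble(bin = seq_len(n_bins),
                        lo = edges[seq_len(n_bins)],
                        hi = edges[seq_len(n_bins) + 1L],
                        x = as.integer(rec$counts$x),
                        y = as.integer(rec$counts$y),
                        z = as.integer(rec$counts$z))
  structure(out,
            class = c("gait_histogram", class(out)),
            sensor_kind = rec$sensor_kind,
            n_bins = n_bins,
            bin_range = c(lo, hi))
}

# --- internal vectorised scoring -------------------------------------------
# Gallery-scale scoring flattens each histogram to a length-3B vector with
# every axis block normalised to unit mass; the per-axis intersection is then
# a plain sum of element-wise minima, and the fused score a mean over axes.

hist_vec <- function(h) {
  m <- cbind(h$x, h$y, h$z)
  tot <- colSums(m)
  if (any(tot <= 0)) abort("histogram has a zero-total axis.")
  as.vector(sweep(m, 2L, tot, "/"))
}

# rows of Q and R are hist_vec() vectors; returns nq x nr matrix of
# per-sensor similarity (mean over the three axis blocks)
cross_similarity <- function(Q, R, n_bins) {
  nq <- nrow(Q); nr <- nrow(R)
  out <- matrix(0, nq, nr)
  for (i in seq_len(nq)) {
    qm <- matrix(Q[i, ], nr, ncol(Q), byrow = TRUE)
    mins <- pmin(qm, R)
    ax <- vapply(1:3, function(a) {
      cols <- ((a - 1L) * n_bins + 1L):(a * n_bins)
      rowSums(mins[, cols, drop = FALSE])
    }, numeric(nr))
    out[i, ] <- rowMeans(matrix(ax, nr, 3L))
  }
  out
}
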