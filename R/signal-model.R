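#' @importFrom rlang abort warn .data
#' @importFrom stats median rnorm runif setNames
#' @importFrom utils head tail
NULL

SENSOR_KINDS <- c("accelerometer", "gyroscope")

# Full range of the directional transform 1 + arcsin(component / magnitude).
transform_range <- function() c(1 - pi / 2, 1 + pi / 2)

#' Construct a tri-axial sensor window
#'
#' A sensor window is a fixed-duration block of tri-axial readings from one
#' motion sensor: acceleration in m/s^2 (gravity included, as calibrated
#' Android sensors report it) or angular speed in rad/s. It is stored as a
#' tibble with columns `t` (seconds from window start), `x`, `y`, `z`, and
#' carries the sensor kind, sample rate and duration as attributes.
#'
#' @param samples A data frame with numeric columns `x`, `y`, `z` (a `t`
#'   column is kept if present, otherwise generated from the sample rate).
#' @param sensor_kind `"accelerometer"` or `"gyroscope"`.
#' @param sample_rate_hz Positive sampling rate in Hz.
#' @param duration_s Window duration in seconds; defaults to
#'   `nrow(samples) / sample_rate_hz`.
#'
#' @return A `sensor_window` tibble.
#' @examples
#' w <- sensor_window(data.frame(x = 0, y = 0, z = 9.81),
#'                    "accelerometer", sample_rate_hz = 25)
#' @export
sensor_window <- function(samples, sensor_kind, sample_rate_hz,
                          duration_s = NULL) {
  sensor_kind <- match.arg(sensor_kind, SENSOR_KINDS)
  if (!is.data.frame(samples) || !all(c("x", "y", "z") %in% names(samples))) {
    abort("`samples` must be a data frame with columns x, y, z.")
  }
  if (nrow(samples) < 1L) abort("a sensor window needs at least one sample.")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    abort("`sample_rate_hz` must be a positive number.")
  }
  xyz <- as.matrix(samples[, c("x", "y", "z")])
  if (!is.numeric(xyz) || any(!is.finite(xyz))) {
    abort("sensor readings must all be finite numbers.")
  }
  if (is.null(duration_s)) duration_s <- nrow(samples) / sample_rate_hz
  if (duration_s <= 0) abort("`duration_s` must be positive.")
  t <- if ("t" %in% names(samples)) samples[["t"]] else
    (seq_len(nrow(samples)) - 1L) / sample_rate_hz
  out <- tibble::tibble(t = as.double(t),
                        x = as.double(samples$x),
                        y = as.double(samples$y),
                        z = as.double(samples$z))
  structure(out,
            class = c("sensor_window", class(out)),
            sensor_kind = sensor_kind,
            sample_rate_hz = as.double(sample_rate_hz),
            duration_s = as.double(duration_s))
}

#' @export
print.sensor_window <- function(x, ...) {
  cat(sprintf("<sensor_window: %s, %d samples @ %g Hz, %g s>\n",
              attr(x, "sensor_kind"), nrow(x),
              attr(x, "sample_rate_hz"), attr(x, "duration_s")))
  NextMethod()
}

#' Sensor kind of a window, signal or histogram
#' @param x A `sensor_window`, `directional_signal` or `gait_histogram`.
#' @return `"accelerometer"` or `"gyroscope"`.
#' @export
sensor_kind <- function(x) attr(x, "sensor_kind")

#' Directional (arcsine) transform of a sensor window
#'
#' Encodes each tri-axial reading by its direction only: for a sample
#' \eqn{(x_i, y_i, z_i)} with magnitude \eqn{m_i = \sqrt{x_i^2+y_i^2+z_i^2}},
#' the value kept for the OX axis is \eqn{X_i = 1 + \arcsin(x_i / m_i)}
#' (and likewise for OY, OZ). The arcsine smooths the ratio and the +1 shift
#' makes every value positive, so all outputs lie in
#' \eqn{[1 - \pi/2,\; 1 + \pi/2]}. The transform is invariant to positive
#' rescaling of the input, which makes the downstream histograms insensitive
#' to sensor units and overall signal energy.
#'
#' Samples whose magnitude falls below `magnitude_epsilon` have no defined
#' direction; they are dropped and counted in the `dropped_count` attribute
#' rather than assigned an arbitrary value.
#'
#' @param window A [sensor_window()].
#' @param magnitude_epsilon Positive threshold below which a sample's
#'   magnitude is treated as zero. Default `1e-9`.
#'
#' @return A `directional_signal` tibble with columns `x`, `y`, `z` of
#'   transformed values and attributes `sensor_kind` and `dropped_count`.
#' @examples
#' w <- sensor_window(data.frame(x = 0, y = 0, z = 9.81),
#'                    "accelerometer", 25)
#' transform_window(w)  # OZ value is 1 + pi/2
#' @export
transform_window <- function(window, magnitude_epsilon = 1e-9) {
  if (!inherits(window, "sensor_window")) {
    abort("`window` must be a sensor_window.")
  }
  if (!is.numeric(magnitude_epsilon) || magnitude_epsilon <= 0) {
    abort("`magnitude_epsilon` must be a small positive number.")
  }
  xyz <- cbind(window$x, window$y, window$z)
  m <- sqrt(rowSums(xyz^2))
  keep <- m >= magnitude_epsilon
  dropped <- sum(!keep)
  if (!any(keep)) {
    abort("empty transformed signal: every sample has near-zero magnitude.")
  }
  # ratios are in [-1, 1] by construction; clamp away rounding overshoot
  ratio <- xyz[keep, , drop = FALSE] / m[keep]
  ratio[ratio > 1] <- 1
  ratio[ratio < -1] <- -1
  v <- 1 + asin(ratio)
  out <- tibble::tibble(x = v[, 1L], y = v[, 2L], z = v[, 3L])
  structure(out,
            class = c("directional_signal", class(out)),
            sensor_kind = attr(window, "sensor_kind"),
            dropped_count = dropped)
}

#' @export
print.directional_signal <- function(x, ...) {
  cat(sprintf("<directional_signal: %s, %d values, %d dropped>\n",
              attr(x, "sensor_kind"), nrow(x), attr(x, "dropped_count")))
  NextMethod()
}

#' Number of samples dropped by the directional transform
#' @param signal A `directional_signal`.
#' @return Non-negative integer count of near-zero-magnitude samples removed.
#' @export
dropped_count <- function(signal) attr(signal, "dropped_count")
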