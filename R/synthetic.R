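GRAVITY_MS2 <- 9.81

# Per-placement device pose and signal attenuation. Left-side placements
# mirror the lateral (x) axis of the right-side pose, which reproduces the
# left/right co-clustering seen when histograms ignore sign conventions
# only partially (the intersection keeps axis identity but mirrored limbs
# share most of their direction distribution).
PLACEMENT_EFFECTS <- list(
  torso = list(euler = c(0, 0, 0), mirror_x = FALSE, amp_scale = 0.7),
  right_arm = list(euler = c(0.5, 0.3, 0.2), mirror_x = FALSE, amp_scale = 0.9),
  left_arm = list(euler = c(0.5, 0.3, 0.2), mirror_x = TRUE, amp_scale = 0.9),
  right_leg = list(euler = c(0.2, -0.4, 0.1), mirror_x = FALSE, amp_scale = 1),
  left_leg = list(euler = c(0.2, -0.4, 0.1), mirror_x = TRUE, amp_scale = 1))

euler_rotation <- function(euler) {
  cr <- cos(euler[1L]); sr <- sin(euler[1L])
  cp <- cos(euler[2L]); sp <- sin(euler[2L])
  cy <- cos(euler[3L]); sy <- sin(euler[3L])
  Rx <- matrix(c(1, 0, 0, 0, cr, sr, 0, -sr, cr), 3L, 3L)
  Ry <- matrix(c(cp, 0, -sp, 0, 1, 0, sp, 0, cp), 3L, 3L)
  Rz <- matrix(c(cy, sy, 0, -sy, cy, 0, 0, 0, 1), 3L, 3L)
  Rz %*% Ry %*% Rx
}

#' Define a synthetic walker's gait profile
#'
#' The generator models a walker's tri-axial signals as a truncated Fourier
#' series on the step frequency — the simplest signal with the repetitive
#' structure that makes walking recognisable to the histogram method. What
#' distinguishes users is the *direction* content of their motion: per-axis
#' amplitudes and phase offsets (body build and arm/leg swing), harmonic
#' mix (gait smoothness), and the device pose. Gravity rides on one axis of
#' the accelerometer, as calibrated phone sensors report it, and additive
#' Gaussian noise models sensor and soft-tissue jitter.
#'
#' @param user_id Identifier.
#' @param step_frequency_hz Step rate; normal walking is roughly
#'   1.4-2.5 Hz.
#' @param accel_amplitudes Per-axis (x, y, z) acceleration amplitudes in
#'   m/s^2.
#' @param gyro_amplitudes Per-axis angular-speed amplitudes in rad/s.
#' @param harmonic_weights Relative weights of harmonics 1..H of the step
#'   frequency.
#' @param phase_offsets Per-axis phase in radians.
#' @param gravity_axis Axis carrying the +9.81 m/s^2 offset; default "z".
#' @param noise_sd Named Gaussian noise standard deviations,
#'   `c(accel = ..., gyro = ...)`.
#' @param orientation Device pose as three Euler angles (roll, pitch, yaw)
#'   applied to both sensors.
#'
#' @return A `gait_profile` list.
#' @export
gait_profile <- function(user_id,
                         step_frequency_hz = 1.9,
                         accel_amplitudes = c(1.2, 2.5, 3.5),
                         gyro_amplitudes = c(0.8, 0.5, 1.2),
                         harmonic_weights = c(1, 0.5, 0.25),
                         phase_offsets = c(0, pi / 3, 2 * pi / 3),
                         gravity_axis = c("z", "x", "y"),
                         noise_sd = c(accel = 0.6, gyro = 0.12),
                         orientation = c(0, 0, 0)) {
  gravity_axis <- match.arg(gravity_axis)
  stopifnot(length(accel_amplitudes) == 3L, length(gyro_amplitudes) == 3L,
            length(phase_offsets) == 3L, length(orientation) == 3L)
  if (step_frequency_hz <= 0) abort("`step_frequency_hz` must be positive.")
  if (any(accel_amplitudes < 0) || any(gyro_amplitudes < 0) ||
      any(noise_sd < 0)) {
    abort("amplitudes and noise standard deviations must be non-negative.")
  }
  if (any(!is.finite(harmonic_weights))) {
    abort("`harmonic_weights` must be finite.")
  }
  structure(list(user_id = as.character(user_id),
                 step_frequency_hz = step_frequency_hz,
                 accel_amplitudes = accel_amplitudes,
                 gyro_amplitudes = gyro_amplitudes,
                 harmonic_weights = harmonic_weights,
                 phase_offsets = phase_offsets,
                 gravity_axis = gravity_axis,
                 noise_sd = noise_sd,
                 orientation = orientation),
            class = "gait_profile")
}

fourier_signal <- function(t, f, amps, weights, phases, phase_lead = 0) {
  out <- matrix(0, length(t), 3L)
  for (a in 1:3) {
    s <- 0
    for (h in seq_along(weights)) {
      s <- s + weights[h] * sin(2 * pi * h * f * t + phases[a] + phase_lead)
    }
    out[, a] <- amps[a] * s
  }
  out
}

#' Generate one accelerometer + gyroscope window from a profile
#'
#' Synthesises `duration_s * rate_hz` samples: the Fourier gait signal plus
#' a gravity offset (accelerometer only), rotated by the profile's device
#' orientation, with the gyroscope leading the accelerometer by a quarter
#' phase (angular speed leads displacement-like signals), and Gaussian
#' noise added in the device frame. Deterministic given `seed`.
#'
#' @param profile A [gait_profile()].
#' @param duration_s Window length in seconds; default 5.
#' @param rate_hz Sampling rate; default 25.
#' @param seed Integer seed; when `NULL` the current RNG stream is used.
#' @param mirror_x Negate the lateral axis (left-limb placements).
#'
#' @return A list with elements `accel` and `gyro`, both [sensor_window()]s.
#' @export
generate_window <- function(profile, duration_s = 5, rate_hz = 25,
                            seed = NULL, mirror_x = FALSE) {
  if (!inherits(profile, "gait_profile")) {
    abort("`profile` must be a gait_profile.")
  }
  if (duration_s <= 0 || rate_hz <= 0) {
    abort("`duration_s` and `rate_hz` must be positive.")
  }
  gen <- function() {
    n <- round(rate_hz * duration_s)
    t <- (seq_len(n) - 1L) / rate_hz
    Rm <- euler_rotation(profile$orientation)
    grav <- c(x = 0, y = 0, z = 0)
    grav[profile$gravity_axis] <- GRAVITY_MS2
    acc <- fourier_signal(t, profile$step_frequency_hz,
                          profile$accel_amplitudes,
                          profile$harmonic_weights, profile$phase_offsets)
    acc <- sweep(acc, 2L, grav, "+") %*% t(Rm)
    gyr <- fourier_signal(t, profile$step_frequency_hz,
                          profile$gyro_amplitudes,
                          profile$harmonic_weights, profile$phase_offsets,
                          phase_lead = pi / 2) %*% t(Rm)
    if (profile$noise_sd[["accel"]] > 0) {
      acc <- acc + matrix(rnorm(3L * n, sd = profile$noise_sd[["accel"]]), n, 3L)
    }
    if (profile$noise_sd[["gyro"]] > 0) {
      gyr <- gyr + matrix(rnorm(3L * n, sd = profile$noise_sd[["gyro"]]), n, 3L)
    }
    if (mirror_x) {
      acc[, 1L] <- -acc[, 1L]
      gyr[, 1L] <- -gyr[, 1L]
    }
    list(accel = sensor_window(
           tibble::tibble(t = t, x = acc[, 1L], y = acc[, 2L], z = acc[, 3L]),
           "accelerometer", rate_hz, duration_s),
         gyro = sensor_window(
           tibble::tibble(t = t, x = gyr[, 1L], y = gyr[, 2L], z = gyr[, 3L]),
           "gyroscope", rate_hz, duration_s))
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

#' Cohort specification for the synthetic generator
#'
#' Defaults reproduce the shape of the reference recordings the recogniser
#' was evaluated on: eight subjects with sixty 5-s samples each at 25 Hz.
#'
#' @param n_users Number of walkers; default 8.
#' @param samples_per_user Windows per walker (per placement); default 60.
#' @param duration_s Window length; default 5 s.
#' @param rate_hz Sampling rate; default 25 Hz.
#' @param placements Device placements to simulate; default `"right_leg"`
#'   (phone in the trouser pocket).
#' @param separation Non-negative scalar scaling between-user profile
#'   differences; 0 collapses all users onto one profile (the recogniser's
#'   worst case), 1 spreads step frequency, amplitudes and phases over
#'   their normal inter-person ranges.
#' @param jitter Scalar scaling the within-user sample-to-sample
#'   perturbation of frequency, phase and amplitude; default 1.
#' @param noise_sd Sensor noise standard deviations as in [gait_profile()].
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_users = 8L, samples_per_user = 60L,
                        duration_s = 5, rate_hz = 25,
                        placements = "right_leg",
                        separation = 1, jitter = 1,
                        noise_sd = c(accel = 0.6, gyro = 0.12),
                        seed = 1L) {
  placements <- match.arg(placements, PLACEMENTS, several.ok = TRUE)
  n_users <- as.integer(n_users); samples_per_user <- as.integer(samples_per_user)
  if (is.na(n_users) || n_users < 1L) abort("`n_users` must be >= 1.")
  if (is.na(samples_per_user) || samples_per_user < 1L) {
    abort("`samples_per_user` must be >= 1.")
  }
  if (separation < 0 || jitter < 0) {
    abort("`separation` and `jitter` must be non-negative.")
  }
  structure(list(n_users = n_users, samples_per_user = samples_per_user,
                 duration_s = duration_s, rate_hz = rate_hz,
                 placements = placements, separation = separation,
                 jitter = jitter, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a labelled synthetic cohort
#'
#' Draws one base [gait_profile()] per user — step frequency spread across
#' the walking range and per-axis amplitudes, phases, harmonic mix and
#' device tilt perturbed around population means, all scaled by
#' `separation` — then synthesises each sample with small per-sample
#' jitter (frequency, phase, amplitude) and fresh sensor noise. When
#' several placements are requested, each sample is rendered at every
#' placement with that placement's pose offset (left-side placements
#' mirror the lateral axis). Fully reproducible from the spec's seed.
#'
#' @param spec A [cohort_spec()] (or arguments forwarded to it).
#' @param ... Arguments passed to [cohort_spec()] when `spec` is missing.
#' @return A windows tibble: `user_id`, `sample_id`, `activity`,
#'   `placement`, and list-columns `accel`, `gyro`.
#' @examples
#' ds <- generate_cohort(cohort_spec(n_users = 2, samples_per_user = 4,
#'                                   seed = 7))
#' @export
generate_cohort <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- cohort_spec(...)
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec.")
  withr::with_seed(spec$seed, {
    nu <- spec$n_users
    sep <- spec$separation
    spread <- if (nu == 1L) 0 else seq(-1, 1, length.out = nu)
    base_freq <- 1.95 + 0.55 * sep * spread
    profiles <- vector("list", nu)
    for (u in seq_len(nu)) {
      profiles[[u]] <- gait_profile(
        user_id = sprintf("u%02d", u),
        step_frequency_hz = max(base_freq[u], 0.5),
        accel_amplitudes = c(1.2, 2.5, 3.5) * (1 + sep * runif(3, -0.35, 0.35)),
        gyro_amplitudes = c(0.8, 0.5, 1.2) * (1 + sep * runif(3, -0.35, 0.35)),
        harmonic_weights = c(1, 0.5, 0.25) * (1 + sep * runif(3, -0.3, 0.3)),
        phase_offsets = c(0, pi / 3, 2 * pi / 3) + sep * runif(3, -pi / 2, pi / 2),
        noise_sd = spec$noise_sd,
        orientation = sep * runif(3, -0.15, 0.15))
    }
    rows <- list()
    for (u in seq_len(nu)) {
      bp <- profiles[[u]]
      for (s in seq_len(spec$samples_per_user)) {
        # per-sample jitter: same walker, a different walk
        jp <- bp
        jp$step_frequency_hz <- bp$step_frequency_hz *
          (1 + spec$jitter * rnorm(1, sd = 0.02))
        jp$phase_offsets <- bp$phase_offsets +
          spec$jitter * rnorm(3, sd = 0.05)
        jp$accel_amplitudes <- bp$accel_amplitudes *
          (1 + spec$jitter * rnorm(3, sd = 0.05))
        jp$gyro_amplitudes <- bp$gyro_amplitudes *
          (1 + spec$jitter * rnorm(3, sd = 0.05))
        for (pl in spec$placements) {
          eff <- PLACEMENT_EFFECTS[[pl]]
          pp <- jp
          pp$orientation <- jp$orientation + eff$euler
          pp$accel_amplitudes <- jp$accel_amplitudes * eff$amp_scale
          pp$gyro_amplitudes <- jp$gyro_amplitudes * eff$amp_scale
          w <- generate_window(pp, spec$duration_s, spec$rate_hz,
                               seed = NULL, mirror_x = eff$mirror_x)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            user_id = bp$user_id, sample_id = s, activity = "walking",
            placement = pl, accel = list(w$accel), gyro = list(w$gyro))
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}
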