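RECOGNITION_MODES <- c("fused", "accel_only", "gyro_only")

#' Build a histogram gallery from a window dataset
#'
#' Converts each (accelerometer, gyroscope) window pair of a dataset into
#' per-axis directional histograms, yielding the gallery representation used
#' by classification, verification and clustering. Metadata columns
#' (`user_id`, `sample_id`, `activity`, `placement`, `split`) are carried
#' through.
#'
#' @param dataset A tibble with list-columns `accel` and/or `gyro` of
#'   [sensor_window()] objects, e.g. from [generate_cohort()] or the readers.
#' @param n_bins Bins per axis; default 20.
#' @param bin_range Histogram range; default the transform's full range.
#' @param magnitude_epsilon Passed to [transform_window()].
#'
#' @return A gallery tibble with list-columns `accel_hist` and/or
#'   `gyro_hist` of `gait_histogram` objects.
#' @export
build_gallery <- function(dataset, n_bins = 20L,
                          bin_range = transform_range(),
                          magnitude_epsilon = 1e-9) {
  if (!is.data.frame(dataset) || nrow(dataset) == 0L) {
    abort("`dataset` must be a non-empty data frame of sensor windows.")
  }
  has_accel <- "accel" %in% names(dataset)
  has_gyro <- "gyro" %in% names(dataset)
  if (!has_accel && !has_gyro) {
    abort("`dataset` needs an `accel` and/or `gyro` list-column of windows.")
  }
  to_hist <- function(w) {
    build_histogram(transform_window(w, magnitude_epsilon),
                    n_bins = n_bins, bin_range = bin_range)
  }
  out <- tibble::as_tibble(dataset)
  if (has_accel) {
    out$accel_hist <- purrr::map(out$accel, to_hist)
    out$accel <- NULL
  }
  if (has_gyro) {
    out$gyro_hist <- purrr::map(out$gyro, to_hist)
    out$gyro <- NULL
  }
  out
}

gallery_mode_cols <- function(gallery, mode) {
  cols <- switch(mode,
                 fused = c("accel_hist", "gyro_hist"),
                 accel_only = "accel_hist",
                 gyro_only = "gyro_hist")
  missing <- setdiff(cols, names(gallery))
  if (length(missing)) {
    abort(sprintf("gallery lacks %s required by mode '%s'.",
                  paste(missing, collapse = ", "), mode))
  }
  cols
}

# flatten a gallery's histograms into one normalised matrix per sensor
gallery_matrices <- function(gallery, mode) {
  cols <- gallery_mode_cols(gallery, mode)
  ref <- gallery[[cols[1L]]][[1L]]
  n_bins <- attr(ref, "n_bins")
  for (cl in cols) {
    for (h in gallery[[cl]]) check_compatible(h, gallery[[cl]][[1L]])
  }
  if (length(cols) == 2L) {
    a <- gallery[[cols[1L]]][[1L]]; g <- gallery[[cols[2L]]][[1L]]
    if (!identical(attr(a, "n_bins"), attr(g, "n_bins"))) {
      abort("accelerometer and gyroscope histograms use different bin counts.")
    }
  }
  mats <- lapply(cols, function(cl) {
    do.call(rbind, lapply(gallery[[cl]], hist_vec))
  })
  names(mats) <- cols
  list(mats = mats, n_bins = n_bins)
}

# nq x nr fused similarity matrix between two galleries under a mode
gallery_cross_scores <- function(query, reference, mode) {
  qm <- gallery_matrices(query, mode)
  rm_ <- gallery_matrices(reference, mode)
  if (!identical(qm$n_bins, rm_$n_bins)) {
    abort("incompatible histograms: different binning between galleries.")
  }
  per_sensor <- lapply(names(qm$mats), function(cl) {
    cross_similarity(qm$mats[[cl]], rm_$mats[[cl]], qm$n_bins)
  })
  Reduce(`+`, per_sensor) / length(per_sensor)
}

#' Classify test samples against an enrolled gallery
#'
#' Scores each test sample against every gallery sample regardless of user
#' (gallery histograms as the intersection denominator) and predicts the
#' user of the best-matching gallery sample. Ties are broken by the lowest
#' gallery index, so results are deterministic.
#'
#' @param test,gallery Gallery tibbles from [build_gallery()]; `gallery`
#'   must have a `user_id` column.
#' @param mode `"fused"` (average of accelerometer and gyroscope scores,
#'   the default), `"accel_only"` or `"gyro_only"`.
#'
#' @return A tibble with one row per test sample: `predicted_user`,
#'   `best_score`, `best_index`, plus the test's own metadata columns
#'   (`user_id` becomes `true_user` when present).
#' @export
classify_gait <- function(test, gallery, mode = c("fused", "accel_only",
                                                  "gyro_only")) {
  mode <- match.arg(mode)
  if (!is.data.frame(gallery) || nrow(gallery) == 0L) {
    abort("`gallery` must be a non-empty gallery tibble.")
  }
  if (!"user_id" %in% names(gallery)) abort("`gallery` needs a user_id column.")
  if (!is.data.frame(test) || nrow(test) == 0L) {
    abort("`test` must be a non-empty gallery tibble.")
  }
  S <- gallery_cross_scores(test, gallery, mode)
  best <- apply(S, 1L, which.max)       # which.max: lowest index on ties
  out <- tibble::tibble(
    predicted_user = as.character(gallery$user_id[best]),
    best_score = S[cbind(seq_len(nrow(S)), best)],
    best_index = as.integer(best))
  if ("user_id" %in% names(test)) {
    out <- dplyr::bind_cols(tibble::tibble(true_user = as.character(test$user_id)),
                            out)
  }
  for (cl in intersect(c("sample_id", "activity", "placement"), names(test))) {
    out[[cl]] <- test[[cl]]
  }
  out
}

#' Enrol a user: intra-set minimum score and acceptance threshold
#'
#' Scores every ordered pair of the user's trusted samples (the second
#' sample of each pair acting as the enrolled denominator), takes the
#' minimum, and multiplies it by an error factor to obtain the acceptance
#' threshold. The factor (default 0.95) concedes that genuine future
#' samples, recorded in less controlled conditions than the enrolment set,
#' may score slightly below the worst intra-set score.
#'
#' @param samples A gallery tibble of >= 2 samples from a single user.
#' @param error_factor Multiplier in (0, 1\]; default 0.95.
#' @param mode Scoring mode as in [classify_gait()].
#'
#' @return A `gait_enrolment` object: the samples plus `min_intra_score`,
#'   `error_factor` and `threshold = error_factor * min_intra_score`.
#' @export
build_enrolment <- function(samples, error_factor = 0.95,
                            mode = c("fused", "accel_only", "gyro_only")) {
  mode <- match.arg(mode)
  if (!is.data.frame(samples) || nrow(samples) < 2L) {
    abort("enrolment too small: need at least 2 samples of the user.")
  }
  if (!"user_id" %in% names(samples)) abort("`samples` needs a user_id column.")
  uid <- unique(as.character(samples$user_id))
  if (length(uid) != 1L) abort("enrolment samples must belong to one user.")
  if (!is.numeric(error_factor) || length(error_factor) != 1L ||
      error_factor <= 0 || error_factor > 1) {
    abort("`error_factor` must lie in (0, 1].")
  }
  S <- gallery_cross_scores(samples, samples, mode)
  off <- S[row(S) != col(S)]
  min_intra <- min(off)
  structure(list(user_id = uid,
                 samples = samples,
                 mode = mode,
                 n_samples = nrow(samples),
                 min_intra_score = min_intra,
                 error_factor = error_factor,
                 threshold = error_factor * min_intra),
            class = "gait_enrolment")
}

#' @export
print.gait_enrolment <- function(x, ...) {
  cat(sprintf(
    "<gait_enrolment: user %s, %d samples, mode %s>\n  min intra-score %.4f x factor %.2f -> threshold %.4f\n",
    x$user_id, x$n_samples, x$mode, x$min_intra_score, x$error_factor,
    x$threshold))
  invisible(x)
}

#' Verify claimed identities against an enrolment set
#'
#' Each test sample is scored against every sample of the claimed user's
#' enrolment set (enrolment histograms as the denominator); the attempt is
#' accepted when the average score reaches the enrolment threshold.
#'
#' @param test A gallery tibble of one or more attempt samples.
#' @param enrolment A [build_enrolment()] result.
#' @param mode Scoring mode; defaults to the enrolment's own mode.
#'
#' @return A decisions tibble: `claimed_user`, `mean_score`, `threshold`,
#'   `accepted`, `flag` (NA unless the attempt could not be scored), plus
#'   `true_user` when the test carries a `user_id`.
#' @export
verify_gait <- function(test, enrolment, mode = NULL) {
  if (!inherits(enrolment, "gait_enrolment")) {
    abort("`enrolment` must come from build_enrolment().")
  }
  if (is.null(mode)) mode <- enrolment$mode
  mode <- match.arg(mode, RECOGNITION_MODES)
  if (!is.data.frame(test) || nrow(test) == 0L) {
    abort("`test` must be a non-empty gallery tibble.")
  }
  S <- gallery_cross_scores(test, enrolment$samples, mode)
  mean_score <- rowMeans(S)
  out <- tibble::tibble(
    claimed_user = enrolment$user_id,
    mean_score = mean_score,
    threshold = enrolment$threshold,
    accepted = mean_score >= enrolment$threshold,
    flag = NA_character_)
  if ("user_id" %in% names(test)) {
    out <- dplyr::bind_cols(tibble::tibble(true_user = as.character(test$user_id)),
                            out)
  }
  out
}

#' Majority vote over several accept/reject decisions
#'
#' Aggregates per-sample decisions of one validation attempt: accepted only
#' if strictly more than half the decisions accept. An even split therefore
#' rejects — the fail-safe posture for an authentication gate (in normal
#' operation an odd number of samples, default three, is used, so ties do
#' not arise).
#'
#' @param decisions A logical vector, or a decisions tibble with an
#'   `accepted` column.
#' @return A single logical.
#' @examples
#' majority_vote(c(TRUE, TRUE, FALSE))  # TRUE
#' majority_vote(c(TRUE, FALSE))        # FALSE (tie -> reject)
#' @export
majority_vote <- function(decisions) {
  acc <- if (is.data.frame(decisions)) decisions$accepted else decisions
  if (is.null(acc) || length(acc) == 0L) {
    abort("`decisions` must contain at least one accept/reject decision.")
  }
  if (!is.logical(acc) || any(is.na(acc))) {
    abort("decisions must be non-missing logicals.")
  }
  sum(acc) > length(acc) / 2
}

#' Biometric error rates from genuine and impostor attempts
#'
#' Tallies accepted/rejected attempts into the standard verification
#' metrics: FRR (rejected genuine attempts / genuine attempts), FAR
#' (accepted impostor attempts / impostor attempts) and overall accuracy
#' (correct decisions / all attempts). With zero impostor attempts FAR is
#' undefined; it is reported as 0 with `far_undefined = TRUE` (and
#' symmetrically for FRR).
#'
#' @param genuine Decisions tibble (or logical vector of `accepted`) for
#'   genuine attempts; may be empty.
#' @param impostor Same for impostor attempts.
#'
#' @return A one-row `gait_metrics` tibble: `accuracy`, `far`, `frr`,
#'   `far_undefined`, `frr_undefined` and the four underlying tallies.
#' @export
evaluate_decisions <- function(genuine, impostor) {
  get_acc <- function(d) {
    a <- if (is.data.frame(d)) d$accepted else d
    if (is.null(a)) logical(0) else a
  }
  g <- get_acc(genuine); i <- get_acc(impostor)
  if (length(g) + length(i) == 0L) abort("no attempts to evaluate.")
  ga <- sum(g); gr <- length(g) - ga
  ia <- sum(i); ir <- length(i) - ia
  out <- tibble::tibble(
    accuracy = (ga + ir) / (length(g) + length(i)),
    far = if (length(i) > 0L) ia / length(i) else 0,
    frr = if (length(g) > 0L) gr / length(g) else 0,
    far_undefined = length(i) == 0L,
    frr_undefined = length(g) == 0L,
    genuine_accepts = as.integer(ga),
    genuine_rejects = as.integer(gr),
    impostor_accepts = as.integer(ia),
    impostor_rejects = as.integer(ir))
  class(out) <- c("gait_metrics", class(out))
  out
}

#' Classification accuracy as a function of histogram bin count
#'
#' Rebuilds every histogram at each requested bin count and measures
#' nearest-sample classification accuracy on the dataset's enrol/test
#' split. The default sweep, 10 to 40 bins in steps of 3, brackets the
#' default of 20 bins (about a sixth of the 125 readings per 5-s window
#' at 25 Hz).
#'
#' @param dataset A window dataset with a `split` column ("enrol"/"test"),
#'   e.g. [generate_cohort()] piped through [make_split()].
#' @param bin_counts Integer vector of bin counts, each >= 2.
#'   Default `seq(10, 40, by = 3)`.
#' @param mode Scoring mode as in [classify_gait()].
#'
#' @return A `bin_sweep` tibble with columns `n_bins` and `accuracy`.
#' @export
sweep_bins <- function(dataset, bin_counts = seq(10L, 40L, by = 3L),
                       mode = c("fused", "accel_only", "gyro_only")) {
  mode <- match.arg(mode)
  if (length(bin_counts) == 0L || any(bin_counts < 2L)) {
    abort("`bin_counts` must be a non-empty vector of integers >= 2.")
  }
  if (!"split" %in% names(dataset)) {
    abort("`dataset` needs a split column; see make_split().")
  }
  acc <- vapply(as.integer(bin_counts), function(nb) {
    gal <- build_gallery(dataset, n_bins = nb)
    res <- classify_gait(gal[gal$split == "test", ],
                         gal[gal$split == "enrol", ], mode = mode)
    mean(res$predicted_user == res$true_user)
  }, numeric(1L))
  out <- tibble::tibble(n_bins = as.integer(bin_counts), accuracy = acc)
  class(out) <- c("bin_sweep", class(out))
  out
}
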