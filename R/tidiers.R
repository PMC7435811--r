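#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an enrolment set into per-sample intra-set scores
#'
#' @param x A [build_enrolment()] result.
#' @param ... Unused.
#' @return A tibble with one row per enrolment sample: its mean and
#'   minimum similarity against the other samples of the set.
#' @export
tidy.gait_enrolment <- function(x, ...) {
  S <- gallery_cross_scores(x$samples, x$samples, x$mode)
  diag(S) <- NA_real_
  out <- tibble::tibble(
    user_id = x$user_id,
    sample = seq_len(nrow(S)),
    mean_intra_score = rowMeans(S, na.rm = TRUE),
    min_intra_score = apply(S, 1L, min, na.rm = TRUE))
  if ("sample_id" %in% names(x$samples)) out$sample_id <- x$samples$sample_id
  out
}

#' One-row summary of an enrolment set
#' @inheritParams tidy.gait_enrolment
#' @return A one-row tibble: user, sample count, mode, minimum intra-set
#'   score, error factor and acceptance threshold.
#' @export
glance.gait_enrolment <- function(x, ...) {
  tibble::tibble(user_id = x$user_id, n_samples = x$n_samples,
                 mode = x$mode, min_intra_score = x$min_intra_score,
                 error_factor = x$error_factor, threshold = x$threshold)
}

#' Tidy a clustering into per-sample assignments
#' @param x A [cluster_samples()] result.
#' @param ... Unused.
#' @return A tibble: `sample`, `cluster`, `is_medoid`, and `label` when
#'   placement labels are known.
#' @export
tidy.gait_clustering <- function(x, ...) {
  out <- tibble::tibble(sample = seq_len(x$n),
                        cluster = x$assignment,
                        is_medoid = seq_len(x$n) %in% x$medoid_indices)
  if (!is.null(x$labels)) out$label <- x$labels
  out
}

#' One-row summary of a clustering
#' @inheritParams tidy.gait_clustering
#' @return A one-row tibble: `k`, `n`, final objective and iteration count.
#' @export
glance.gait_clustering <- function(x, ...) {
  tibble::tibble(k = x$k, n = x$n, objective = x$objective,
                 n_iterations = length(x$objective_trace))
}

#' Tidy biometric metrics into long attempt tallies
#' @param x An [evaluate_decisions()] result.
#' @param ... Unused.
#' @return A tibble with one row per (attempt type, decision) tally.
#' @export
tidy.gait_metrics <- function(x, ...) {
  tibble::tibble(
    attempt = c("genuine", "genuine", "impostor", "impostor"),
    decision = c("accepted", "rejected", "accepted", "rejected"),
    n = c(x$genuine_accepts, x$genuine_rejects,
          x$impostor_accepts, x$impostor_rejects))
}

#' One-row summary of biometric metrics
#' @inheritParams tidy.gait_metrics
#' @return The metrics as a plain one-row tibble.
#' @export
glance.gait_metrics <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "gait_metrics")
  out
}
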