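#' Pairwise distance matrix from histogram similarity
#'
#' Distance between two gallery samples is one minus their symmetrised
#' similarity, where the symmetrised similarity is the mean of the two
#' orientations of the intersection score (each sample once as denominator).
#' Diagonal entries are exactly zero and all entries lie in \[0, 1\], giving
#' a dissimilarity suitable for medoid clustering.
#'
#' @param samples A gallery tibble of >= 2 compatible samples.
#' @param mode Scoring mode as in [classify_gait()].
#'
#' @return A `dist_matrix`: an n x n symmetric numeric matrix with a
#'   `labels` attribute holding the samples' `placement` column if present.
#' @export
similarity_distance_matrix <- function(samples,
                                       mode = c("fused", "accel_only",
                                                "gyro_only")) {
  mode <- match.arg(mode)
  if (!is.data.frame(samples) || nrow(samples) < 2L) {
    abort("need at least 2 samples to build a distance matrix.")
  }
  S <- gallery_cross_scores(samples, samples, mode)
  sym <- (S + t(S)) / 2
  D <- 1 - sym
  D[D < 0] <- 0
  diag(D) <- 0
  structure(D,
            class = c("dist_matrix", "matrix", "array"),
            labels = if ("placement" %in% names(samples))
              as.character(samples$placement) else NULL)
}

#' Cluster gait samples by k-medoids over a precomputed distance
#'
#' Partitions samples into `k` clusters under the similarity-derived
#' distance. Because that distance is not Euclidean, cluster centres are
#' medoids (actual samples) rather than means: starting from a seeded
#' random choice of `k` medoids, samples are assigned to their nearest
#' medoid and each cluster's medoid is replaced by the member minimising
#' the within-cluster distance total, alternating until the assignment is
#' stable. The best of `n_restarts` seeded starts (by total within-cluster
#' distance) is returned, so results are deterministic given the seed.
#'
#' @param dmat A [similarity_distance_matrix()] result (or any symmetric
#'   non-negative matrix with zero diagonal).
#' @param k Number of clusters, `1 <= k <= n`. Default 5, one per device
#'   placement (torso, both arms, both legs).
#' @param seed Integer seed controlling medoid initialisation.
#' @param n_restarts Number of seeded restarts; default 5.
#'
#' @return A `gait_clustering` object: `assignment` (cluster index per
#'   sample), `medoid_indices`, `objective` (total within-cluster
#'   distance), `objective_trace` (per accepted iteration of the winning
#'   restart), `k`, `labels`.
#' @export
cluster_samples <- function(dmat, k = 5L, seed = 1L, n_restarts = 5L) {
  if (!is.matrix(dmat) || nrow(dmat) != ncol(dmat)) {
    abort("`dmat` must be a square distance matrix.")
  }
  n <- nrow(dmat)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n) {
    abort(sprintf("`k` must lie in [1, %d].", n))
  }
  run_once <- function(medoids) {
    assignment <- integer(n)
    trace <- numeric(0)
    repeat {
      D <- dmat[, medoids, drop = FALSE]
      new_assign <- apply(D, 1L, which.min)      # lowest index on ties
      new_assign[medoids] <- seq_along(medoids)  # medoids stay put
      for (c_i in seq_along(medoids)) {
        members <- which(new_assign == c_i)
        if (length(members) == 0L) next
        within <- colSums(dmat[members, members, drop = FALSE])
        medoids[c_i] <- members[which.min(within)]
      }
      D <- dmat[, medoids, drop = FALSE]
      assignment_new <- apply(D, 1L, which.min)
      assignment_new[medoids] <- seq_along(medoids)
      obj <- sum(D[cbind(seq_len(n), assignment_new)])
      trace <- c(trace, obj)
      if (identical(assignment_new, assignment)) break
      assignment <- assignment_new
      if (length(trace) > n * n) break  # hard stop; never reached in practice
    }
    list(assignment = assignment, medoids = medoids,
         objective = trace[length(trace)], trace = trace)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    start <- withr::with_seed(as.integer(seed) + r - 1L,
                              sort(sample.int(n, k)))
    res <- run_once(start)
    if (is.null(best) || res$objective < best$objective - 1e-15) best <- res
  }
  structure(list(k = k,
                 assignment = best$assignment,
                 medoid_indices = best$medoids,
                 objective = best$objective,
                 objective_trace = best$trace,
                 n = n,
                 labels = attr(dmat, "labels")),
            class = "gait_clustering")
}

#' @export
print.gait_clustering <- function(x, ...) {
  cat(sprintf("<gait_clustering: %d samples in %d clusters, objective %.4f>\n",
              x$n, x$k, x$objective))
  invisible(x)
}

#' Cross-tabulate clusters against device-placement labels
#'
#' @param clustering A [cluster_samples()] result.
#' @param labels Placement labels per sample; defaults to the labels stored
#'   on the distance matrix.
#'
#' @return A tibble contingency table, one row per cluster, one column per
#'   label, whose grand total equals the number of samples.
#' @export
cluster_composition <- function(clustering, labels = NULL) {
  if (!inherits(clustering, "gait_clustering")) {
    abort("`clustering` must come from cluster_samples().")
  }
  if (is.null(labels)) labels <- clustering$labels
  if (is.null(labels)) abort("no placement labels available.")
  if (length(labels) != clustering$n) {
    abort("`labels` length does not match the clustered sample count.")
  }
  tab <- table(cluster = factor(clustering$assignment,
                                levels = seq_len(clustering$k)),
               label = labels)
  out <- tibble::as_tibble(as.data.frame.matrix(tab))
  dplyr::bind_cols(tibble::tibble(cluster = seq_len(clustering$k)), out)
}

#' Verification routed through placement clusters
#'
#' Mixed device placements dilute an enrolment set: a probe recorded on the
#' leg scores poorly against torso enrolment samples even for the genuine
#' user. Cluster routing addresses this by assigning the probe to the
#' cluster of its nearest medoid and verifying only against the claimed
#' user's enrolment samples inside that cluster, so thresholds and scores
#' are computed among like-placed samples. If the claimed user has fewer
#' than two samples in the routed cluster, the attempt is rejected with a
#' `"no enrolment in cluster"` flag.
#'
#' @param test A gallery tibble of attempt samples.
#' @param gallery The enrolment gallery over which `clustering` was built
#'   (row order must match the distance matrix).
#' @param clustering A [cluster_samples()] result over `gallery`.
#' @param claimed_user The identity being claimed.
#' @param error_factor Threshold factor for the per-cluster enrolment.
#' @param mode Scoring mode.
#'
#' @return A decisions tibble as from [verify_gait()], with an added
#'   `cluster` column; unroutable attempts carry `accepted = FALSE` and a
#'   flag.
#' @export
clustered_verify <- function(test, gallery, clustering, claimed_user,
                             error_factor = 0.95,
                             mode = c("fused", "accel_only", "gyro_only")) {
  mode <- match.arg(mode)
  if (!inherits(clustering, "gait_clustering")) {
    abort("`clustering` must come from cluster_samples().")
  }
  if (clustering$n != nrow(gallery)) {
    abort("`clustering` was not built over this gallery.")
  }
  medoid_gal <- gallery[clustering$medoid_indices, , drop = FALSE]
  S <- gallery_cross_scores(test, medoid_gal, mode)
  sym <- S  # probe-vs-medoid similarity; nearest medoid = max similarity
  routed <- apply(sym, 1L, which.max)
  res <- vector("list", nrow(test))
  for (i in seq_len(nrow(test))) {
    cl <- routed[i]
    in_cluster <- which(clustering$assignment == cl &
                          as.character(gallery$user_id) == as.character(claimed_user))
    ti <- test[i, , drop = FALSE]
    if (length(in_cluster) < 2L) {
      row <- tibble::tibble(claimed_user = as.character(claimed_user),
                            mean_score = NA_real_, threshold = NA_real_,
                            accepted = FALSE,
                            flag = "no enrolment in cluster")
      if ("user_id" %in% names(ti)) {
        row <- dplyr::bind_cols(tibble::tibble(true_user = as.character(ti$user_id)),
                                row)
      }
    } else {
      enr <- build_enrolment(gallery[in_cluster, , drop = FALSE],
                             error_factor = error_factor, mode = mode)
      row <- verify_gait(ti, enr, mode = mode)
    }
    row$cluster <- as.integer(cl)
    res[[i]] <- row
  }
  dplyr::bind_rows(res)
}
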