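# Independent oracles and fixture builders used across the suite.

# Naive per-bin double loop for the intersection similarity: sum of minima
# over bins divided by the reference total, averaged over the three axes.
# Kept deliberately loop-based and separate from the package's vectorised path.
naive_intersection <- function(query, reference) {
  per_axis <- numeric(3)
  axes <- c("x", "y", "z")
  for (a in 1:3) {
    q <- query[[axes[a]]]; r <- reference[[axes[a]]]
    s <- 0
    for (i in seq_along(q)) s <- s + min(q[i], r[i])
    per_axis[a] <- s / sum(r)
  }
  mean(per_axis)
}

# Adjusted Rand index straight from the contingency table (Hubert & Arabie),
# independent of any clustering package.
ari_contingency <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(as.vector(tab))
  row_c <- sum_comb(rowSums(tab)); col_c <- sum_comb(colSums(tab))
  expected <- row_c * col_c / choose(n, 2)
  max_idx <- (row_c + col_c) / 2
  if (max_idx == expected) return(1)
  (idx - expected) / (max_idx - expected)
}

# Build a gait_histogram directly from count vectors (bypasses the binning
# path so histogram tests can use arbitrary planted counts).
make_hist <- function(x, y, z, sensor = "accelerometer",
                      bin_range = 1 + c(-pi / 2, pi / 2)) {
  n_bins <- length(x)
  stopifnot(length(y) == n_bins, length(z) == n_bins)
  width <- diff(bin_range) / n_bins
  edges <- bin_range[1] + width * (0:n_bins)
  out <- tibble::tibble(bin = seq_len(n_bins),
                        lo = edges[seq_len(n_bins)],
                        hi = edges[-1],
                        x = as.integer(x), y = as.integer(y),
                        z = as.integer(z))
  structure(out, class = c("gait_histogram", class(out)),
            sensor_kind = sensor, n_bins = as.integer(n_bins),
            bin_range = bin_range)
}

# Random histogram with a fixed per-axis total (equal-total comparisons).
rand_hist <- function(n_bins, total, sensor = "accelerometer") {
  draw <- function() as.integer(stats::rmultinom(1, total, runif(n_bins)))
  make_hist(draw(), draw(), draw(), sensor = sensor)
}

# A tiny gallery tibble from planted accelerometer/gyroscope histograms.
make_gallery <- function(user_ids, accel_hists, gyro_hists = NULL) {
  out <- tibble::tibble(user_id = user_ids, accel_hist = accel_hists)
  if (!is.null(gyro_hists)) out$gyro_hist <- gyro_hists
  out
}

# Small seeded cohort split into enrol/test, shared by recognition tests.
small_cohort <- function(n_users = 3, samples_per_user = 8, seed = 7, ...) {
  generate_cohort(cohort_spec(n_users = n_users,
                              samples_per_user = samples_per_user,
                              seed = seed, ...))
}

# Genuine/impostor verification decisions over a split gallery.
run_verification_helper <- function(gal, error_factor = 0.95, mode = "fused") {
  enr_gal <- gal[gal$split == "enrol", ]
  tst_gal <- gal[gal$split == "test", ]
  gen <- list(); imp <- list()
  for (u in unique(gal$user_id)) {
    e <- build_enrolment(enr_gal[enr_gal$user_id == u, ],
                         error_factor = error_factor, mode = mode)
    d <- verify_gait(tst_gal, e, mode = mode)
    gen[[u]] <- d[d$true_user == u, ]
    imp[[u]] <- d[d$true_user != u, ]
  }
  list(genuine = dplyr::bind_rows(gen), impostor = dplyr::bind_rows(imp))
}
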