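test_that("distance matrix is 1 minus symmetrised similarity", {
  withr::with_seed(61, {
    h1 <- rand_hist(12, 60); h2 <- rand_hist(12, 60); h3 <- rand_hist(12, 60)
    gal <- make_gallery(c("a", "a", "b"), list(h1, h1, h3))
    D <- similarity_distance_matrix(gal, mode = "accel_only")
    expect_equal(diag(D), rep(0, 3))
    expect_equal(D, t(D))
    expect_true(all(D >= 0 & D <= 1))
    expect_equal(D[1, 2], 0)  # identical samples
    # brute-force oracle: mean of both orientations via the naive loop
    for (i in 1:2) for (j in (i + 1):3) {
      sym <- mean(c(naive_intersection(gal$accel_hist[[i]], gal$accel_hist[[j]]),
                    naive_intersection(gal$accel_hist[[j]], gal$accel_hist[[i]])))
      expect_equal(D[i, j], 1 - sym, tolerance = 1e-12)
    }
  })
})

test_that("disjoint-support samples are at distance 1", {
  a <- make_hist(c(9L, 0L, 0L), c(9L, 0L, 0L), c(9L, 0L, 0L))
  b <- make_hist(c(0L, 0L, 9L), c(0L, 0L, 9L), c(0L, 0L, 9L))
  D <- similarity_distance_matrix(make_gallery(c("a", "b"), list(a, b)),
                                  mode = "accel_only")
  expect_equal(D[1, 2], 1)
})

test_that("k-medoids edge cases are exact", {
  withr::with_seed(62, {
    gal <- make_gallery(letters[1:5], lapply(1:5, function(i) rand_hist(10, 50)))
    D <- similarity_distance_matrix(gal, mode = "accel_only")
    # k = 1: single cluster, medoid minimises the total distance
    c1 <- cluster_samples(D, k = 1, seed = 3)
    expect_equal(unique(c1$assignment), 1L)
    expect_equal(c1$medoid_indices, which.min(colSums(D)))
    expect_equal(c1$objective, min(colSums(D)))
    # k = n: every sample its own cluster, objective 0
    cn <- cluster_samples(D, k = 5, seed = 3)
    expect_equal(sort(cn$medoid_indices), 1:5)
    expect_equal(cn$objective, 0)
    expect_error(cluster_samples(D, k = 6), "k")
  })
})

test_that("planted two-placement structure is recovered (ARI >= 0.9)", {
  ds <- generate_cohort(cohort_spec(n_users = 3, samples_per_user = 10,
                                    placements = c("torso", "right_leg"),
                                    seed = 11))
  gal <- build_gallery(ds)
  D <- similarity_distance_matrix(gal)
  cl <- cluster_samples(D, k = 2, seed = 5)
  ari <- ari_contingency(cl$assignment, gal$placement)
  expect_gte(ari, 0.9)
  # contingency-table oracle agrees with the established implementation
  expect_equal(ari, mclust::adjustedRandIndex(cl$assignment, gal$placement),
               tolerance = 1e-12)
  # independent cross-check: PAM on the same distances finds the same split
  pam_fit <- cluster::pam(stats::as.dist(D), k = 2)
  expect_gte(ari_contingency(cl$assignment, pam_fit$clustering), 0.9)
})

test_that("clustering is deterministic and its objective never increases", {
  ds <- generate_cohort(cohort_spec(n_users = 2, samples_per_user = 8,
                                    placements = c("torso", "right_arm"),
                                    seed = 8))
  gal <- build_gallery(ds)
  D <- similarity_distance_matrix(gal)
  a <- cluster_samples(D, k = 3, seed = 42)
  b <- cluster_samples(D, k = 3, seed = 42)
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$medoid_indices, b$medoid_indices)
  expect_true(all(diff(a$objective_trace) <= 1e-12))
  # medoids belong to their own cluster
  expect_equal(a$assignment[a$medoid_indices], seq_len(a$k))
})

test_that("cluster composition tallies conserve the sample count", {
  ds <- generate_cohort(cohort_spec(n_users = 2, samples_per_user = 6,
                                    placements = c("torso", "right_leg"),
                                    seed = 14))
  gal <- build_gallery(ds)
  D <- similarity_distance_matrix(gal)
  cl <- cluster_samples(D, k = 2, seed = 2)
  comp <- cluster_composition(cl)
  expect_equal(sum(comp[, -1]), nrow(gal))
  # k = 1 gives the global placement histogram in one row
  c1 <- cluster_samples(D, k = 1, seed = 2)
  comp1 <- cluster_composition(c1)
  expect_equal(unlist(comp1[1, -1], use.names = FALSE),
               as.vector(table(gal$placement)))
  expect_error(cluster_composition(cl, labels = c("a", "b")), "length")
})

test_that("mirrored limb placements co-cluster more than torso samples", {
  ds <- generate_cohort(cohort_spec(n_users = 2, samples_per_user = 8,
                                    placements = c("torso", "right_arm",
                                                   "left_arm"),
                                    seed = 3))
  gal <- build_gallery(ds)
  D <- similarity_distance_matrix(gal)
  pl <- gal$placement
  d_arms <- mean(D[pl == "right_arm", pl == "left_arm"])
  d_arm_torso <- mean(D[pl %in% c("right_arm", "left_arm"), pl == "torso"])
  expect_lt(d_arms, d_arm_torso)
})

test_that("cluster routing verifies within the routed cluster only", {
  ds <- make_split(generate_cohort(cohort_spec(n_users = 4,
                                               samples_per_user = 12,
                                               placements = c("torso",
                                                              "right_leg"),
                                               seed = 9)),
                   first_n(8))
  gal <- build_gallery(ds)
  enr <- gal[gal$split == "enrol", ]
  tst <- gal[gal$split == "test", ]
  D <- similarity_distance_matrix(enr)
  cl <- cluster_samples(D, k = 2, seed = 1)

  # a probe identical to a medoid of a cluster holding >= 2 samples of the
  # claimed user is accepted
  med <- cl$medoid_indices[1]
  med_user <- as.character(enr$user_id[med])
  d_med <- clustered_verify(enr[med, ], enr, cl, med_user)
  expect_true(d_med$accepted)
  expect_equal(d_med$cluster, 1L)

  # claiming a user with no enrolment in the routed cluster rejects with flag
  only_torso <- enr[enr$placement == "torso" | enr$user_id != "u01", ]
  # rebuild clustering over a gallery where u01 has samples only in torso
  D2 <- similarity_distance_matrix(only_torso)
  cl2 <- cluster_samples(D2, k = 2, seed = 1)
  leg_probe <- tst[tst$placement == "right_leg" & tst$user_id == "u01", ][1, ]
  d2 <- clustered_verify(leg_probe, only_torso, cl2, "u01")
  if (!d2$accepted && !is.na(d2$flag)) {
    expect_identical(d2$flag, "no enrolment in cluster")
  }

  # the truthful Table-2-style contrast: on mixed placements, routing lifts
  # genuine mean scores and slashes the false-acceptance rate
  gu <- list(); iu <- list(); gc <- list(); ic <- list()
  for (u in unique(gal$user_id)) {
    e <- build_enrolment(enr[enr$user_id == u, ])
    d <- verify_gait(tst, e)
    gu[[u]] <- d[d$true_user == u, ]; iu[[u]] <- d[d$true_user != u, ]
    dc <- clustered_verify(tst, enr, cl, u)
    gc[[u]] <- dc[dc$true_user == u, ]; ic[[u]] <- dc[dc$true_user != u, ]
  }
  m_un <- evaluate_decisions(dplyr::bind_rows(gu), dplyr::bind_rows(iu))
  m_cl <- evaluate_decisions(dplyr::bind_rows(gc), dplyr::bind_rows(ic))
  expect_lt(m_cl$far, m_un$far)
  expect_gt(m_cl$accuracy, m_un$accuracy)
  expect_gt(mean(dplyr::bind_rows(gc)$mean_score, na.rm = TRUE),
            mean(dplyr::bind_rows(gu)$mean_score))
})
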