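test_that("classification returns the best-matching gallery user", {
  withr::with_seed(21, {
    gal <- make_gallery(c("ana", "bob", "cat"),
                        list(rand_hist(12, 60), rand_hist(12, 60),
                             rand_hist(12, 60)))
    # a test sample identical to a gallery sample matches it with score 1
    res <- classify_gait(gal[2, ], gal, mode = "accel_only")
    expect_identical(res$predicted_user, "bob")
    expect_equal(res$best_score, 1)
    expect_equal(res$best_index, 2L)
    # single-user gallery: that user regardless of score
    res1 <- classify_gait(gal[1, ], gal[3, ], mode = "accel_only")
    expect_identical(res1$predicted_user, "cat")
  })
})

test_that("classification agrees with a brute-force scan of pairwise scores", {
  ds <- make_split(small_cohort(n_users = 2, samples_per_user = 6, seed = 31),
                   every_kth(3))
  gal <- build_gallery(ds, n_bins = 15)
  enr <- gal[gal$split == "enrol", ]
  tst <- gal[gal$split == "test", ]
  res <- classify_gait(tst, enr, mode = "fused")
  for (i in seq_len(nrow(tst))) {
    scores <- vapply(seq_len(nrow(enr)), function(j) {
      fuse_scores(
        intersection_similarity(tst$accel_hist[[i]], enr$accel_hist[[j]]),
        intersection_similarity(tst$gyro_hist[[i]], enr$gyro_hist[[j]]))
    }, numeric(1))
    expect_equal(res$best_index[i], which.max(scores))
    expect_equal(res$best_score[i], max(scores), tolerance = 1e-12)
    expect_identical(res$predicted_user[i],
                     as.character(enr$user_id[which.max(scores)]))
  }
  # well-separated two-user cohort: every test sample recovers its user
  expect_true(all(res$predicted_user == res$true_user))
})

test_that("enrolment derives the threshold from the intra-set minimum", {
  h <- rand_hist(10, 40); g <- rand_hist(10, 40, "gyroscope")
  same <- make_gallery(rep("u", 3), list(h, h, h), list(g, g, g))
  e <- build_enrolment(same)
  expect_equal(e$min_intra_score, 1)
  expect_equal(e$threshold, 0.95)

  withr::with_seed(5, {
    two <- make_gallery(rep("u", 2),
                        list(rand_hist(10, 40), rand_hist(10, 40)),
                        list(rand_hist(10, 40, "gyroscope"),
                             rand_hist(10, 40, "gyroscope")))
    # oracle: both ordered pairs scored by the scalar path
    s12 <- fuse_scores(
      intersection_similarity(two$accel_hist[[1]], two$accel_hist[[2]]),
      intersection_similarity(two$gyro_hist[[1]], two$gyro_hist[[2]]))
    s21 <- fuse_scores(
      intersection_similarity(two$accel_hist[[2]], two$accel_hist[[1]]),
      intersection_similarity(two$gyro_hist[[2]], two$gyro_hist[[1]]))
    e1 <- build_enrolment(two, error_factor = 1.0)
    expect_equal(e1$threshold, min(s12, s21), tolerance = 1e-12)
    e95 <- build_enrolment(two)
    expect_equal(e95$threshold, 0.95 * min(s12, s21), tolerance = 1e-12)
  })

  expect_error(build_enrolment(same[1, ]), "enrolment too small")
  expect_error(build_enrolment(same, error_factor = 1.5), "error_factor")
})

test_that("verification accepts when the mean score reaches the threshold", {
  h <- rand_hist(10, 40); g <- rand_hist(10, 40, "gyroscope")
  enr <- build_enrolment(make_gallery(rep("u", 3), list(h, h, h),
                                      list(g, g, g)))
  # identical to every enrolment sample -> mean 1 -> accepted
  d <- verify_gait(make_gallery("u", list(h), list(g)), enr)
  expect_true(d$accepted)
  expect_equal(d$mean_score, 1)
  # disjoint support -> mean 0 -> rejected
  far_a <- make_hist(c(rep(0L, 9), 40L), c(rep(0L, 9), 40L),
                     c(rep(0L, 9), 40L))
  ha <- make_hist(c(40L, rep(0L, 9)), c(40L, rep(0L, 9)),
                  c(40L, rep(0L, 9)))
  gb <- make_hist(c(40L, rep(0L, 9)), c(40L, rep(0L, 9)),
                  c(40L, rep(0L, 9)), sensor = "gyroscope")
  gfar <- make_hist(c(rep(0L, 9), 40L), c(rep(0L, 9), 40L),
                    c(rep(0L, 9), 40L), sensor = "gyroscope")
  enr2 <- build_enrolment(make_gallery(rep("u", 2), list(ha, ha),
                                       list(gb, gb)))
  d2 <- verify_gait(make_gallery("x", list(far_a), list(gfar)), enr2)
  expect_false(d2$accepted)
  expect_equal(d2$mean_score, 0)
})

test_that("an impostor from a distant profile is rejected end to end", {
  ds <- make_split(small_cohort(n_users = 2, samples_per_user = 8, seed = 19,
                                separation = 2),
                   first_n(6))
  gal <- build_gallery(ds)
  enr <- build_enrolment(gal[gal$split == "enrol" & gal$user_id == "u01", ])
  imp <- gal[gal$split == "test" & gal$user_id == "u02", ]
  d <- verify_gait(imp, enr)
  expect_true(all(!d$accepted))
  gen <- gal[gal$split == "test" & gal$user_id == "u01", ]
  expect_true(all(verify_gait(gen, enr)$accepted))
})

test_that("majority voting needs a strict majority and fails safe on ties", {
  expect_true(majority_vote(c(TRUE, TRUE, FALSE)))
  expect_false(majority_vote(c(FALSE, FALSE, TRUE)))
  expect_false(majority_vote(c(TRUE, FALSE)))
  expect_true(majority_vote(tibble::tibble(accepted = c(TRUE, TRUE, TRUE))))
  expect_error(majority_vote(logical(0)), "at least one")
})

test_that("biometric metrics tally attempts per their definitions", {
  perfect <- evaluate_decisions(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$far, 0)
  expect_equal(perfect$frr, 0)

  no_imp <- evaluate_decisions(c(rep(TRUE, 9), FALSE), logical(0))
  expect_equal(no_imp$frr, 0.1)
  expect_equal(no_imp$far, 0)
  expect_true(no_imp$far_undefined)

  mixed <- evaluate_decisions(c(TRUE, TRUE, TRUE, FALSE),
                              c(TRUE, rep(FALSE, 5)))
  expect_equal(mixed$accuracy, 0.8)
  expect_equal(mixed$far, 1 / 6)
  expect_equal(mixed$frr, 1 / 4)
  # tallies conserve
  expect_equal(mixed$genuine_accepts + mixed$genuine_rejects, 4L)
  expect_equal(mixed$impostor_accepts + mixed$impostor_rejects, 6L)
  expect_error(evaluate_decisions(logical(0), logical(0)), "no attempts")
})

test_that("acceptances grow monotonically as the error factor decreases", {
  ds <- make_split(small_cohort(n_users = 3, samples_per_user = 8, seed = 23,
                                noise_sd = c(accel = 1.2, gyro = 0.25)),
                   first_n(5))
  gal <- build_gallery(ds)
  factors <- c(1.0, 0.95, 0.9, 0.8, 0.6)
  n_accepted <- vapply(factors, function(f) {
    v <- run_verification_helper(gal, error_factor = f)
    sum(v$genuine$accepted) + sum(v$impostor$accepted)
  }, numeric(1))
  expect_true(all(diff(n_accepted) >= 0))
})

test_that("enrolment samples classify to their own user with score 1", {
  ds <- small_cohort(n_users = 2, samples_per_user = 4, seed = 29)
  gal <- build_gallery(ds)
  res <- classify_gait(gal, gal)
  expect_true(all(res$predicted_user == res$true_user))
  expect_true(all(abs(res$best_score - 1) < 1e-12))
})

test_that("bin sweep covers the requested grid and matches plain accuracy", {
  ds <- make_split(small_cohort(n_users = 2, samples_per_user = 6, seed = 13),
                   every_kth(3))
  sw <- sweep_bins(ds)
  expect_equal(nrow(sw), 11L)
  expect_equal(sw$n_bins, seq(10L, 40L, by = 3L))
  expect_true(all(sw$accuracy >= 0 & sw$accuracy <= 1))

  one <- sweep_bins(ds, bin_counts = 20L)
  gal <- build_gallery(ds, n_bins = 20)
  res <- classify_gait(gal[gal$split == "test", ],
                       gal[gal$split == "enrol", ])
  expect_equal(one$accuracy, mean(res$predicted_user == res$true_user))

  # a perfectly separable noise-free cohort is exact at every bin count
  clean <- make_split(small_cohort(n_users = 2, samples_per_user = 6,
                                   seed = 37, separation = 2, jitter = 0,
                                   noise_sd = c(accel = 0, gyro = 0)),
                      every_kth(3))
  sw_clean <- sweep_bins(clean)
  expect_true(all(sw_clean$accuracy == 1))
  expect_error(sweep_bins(ds, bin_counts = integer(0)), "bin_counts")
})
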