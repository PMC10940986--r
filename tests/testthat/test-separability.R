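test_that("a margin-separated point set is decoded almost perfectly", {
  # labels are a deterministic function of the PC1 sign, wide margin
  withr::with_seed(1, {
    x1 <- c(runif(100, 0, 0.3), runif(100, 0.7, 1))
    pts <- cbind(x1, matrix(runif(200 * 3), 200, 3))
    ps <- make_ps(pts, rep(c("spont_pooled", "evoked"), each = 100))
    res <- evaluate_separability(ps, spont_pool = NULL,
                                 knn_config(reps = 10, shuffle_reps = 20,
                                            seed = 2))
    expect_gte(res$accuracy, 0.99)
    expect_lt(res$empirical_p, 0.05)
  })
})

test_that("labels independent of the coordinates score inside their own null band", {
  ps <- two_cloud_ps(100, 4, shift = 0, seed = 3)
  res <- evaluate_separability(ps, spont_pool = NULL,
                               knn_config(reps = 20, shuffle_reps = 100,
                                          seed = 4))
  expect_lt(abs(res$accuracy - res$null_mean), 3 * res$null_sd)
  expect_gt(res$empirical_p, 0.05)
})

test_that("the default configuration records reps x folds fold-level evaluations", {
  ps <- two_cloud_ps(25, 2, shift = 1, seed = 5)
  res <- evaluate_separability(ps, spont_pool = NULL,
                               knn_config(reps = 100, folds = 5,
                                          shuffle_reps = 10, seed = 6))
  expect_equal(dim(res$fold_accuracies), c(100L, 5L))
  expect_equal(sum(!is.na(res$fold_accuracies)), 500L)
  expect_length(res$rep_accuracies, 100L)
  expect_equal(res$accuracy, mean(res$rep_accuracies))
  expect_true(all(res$rep_accuracies >= 0 & res$rep_accuracies <= 1))
})

test_that("label shuffles preserve class counts and centre on chance", {
  ps2 <- two_cloud_ps(120, 3, shift = 2, seed = 7)
  null2 <- shuffle_null(ps2, knn_config(reps = 1, shuffle_reps = 60,
                                        seed = 8))
  expect_length(null2, 60L)
  expect_gt(mean(null2), 0.45)
  expect_lt(mean(null2), 0.55)
  # three balanced classes: chance at 1/3
  withr::with_seed(9, {
    pts <- matrix(runif(240 * 3), 240, 3)
    ps3 <- make_ps(pts, rep(c("evoked", "spont_pre", "spont_post"), each = 80))
  })
  null3 <- shuffle_null(ps3, knn_config(shuffle_reps = 60, seed = 10))
  expect_gt(mean(null3), 0.28)
  expect_lt(mean(null3), 0.38)
})

test_that("empirical significance uses the add-one correction at both extremes", {
  res <- structure(
    list(accuracy = 0.9, null_accuracies = seq(0.4, 0.6, length.out = 100)),
    class = "ecog_separability"
  )
  expect_equal(empirical_significance(res), 1 / 101)
  res$accuracy <- 0.1
  expect_equal(empirical_significance(res), 1)
  # observed at the null median: p near 0.5 (direct counting oracle)
  res$accuracy <- median(res$null_accuracies)
  expect_equal(
    empirical_significance(res),
    (1 + sum(res$null_accuracies >= res$accuracy)) / 101
  )
  expect_lt(abs(empirical_significance(res) - 0.5), 0.02)
})

test_that("separability results are reproducible for a fixed configuration", {
  ps <- two_cloud_ps(60, 3, shift = 1, seed = 11)
  cfg <- knn_config(reps = 10, shuffle_reps = 20, seed = 12)
  a <- evaluate_separability(ps, spont_pool = NULL, cfg)
  b <- evaluate_separability(ps, spont_pool = NULL, cfg)
  expect_identical(a$rep_accuracies, b$rep_accuracies)
  expect_identical(a$null_accuracies, b$null_accuracies)
})

test_that("spontaneous points are redrawn every resample_every repetitions", {
  ses <- quick_session(seed = 13, spont = 10, stim = 20)
  rec <- zscore_recording(remove_artifacts(ses$recording, ses$events))
  scores <- project_scores(rec, fit_pca(rec))
  ps <- label_period(scores, ses$schedule, ses$events, 2L,
                     labeling_config(points_per_class = 100, seed = 14))
  cfg <- knn_config(reps = 20, resample_every = 10, shuffle_reps = 10,
                    seed = 15)
  with_pool <- evaluate_separability(ps, spont_pool = attr(ps, "pool"), cfg)
  fixed <- evaluate_separability(ps, spont_pool = NULL, cfg)
  # first block identical, later blocks computed on redrawn spontaneous data
  expect_identical(with_pool$rep_accuracies[1:10], fixed$rep_accuracies[1:10])
  expect_false(identical(with_pool$rep_accuracies[11:20],
                         fixed$rep_accuracies[11:20]))
  expect_error(knn_config(reps = 25, resample_every = 10), "multiple")
})

test_that("accuracy grows with the global shift amplitude", {
  acc <- vapply(c(0, 0.8, 2), function(a) {
    ses <- quick_session(seed = 16, spont = 10, stim = 20,
                         global_shift_amp = a, lfp_amp = 0)
    rec <- zscore_recording(remove_artifacts(ses$recording, ses$events))
    scores <- project_scores(rec, fit_pca(rec))
    ps <- label_period(scores, ses$schedule, ses$events, 2L,
                       labeling_config(points_per_class = 120, seed = 17))
    evaluate_separability(ps, spont_pool = NULL,
                          knn_config(reps = 10, shuffle_reps = 5,
                                     seed = 18))$accuracy
  }, numeric(1))
  sd_rep <- 0.03  # generous bound on repetition-level variability
  expect_gte(acc[2], acc[1] - 2 * sd_rep)
  expect_gte(acc[3], acc[2] - 2 * sd_rep)
  expect_gt(acc[3], acc[1] + 0.1)
})

test_that("too few points per class for the fold count is rejected", {
  ps <- two_cloud_ps(4, 2, shift = 1, seed = 19)
  expect_error(
    evaluate_separability(ps, spont_pool = NULL, knn_config(folds = 5)),
    "at least 5 points"
  )
})
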