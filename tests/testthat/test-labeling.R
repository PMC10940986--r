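one_period_setup <- function(seed = 1, freq = 1, spont = 20, stim = 30,
                             ...) {
  ses <- quick_session(seed = seed, freq = freq, spont = spont,
                       stim = stim, ...)
  rec <- zscore_recording(remove_artifacts(ses$recording, ses$events))
  emb <- fit_pca(rec)
  list(ses = ses, scores = project_scores(rec, emb))
}

test_that("the evoked window covers 5-195 ms after each pulse (190 samples)", {
  events <- tibble::tibble(time_s = 0, site = "LFP", period_index = 1L)
  period <- tibble::tibble(period_index = 1L, kind = "stimulation",
                           site = "LFP", frequency_hz = 1,
                           start_s = 0, end_s = 10)
  idx <- evoked_indices(events, period, labeling_config(), fs_hz = 1000)
  expect_length(idx, 190L)
  # pulse at t=0 occupies sample 1; window starts 5 ms later
  expect_equal(idx, 6:195)
})

test_that("no pulses give an empty evoked set; overlapping windows are rejected", {
  period <- tibble::tibble(period_index = 1L, kind = "stimulation",
                           site = "LFP", frequency_hz = 1,
                           start_s = 0, end_s = 10)
  empty <- tibble::tibble(time_s = numeric(), site = character(),
                          period_index = integer())
  expect_length(evoked_indices(empty, period, labeling_config(), 1000), 0L)
  period$frequency_hz <- 6  # 166.7 ms spacing < 195 ms window
  expect_error(evoked_indices(empty, period, labeling_config(), 1000), "6 Hz")
})

test_that("at 5 Hz windows abut without overlap and index counts multiply out", {
  sched <- make_protocol(5, sites = "LFP", spont_dur_s = 10, stim_dur_s = 300)
  ev <- generate_events(sched)
  period <- sched[2, ]
  idx <- evoked_indices(ev, period, labeling_config(), 1000)
  # oracle: brute-force interval enumeration over the sample grid
  pulses <- round(ev$time_s * 1000) + 1
  brute <- sort(unique(unlist(lapply(pulses, function(p) (p + 5):(p + 194)))))
  brute <- brute[brute <= 310 * 1000]
  expect_equal(idx, brute)
  expect_length(idx, 1500L * 190L)
  expect_equal(anyDuplicated(idx), 0L)
})

test_that("spontaneous draws return exactly the requested count, reproducibly", {
  st <- one_period_setup(seed = 2)
  sched <- st$ses$schedule
  cfg <- labeling_config(seed = 42)
  a <- sample_spontaneous(sched[c(1, 3), ], 500, cfg, 1000, st$ses$events)
  b <- sample_spontaneous(sched[c(1, 3), ], 500, cfg, 1000, st$ses$events)
  expect_identical(a, b)
  expect_length(a, 500L)
  c <- sample_spontaneous(sched[c(1, 3), ], 500, cfg, 1000, st$ses$events,
                          seed = 43)
  expect_false(identical(a, c))
})

test_that("spontaneous indices stay in spontaneous periods, clear of post-stimulus carryover", {
  st <- one_period_setup(seed = 3, spont = 10, stim = 30)
  sched <- st$ses$schedule
  ev <- st$ses$events
  cfg <- labeling_config(seed = 1)
  for (mode in c("contiguous_segments", "uniform_samples")) {
    cfg$spont_draw <- mode
    idx <- sample_spontaneous(sched[c(1, 3), ], 2000, cfg, 1000, ev)
    t_idx <- (idx - 1) / 1000
    in_spont <- (t_idx >= 0 & t_idx < 10) | (t_idx >= 40 & t_idx < 50)
    expect_true(all(in_spont))
    # never within 195 ms after a pulse (matters at the period boundary)
    for (p in ev$time_s) {
      expect_false(any(t_idx >= p & t_idx < p + 0.195))
    }
  }
})

test_that("contiguous spontaneous segments do not overlap and truncate the last draw", {
  st <- one_period_setup(seed = 4, spont = 10, stim = 30)
  sched <- st$ses$schedule
  idx <- sample_spontaneous(sched[c(1, 3), ], 475, labeling_config(seed = 9),
                            1000, st$ses$events)
  expect_length(idx, 475L)                    # 2 full segments + 95
  expect_equal(anyDuplicated(idx), 0L)
  runs <- rle(diff(idx) == 1)
  expect_true(all(runs$lengths[runs$values] <= 189))
})

test_that("insufficient spontaneous data is rejected with counts", {
  sched <- make_protocol(1, sites = "LFP", spont_dur_s = 1, stim_dur_s = 10)
  expect_error(
    sample_spontaneous(sched[c(1, 3), ], 10000, labeling_config(), 1000),
    "2000 samples available, 10000 required"
  )
})

test_that("uniform spontaneous draws are uniform over the eligible range", {
  sched <- make_protocol(1, sites = "LFP", spont_dur_s = 100,
                         stim_dur_s = 10)
  cfg <- labeling_config(spont_draw = "uniform_samples", seed = 5)
  idx <- sample_spontaneous(sched[1, ], 10000, cfg, 1000)
  # oracle: chi-square goodness of fit against the uniform distribution
  bins <- cut(idx, breaks = seq(0, 100000, by = 10000))
  p <- suppressWarnings(chisq.test(table(bins))$p.value)
  expect_gt(p, 0.01)
})

test_that("two-group point sets are balanced with pooled spontaneous labels", {
  st <- one_period_setup(seed = 5)
  cfg <- labeling_config(points_per_class = 380, seed = 7)
  ps <- label_period(st$scores, st$ses$schedule, st$ses$events, 2L, cfg)
  expect_s3_class(ps, "ecog_pointset")
  expect_equal(nrow(ps), 760L)
  expect_equal(as.vector(table(ps$label)), c(380L, 380L))
  expect_equal(levels(ps$label), c("evoked", "spont_pooled"))
  expect_equal(anyDuplicated(ps$sample), 0L)
  m <- ecogsep:::ps_matrix(ps)
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(attr(ps, "meta")$frequency_hz, 1)
})

test_that("three-group point sets match pre and post counts to the evoked count", {
  st <- one_period_setup(seed = 6)
  cfg <- labeling_config(scheme = "three_group", points_per_class = 100,
                         seed = 8)
  ps <- label_period(st$scores, st$ses$schedule, st$ses$events, 2L, cfg)
  expect_equal(nrow(ps), 300L)
  expect_equal(as.vector(table(ps$label)), c(100L, 100L, 100L))
  expect_equal(levels(ps$label), c("evoked", "spont_pre", "spont_post"))
})

test_that("degenerate or conflicting point-set requests are rejected", {
  st <- one_period_setup(seed = 7)
  cfg <- labeling_config()
  expect_error(
    build_pointset(st$scores, integer(0), 1:10, cfg = cfg),
    "empty"
  )
  cfg3 <- labeling_config(scheme = "three_group")
  expect_error(
    build_pointset(st$scores, 1:10, 11:20, 21:30, cfg3,
                   meta = list(frequency_hz = 4)),
    "4 Hz"
  )
  expect_error(
    build_pointset(st$scores, 1:10, 5:14, cfg = cfg),
    "disjoint"
  )
  expect_error(
    build_pointset(st$scores, 1:10, 11:15, cfg = cfg),
    "imbalance"
  )
})

test_that("evoked and spontaneous samples never share a period", {
  st <- one_period_setup(seed = 8, spont = 10, stim = 30)
  sched <- st$ses$schedule
  cfg <- labeling_config(points_per_class = 150, seed = 3)
  ps <- label_period(st$scores, sched, st$ses$events, 2L, cfg)
  t_s <- (ps$sample - 1) / 1000
  stim_window <- t_s >= sched$start_s[2] & t_s < sched$end_s[2]
  expect_true(all(stim_window[ps$label == "evoked"]))
  expect_false(any(stim_window[ps$label != "evoked"]))
})

test_that("class balance holds across many random labeling configurations", {
  st <- one_period_setup(seed = 9, spont = 10, stim = 20)
  withr::with_seed(10, {
    for (i in 1:100) {
      scheme <- sample(c("two_group", "three_group"), 1)
      cfg <- labeling_config(
        scheme = scheme,
        spont_draw = sample(c("contiguous_segments", "uniform_samples"), 1),
        points_per_class = sample(20:60, 1),
        seed = sample.int(1e6, 1)
      )
      ps <- label_period(st$scores, st$ses$schedule, st$ses$events, 2L, cfg)
      counts <- table(ps$label)
      expect_equal(length(unique(counts)), 1L)
      expect_equal(anyDuplicated(ps$sample), 0L)
    }
  })
})
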