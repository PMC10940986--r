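test_that("identical seed and parameters give a bit-identical session", {
  a <- quick_session(seed = 11, spont = 5, stim = 10)
  b <- quick_session(seed = 11, spont = 5, stim = 10)
  expect_identical(a$recording$signal, b$recording$signal)
  expect_identical(a$events, b$events)
  c <- quick_session(seed = 12, spont = 5, stim = 10)
  expect_false(identical(a$recording$signal, c$recording$signal))
})

test_that("all effect amplitudes zero gives an all-zero signal", {
  ses <- quick_session(
    seed = 1, spont = 2, stim = 4, osc_amp = 0, noise_sd = 0,
    lfp_amp = 0, global_shift_amp = 0, artifact_amp = 0
  )
  expect_true(all(ses$recording$signal == 0))
})

test_that("noise-only sample covariance approximates the requested covariance", {
  # oracle: the analytic covariance of the coloured-noise model itself
  cc <- 0.25 * (0.8 * diag(8) + 0.2)
  sched <- make_protocol(1, sites = "LFP", spont_dur_s = 50, stim_dur_s = 60)
  # spontaneous-only content: disable oscillation and all event effects
  ses <- simulate_session(
    sim_params(seed = 3, osc_amp = 0, cross_channel_cov = cc,
               lfp_amp = 0, global_shift_amp = 0, artifact_amp = 0),
    sched
  )
  emp <- stats::cov(t(ses$recording$signal))
  expect_lt(max(abs(emp - cc)), 0.05 * max(diag(cc)))
})

test_that("local evoked potential is confined to the responding channel", {
  ses <- quick_session(
    seed = 2, spont = 2, stim = 6, osc_amp = 0, noise_sd = 0,
    lfp_amp = 2, lfp_dur_ms = 30, global_shift_amp = 0, artifact_amp = 0
  )
  sig <- ses$recording$signal
  resp <- which(ses$recording$channels$responding)
  expect_true(all(sig[-resp, ] == 0))
  nz <- which(sig[resp, ] != 0)
  p <- round(ses$events$time_s * 1000) + 1
  # deviation only within lfp_dur_ms after some pulse
  expect_true(all(vapply(nz, function(i) any(i - p >= 0 & i - p < 30),
                         logical(1))))
  expect_true(all(sig[resp, nz] < 0))  # negative-going surface potential
})

test_that("without a global shift, non-responding channels match spontaneous on average", {
  ses <- quick_session(seed = 5, freq = 4, spont = 30, stim = 60,
                       global_shift_amp = 0, lfp_amp = 2)
  rec <- remove_artifacts(ses$recording, ses$events)
  resp <- which(rec$channels$responding)
  post <- epoch_average(rec, ses$events$time_s, win_ms = c(5, 195))  # 240 epochs
  spont_mean <- rowMeans(rec$signal[, 1:30000])
  dev <- abs(rowMeans(post) - spont_mean)
  # noise tolerance: sd of an average over >=200 windows of ~190 samples
  expect_true(all(dev[-resp] < 0.05))
  # the responding channel deviates clearly inside the evoked-potential window
  early <- epoch_average(rec, ses$events$time_s, win_ms = c(5, 35))
  dev_early <- abs(rowMeans(early) - spont_mean)
  expect_gt(dev_early[resp], 0.2)
})

test_that("with a global shift every weighted channel deviates post-stimulus", {
  ses <- quick_session(seed = 6, freq = 4, spont = 30, stim = 60,
                       global_shift_amp = 1.5, lfp_amp = 0)
  rec <- remove_artifacts(ses$recording, ses$events)
  post <- epoch_average(rec, ses$events$time_s, win_ms = c(5, 195))
  spont_mean <- rowMeans(rec$signal[, 1:30000])
  dev <- abs(rowMeans(post) - spont_mean)
  expect_true(all(dev > 0.05))  # default pattern weights every channel
})

test_that("frequency gain scales the global shift amplitude", {
  mk <- function(f) {
    ses <- quick_session(seed = 9, freq = f, spont = 5, stim = 30,
                         osc_amp = 0, noise_sd = 0, lfp_amp = 0,
                         artifact_amp = 0, global_shift_amp = 1)
    max(abs(ses$recording$signal))
  }
  expect_equal(mk(3), mk(1) / 2)  # default gain: 1 below 2 Hz, 0.5 at/above
})

test_that("a non-PSD covariance is rejected", {
  bad <- diag(8)
  bad[1, 1] <- -1
  expect_error(sim_params(cross_channel_cov = bad), "semidefinite")
})

test_that("every event lies in exactly one stimulation period", {
  ses <- quick_session(seed = 4, freq = c(0.5, 2), sites = c("LFP", "RHP"),
                       spont = 5, stim = 20)
  sched <- ses$schedule
  for (i in seq_len(nrow(ses$events))) {
    inside <- which(ses$events$time_s[i] >= sched$start_s &
                      ses$events$time_s[i] < sched$end_s &
                      sched$kind == "stimulation")
    expect_length(inside, 1L)
    expect_equal(sched$period_index[inside], ses$events$period_index[i])
  }
})
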