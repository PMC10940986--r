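#' Simulation parameters for a synthetic ECoG session
#'
#' Bundles every knob of the synthetic generator. Defaults emulate the study
#' conditions: 8 channels digitised at 1 kHz, a shared slow oscillation near
#' 1.6 Hz (the dominant cortical rhythm under ketamine anesthesia), correlated
#' channel noise, a short (20--50 ms) negative-going evoked field potential on
#' the single responding S1 channel, an optional ~200 ms global shift of the
#' cross-channel activity distribution after each pulse, and a one-sample
#' stimulation shock artifact on all channels.
#'
#' @param n_channels Number of channels (default 8).
#' @param fs_hz Sampling rate in Hz (default 1000).
#' @param osc_freq_hz Frequency of the shared slow oscillation (default 1.6).
#' @param osc_amp Amplitude of the slow oscillation (arbitrary,
#'   microvolt-like units; default 1).
#' @param osc_phase_diffusion Phase-diffusion rate of the oscillation in
#'   radians per square-root second (default 1). The oscillation's phase
#'   performs a Wiener random walk around its nominal advance, giving a
#'   narrowband rhythm that peaks at `osc_freq_hz` instead of a pure tone;
#'   a pure tone would phase-lock to periodic stimulation and fabricate
#'   spurious structure. Set 0 for a deterministic sinusoid.
#' @param noise_sd Per-channel noise standard deviation used to build the
#'   default noise covariance (ignored when `cross_channel_cov` is supplied).
#' @param noise_corr Pairwise channel noise correlation used for the default
#'   covariance (default 0.2).
#' @param cross_channel_cov Optional channels x channels positive semidefinite
#'   noise covariance; overrides `noise_sd`/`noise_corr`.
#' @param lfp_amp Peak amplitude of the local evoked field potential on the
#'   responding channel (default 2; negative-going waveform).
#' @param lfp_dur_ms Duration of the evoked potential in ms, in \[20, 50\]
#'   (default 30).
#' @param global_shift_amp Peak amplitude of the global cross-channel
#'   distribution shift following each pulse (0 disables it; default 1).
#' @param global_shift_dur_ms Duration of the global shift envelope in ms
#'   (default 200: post-stimulus activity loops back to the spontaneous
#'   distribution after about 200 ms).
#' @param global_shift_pattern Unit-norm direction of the global shift in
#'   channel space. Default: alternating-sign vector over channels, i.e. a
#'   redistribution of activity across channels orthogonal to the common-mode
#'   slow-wave axis; re-normalised to unit length if needed.
#' @param artifact_amp Amplitude of the single-sample stimulation shock
#'   artifact added on all channels (default 15).
#' @param freq_gain Multiplier applied to `global_shift_amp` as a function of
#'   the stimulation frequency: either a function of frequency or a named
#'   numeric vector (names = frequency in Hz). Default: 1 below 2 Hz, 0.5 at
#'   2 Hz and above, reflecting weaker distribution shifts at high rates.
#' @param seed Integer seed; identical parameters + schedule + seed yield a
#'   bit-identical session.
#'
#' @return A list of class `ecog_sim_params`.
#' @export
sim_params <- function(n_channels = 8L, fs_hz = 1000, osc_freq_hz = 1.6,
                       osc_amp = 1, osc_phase_diffusion = 1,
                       noise_sd = 0.5, noise_corr = 0.2,
                       cross_channel_cov = NULL,
                       lfp_amp = 2, lfp_dur_ms = 30,
                       global_shift_amp = 1, global_shift_dur_ms = 200,
                       global_shift_pattern = NULL,
                       artifact_amp = 15,
                       freq_gain = function(f) ifelse(f < 2, 1, 0.5),
                       seed = 1L) {
  if (fs_hz <= 0) abort(sprintf("`fs_hz` must be positive, got %s", fs_hz))
  if (n_channels < 1L) abort("`n_channels` must be at least 1")
  for (nm in c("lfp_dur_ms", "global_shift_dur_ms")) {
    if (get(nm) <= 0) abort(sprintf("`%s` must be positive", nm))
  }
  if (is.null(cross_channel_cov)) {
    cross_channel_cov <- noise_sd^2 *
      ((1 - noise_corr) * diag(n_channels) + noise_corr)
  }
  cross_channel_cov <- as.matrix(cross_channel_cov)
  if (!isTRUE(all.equal(cross_channel_cov, t(cross_channel_cov),
                        tolerance = 1e-10))) {
    abort("`cross_channel_cov` must be symmetric")
  }
  ev <- eigen(cross_channel_cov, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1)) {
    abort("`cross_channel_cov` must be positive semidefinite")
  }
  if (is.null(global_shift_pattern)) {
    global_shift_pattern <- rep(c(1, -1), length.out = n_channels)
  }
  nrm <- sqrt(sum(global_shift_pattern^2))
  if (nrm == 0) abort("`global_shift_pattern` must be a non-zero vector")
  global_shift_pattern <- global_shift_pattern / nrm
  if (is.numeric(freq_gain) && is.null(names(freq_gain))) {
    abort("a numeric `freq_gain` must be named by frequency")
  }
  structure(
    list(
      n_channels = as.integer(n_channels), fs_hz = fs_hz,
      osc_freq_hz = osc_freq_hz, osc_amp = osc_amp,
      osc_phase_diffusion = osc_phase_diffusion,
      noise_sd = noise_sd, noise_corr = noise_corr,
      cross_channel_cov = cross_channel_cov,
      noise_factor = ev$vectors %*% diag(sqrt(pmax(ev$values, 0)),
                                         n_channels),
      lfp_amp = lfp_amp, lfp_dur_ms = lfp_dur_ms,
      global_shift_amp = global_shift_amp,
      global_shift_dur_ms = global_shift_dur_ms,
      global_shift_pattern = global_shift_pattern,
      artifact_amp = artifact_amp,
      freq_gain = freq_gain,
      seed = as.integer(seed)
    ),
    class = "ecog_sim_params"
  )
}

eval_freq_gain <- function(freq_gain, f) {
  if (is.function(freq_gain)) {
    return(freq_gain(f))
  }
  key <- as.character(f)
  if (key %in% names(freq_gain)) {
    return(unname(freq_gain[[key]]))
  }
  # nearest declared frequency
  fk <- as.numeric(names(freq_gain))
  unname(freq_gain[[which.min(abs(fk - f))]])
}

#' Simulate a synthetic multichannel ECoG session
#'
#' Generates a seeded session following a protocol schedule. The signal is the
#' sum of (i) a shared narrowband slow oscillation (random initial phase,
#' phase-diffusing around `osc_freq_hz`), (ii) Gaussian noise coloured by a factor of the cross-channel
#' covariance, and, per stimulus pulse, (iii) a one-sample shock artifact on
#' all channels, (iv) a damped negative half-sine evoked potential on the
#' responding channel only, and (v) a rank-one global shift: the unit
#' `global_shift_pattern` scaled by `global_shift_amp`, the frequency gain,
#' and a half-sine envelope of duration `global_shift_dur_ms` on all channels.
#'
#' @param params Parameters from [sim_params()].
#' @param schedule Protocol schedule from [make_protocol()].
#' @param channels Channel metadata (default [default_channels()]); exactly
#'   one channel must be flagged `responding` when `lfp_amp != 0`.
#'
#' @return A list with elements `recording` (an [ecog_recording()]), `events`
#'   (tibble from [generate_events()]) and `schedule`.
#' @examples
#' sched <- make_protocol(1, sites = "LFP", spont_dur_s = 5, stim_dur_s = 10)
#' ses <- simulate_session(sim_params(seed = 7), sched)
#' ses$recording
#' @export
simulate_session <- function(params, schedule, channels = default_channels()) {
  stopifnot(inherits(params, "ecog_sim_params"))
  validate_schedule(schedule)
  channels <- as_tibble(channels)
  validate_channels(channels, n_channels = params$n_channels)
  resp <- which(channels$responding)
  if (params$lfp_amp != 0 && length(resp) != 1L) {
    abort("exactly one channel must be flagged `responding`")
  }

  fs <- params$fs_hz
  nc <- params$n_channels
  n <- as.integer(round(max(schedule$end_s) * fs))
  events <- generate_events(schedule)

  sig <- withr::with_seed(params$seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    s <- params$noise_factor %*%
      matrix(stats::rnorm(nc * n), nrow = nc, ncol = n)
    if (params$osc_amp != 0) {
      t_s <- (seq_len(n) - 1L) / fs
      phi <- 2 * pi * params$osc_freq_hz * t_s + phase
      if (params$osc_phase_diffusion > 0) {
        phi <- phi + cumsum(stats::rnorm(
          n, 0, params$osc_phase_diffusion / sqrt(fs)
        ))
      }
      osc <- params$osc_amp * sin(phi)
      s <- s + matrix(osc, nrow = nc, ncol = n, byrow = TRUE)
    }
    s
  })

  if (nrow(events) > 0L) {
    nd_lfp <- as.integer(round(params$lfp_dur_ms * fs / 1000))
    u_lfp <- (seq_len(nd_lfp) - 1L) / nd_lfp
    lfp_shape <- -sin(pi * u_lfp) * exp(-3 * u_lfp)
    nd_gs <- as.integer(round(params$global_shift_dur_ms * fs / 1000))
    u_gs <- (seq_len(nd_gs) - 1L) / nd_gs
    gs_env <- sin(pi * u_gs)
    freq_of_period <- stats::setNames(
      schedule$frequency_hz, schedule$period_index
    )
    for (i in seq_len(nrow(events))) {
      s0 <- time_to_sample(events$time_s[i], fs)
      if (s0 < 1L || s0 > n) next
      if (params$artifact_amp != 0) {
        sig[, s0] <- sig[, s0] + params$artifact_amp
      }
      if (params$lfp_amp != 0 && nd_lfp > 0L) {
        j <- s0 + seq_len(nd_lfp) - 1L
        keep <- j <= n
        sig[resp, j[keep]] <- sig[resp, j[keep]] +
          params$lfp_amp * lfp_shape[keep]
      }
      if (params$global_shift_amp != 0 && nd_gs > 0L) {
        gain <- eval_freq_gain(
          params$freq_gain,
          freq_of_period[[as.character(events$period_index[i])]]
        )
        j <- s0 + seq_len(nd_gs) - 1L
        keep <- j <= n
        sig[, j[keep]] <- sig[, j[keep]] +
          params$global_shift_amp * gain *
            (params$global_shift_pattern %o% gs_env[keep])
      }
    }
  }

  list(
    recording = ecog_recording(sig, fs_hz = fs, channels = channels),
    events = events,
    schedule = schedule,
    params = params
  )
}
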