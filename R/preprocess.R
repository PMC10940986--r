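#' Preprocessing configuration
#'
#' @param artifact_width_ms Width of the stimulus shock-artifact window in ms.
#'   For each pulse, the `artifact_width_ms` worth of samples starting at the
#'   pulse sample is replaced on every channel by the straight line joining
#'   the last untouched sample before and the first untouched sample after the
#'   window. Default 1 ms (one sample at 1 kHz), matching interpolation
#'   between the two time steps immediately around the impulse; residual
#'   artifact is additionally covered by the 5 ms post-pulse exclusion during
#'   labeling.
#' @param sg_window_ms Savitzky-Golay window length in ms (default 20); must
#'   span an odd number of samples at the recording rate (even spans are
#'   widened by one sample).
#' @param sg_polyorder Savitzky-Golay polynomial order (default 3).
#' @param zscore_mode `"center_scale"` (full z-score, the default -- channels
#'   of unequal gain would otherwise dominate the PCA) or `"center_only"`.
#' @param smoother `"savitzky_golay"` (default) or `"moving_average"`.
#'
#' @return A list of class `ecog_preprocess_config`.
#' @export
preprocess_config <- function(artifact_width_ms = 1, sg_window_ms = 20,
                              sg_polyorder = 3L,
                              zscore_mode = c("center_scale", "center_only"),
                              smoother = c("savitzky_golay",
                                           "moving_average")) {
  if (artifact_width_ms <= 0) abort("`artifact_width_ms` must be positive")
  if (sg_window_ms <= 0) abort("`sg_window_ms` must be positive")
  structure(
    list(
      artifact_width_ms = artifact_width_ms,
      sg_window_ms = sg_window_ms,
      sg_polyorder = as.integer(sg_polyorder),
      zscore_mode = match.arg(zscore_mode),
      smoother = match.arg(smoother)
    ),
    class = "ecog_preprocess_config"
  )
}

#' Remove stimulation shock artifacts by linear interpolation
#'
#' For every stimulus pulse, the artifact window (see
#' [preprocess_config()]) is replaced, on every channel, by linear
#' interpolation between the nearest untouched samples flanking the window.
#' All other samples are returned bit-identical; the operation is idempotent
#' for a fixed event set.
#'
#' @param rec An [ecog_recording()].
#' @param events Stimulus event tibble (column `time_s`); an empty table
#'   returns the recording unchanged.
#' @param cfg A [preprocess_config()].
#' @return The recording with artifact windows interpolated.
#' @export
remove_artifacts <- function(rec, events, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (nrow(events) == 0L) return(rec)
  n <- ncol(rec$signal)
  w <- max(1L, as.integer(round(cfg$artifact_width_ms * rec$fs_hz / 1000)))
  s0 <- time_to_sample(events$time_s, rec$fs_hz, rec$t0_s)
  if (any(s0 < 1L | s0 > n)) {
    abort("all event times must lie inside the recording")
  }
  sig <- rec$signal
  clamped <- FALSE
  for (s in s0) {
    a <- s - 1L            # last untouched sample before the window
    b <- s + w             # first untouched sample after the window
    win <- s:(s + w - 1L)
    inside <- win >= 1L & win <= n
    if (!all(inside) || a < 1L || b > n) {
      clamped <- TRUE
      win <- win[inside]
      if (length(win) == 0L) next
      left <- if (a >= 1L) sig[, a] else sig[, min(b, n)]
      right <- if (b <= n) sig[, b] else sig[, max(a, 1L)]
    } else {
      left <- sig[, a]
      right <- sig[, b]
    }
    frac <- (win - (s - 1L)) / (w + 1L)  # position between flanking samples
    sig[, win] <- unname(left) %o% (1 - frac) + unname(right) %o% frac
  }
  if (clamped) {
    warn("artifact window clamped at the recording edge for some event(s)")
  }
  rec$signal <- sig
  rec
}

#' Smooth a recording for visualisation
#'
#' Per-channel Savitzky-Golay filtering (default: 20 ms window, cubic), or a
#' centred moving average when `cfg$smoother = "moving_average"`. Output
#' length equals input length. Smoothing is a visualisation stage only: the
#' separability analysis runs on unsmoothed data so that filtering cannot
#' bias the statistic.
#'
#' @inheritParams remove_artifacts
#' @return The smoothed recording.
#' @export
smooth_recording <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "ecog_recording"))
  w <- as.integer(round(cfg$sg_window_ms * rec$fs_hz / 1000))
  if (w %% 2L == 0L) w <- w + 1L
  if (cfg$smoother == "savitzky_golay") {
    if (w < cfg$sg_polyorder + 1L) {
      abort(sprintf(
        "smoothing window (%d samples) must exceed the polynomial order (%d)",
        w, cfg$sg_polyorder
      ))
    }
    sm <- t(apply(rec$signal, 1L, function(x) {
      signal::sgolayfilt(x, p = cfg$sg_polyorder, n = w)
    }))
  } else {
    half <- (w - 1L) %/% 2L
    n <- ncol(rec$signal)
    sm <- t(apply(rec$signal, 1L, function(x) {
      cs <- cumsum(c(0, x))
      lo <- pmax(seq_len(n) - half, 1L)
      hi <- pmin(seq_len(n) + half, n)
      (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }))
  }
  rec$signal <- sm
  rec
}

#' Z-score a recording per channel
#'
#' Subtracts the per-channel mean over the whole session; in the default
#' `"center_scale"` mode also divides by the per-channel standard deviation
#' (sample, n - 1 denominator). A zero-variance channel maps to all zeros.
#'
#' @inheritParams remove_artifacts
#' @return The standardised recording.
#' @export
zscore_recording <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (ncol(rec$signal) < 2L) abort("need at least 2 samples per channel")
  mu <- rowMeans(rec$signal)
  sig <- rec$signal - mu
  if (cfg$zscore_mode == "center_scale") {
    sdv <- apply(rec$signal, 1L, sd)
    scl <- ifelse(sdv > 0, sdv, Inf)  # constant channel -> all zeros
    sig <- sig / scl
  } else {
    const <- apply(sig, 1L, function(x) all(x == 0))
    sig[const, ] <- 0
  }
  rec$signal <- sig
  rec
}
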