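#' Default eight-electrode channel layout
#'
#' Channel metadata tibble for the default recording montage: eight surface
#' electrodes, four per hemisphere, covering primary motor (M1), somatosensory
#' (S1), visual (V1) and auditory (A1) cortex. Exactly one channel -- the right
#' S1 forepaw area -- is flagged `responding`, i.e. it is the only electrode
#' that carries a conventional local evoked field potential after forepaw
#' stimulation.
#'
#' @return A tibble with columns `name`, `hemisphere` (`"left"`/`"right"`),
#'   `area` (`"M1"`, `"S1"`, `"V1"`, `"A1"`) and `responding` (logical).
#' @examples
#' default_channels()
#' @export
default_channels <- function() {
  tibble(
    name = c("M1_L", "S1_L", "V1_L", "A1_L", "M1_R", "S1_R", "V1_R", "A1_R"),
    hemisphere = rep(c("left", "right"), each = 4L),
    area = rep(c("M1", "S1", "V1", "A1"), times = 2L),
    responding = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  )
}

validate_channels <- function(channels, n_channels = NULL) {
  req <- c("name", "hemisphere", "area", "responding")
  if (!all(req %in% names(channels))) {
    abort(paste0(
      "channel table must have columns ",
      paste(req, collapse = ", ")
    ))
  }
  if (anyDuplicated(channels$name)) {
    abort("channel names must be unique")
  }
  if (!all(channels$hemisphere %in% c("left", "right"))) {
    abort("hemisphere must be 'left' or 'right'")
  }
  if (!is.null(n_channels) && nrow(channels) != n_channels) {
    abort(sprintf(
      "channel table has %d rows but the signal has %d channels",
      nrow(channels), n_channels
    ))
  }
  invisible(channels)
}

#' Construct a multichannel recording object
#'
#' Light container for a channels x samples signal matrix with channel
#' metadata and a sampling rate. All analysis functions in the package take
#' this object (the tabular pieces of a session -- events, schedule, results --
#' are plain tibbles).
#'
#' @param signal Numeric matrix, channels x samples; all values finite.
#' @param fs_hz Sampling rate in Hz (default 1000, i.e. 1 kHz digitisation).
#' @param channels Channel metadata tibble as produced by
#'   [default_channels()]; row order must match the rows of `signal`.
#' @param t0_s Time of the first sample, in seconds (default 0).
#'
#' @return An object of class `ecog_recording`.
#' @export
ecog_recording <- function(signal, fs_hz = 1000,
                           channels = default_channels(), t0_s = 0) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    abort("`signal` must be a numeric matrix (channels x samples)")
  }
  if (!all(is.finite(signal))) {
    abort("`signal` must contain only finite values")
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0) {
    abort(sprintf("`fs_hz` must be a single positive number, got %s", fs_hz))
  }
  channels <- as_tibble(channels)
  validate_channels(channels, n_channels = nrow(signal))
  rownames(signal) <- channels$name
  structure(
    list(signal = signal, fs_hz = fs_hz, channels = channels, t0_s = t0_s),
    class = "ecog_recording"
  )
}

#' @export
print.ecog_recording <- function(x, ...) {
  dur <- ncol(x$signal) / x$fs_hz
  cat(sprintf(
    "<ecog_recording> %d channels x %d samples (%.1f s at %g Hz)\n",
    nrow(x$signal), ncol(x$signal), dur, x$fs_hz
  ))
  cat("channels:", paste(x$channels$name, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ecog_recording <- function(x) dim(x$signal)

# session-relative time (s) -> 1-based sample index of the containing sample
time_to_sample <- function(time_s, fs_hz, t0_s = 0) {
  as.integer(round((time_s - t0_s) * fs_hz)) + 1L
}

#' Average signal epochs around events
#'
#' Utility used mainly by tests and plots: averages the signal in a fixed
#' window around each event time, per channel.
#'
#' @param rec An [ecog_recording()].
#' @param times_s Event times in seconds.
#' @param win_ms Length-2 numeric, window around each event in ms
#'   (e.g. `c(0, 200)` for the 200 ms following each event).
#' @return A channels x window-samples matrix of mean waveforms.
#' @export
epoch_average <- function(rec, times_s, win_ms = c(0, 200)) {
  stopifnot(length(win_ms) == 2L, win_ms[2] > win_ms[1])
  off <- seq.int(
    round(win_ms[1] * rec$fs_hz / 1000),
    round(win_ms[2] * rec$fs_hz / 1000) - 1L
  )
  n <- ncol(rec$signal)
  acc <- matrix(0, nrow(rec$signal), length(off))
  used <- 0L
  for (t in times_s) {
    i <- time_to_sample(t, rec$fs_hz, rec$t0_s) + off
    if (i[1] < 1L || i[length(i)] > n) next
    acc <- acc + rec$signal[, i, drop = FALSE]
    used <- used + 1L
  }
  if (used == 0L) abort("no event window fits inside the recording")
  acc / used
}
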