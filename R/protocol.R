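#' Build an alternating spontaneous/stimulation protocol schedule
#'
#' Constructs the session schedule used throughout the package: spontaneous
#' periods alternate with stimulation periods, every stimulation period is
#' flanked by spontaneous periods, stimulation frequencies increase over the
#' session, and each frequency is delivered once per stimulation site
#' (site order alternates within a frequency, e.g. left forepaw then right
#' hind paw).
#'
#' @param frequencies Stimulation frequencies in Hz (positive). The study
#'   protocol uses frequencies from 0.3 to 5 Hz.
#' @param sites Stimulation sites, a subset of `c("LFP", "RHP")`
#'   (left forepaw / right hind paw).
#' @param spont_dur_s Duration of each spontaneous period in seconds
#'   (default 120 s, i.e. 2 min).
#' @param stim_dur_s Duration of each stimulation period in seconds
#'   (default 300 s, i.e. 5 min).
#'
#' @return A tibble with one row per period: `period_index`, `kind`
#'   (`"spontaneous"`/`"stimulation"`), `site` (`"LFP"`, `"RHP"` or `"none"`),
#'   `frequency_hz` (0 for spontaneous periods), `start_s`, `end_s`. Periods
#'   are contiguous and non-overlapping.
#' @examples
#' make_protocol(c(0.3, 1), sites = "LFP")
#' @export
make_protocol <- function(frequencies, sites = c("LFP", "RHP"),
                          spont_dur_s = 120, stim_dur_s = 300) {
  if (length(frequencies) == 0L) abort("`frequencies` must be non-empty")
  bad <- frequencies[!is.finite(frequencies) | frequencies <= 0]
  if (length(bad)) {
    abort(sprintf(
      "stimulation frequencies must be positive; offending value(s): %s",
      paste(bad, collapse = ", ")
    ))
  }
  if (length(sites) == 0L || !all(sites %in% c("LFP", "RHP"))) {
    abort("`sites` must be a non-empty subset of c(\"LFP\", \"RHP\")")
  }
  for (nm in c("spont_dur_s", "stim_dur_s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive duration, got %s", nm, v))
    }
  }

  frequencies <- sort(unique(frequencies))
  kind <- "spontaneous"
  site <- "none"
  freq <- 0
  for (f in frequencies) {
    for (s in sites) {
      kind <- c(kind, "stimulation", "spontaneous")
      site <- c(site, s, "none")
      freq <- c(freq, f, 0)
    }
  }
  dur <- ifelse(kind == "stimulation", stim_dur_s, spont_dur_s)
  end_s <- cumsum(dur)
  tibble(
    period_index = seq_along(kind),
    kind = kind,
    site = site,
    frequency_hz = freq,
    start_s = end_s - dur,
    end_s = end_s
  )
}

validate_schedule <- function(schedule) {
  req <- c("period_index", "kind", "site", "frequency_hz", "start_s", "end_s")
  if (!all(req %in% names(schedule))) {
    abort(paste0("schedule must have columns ", paste(req, collapse = ", ")))
  }
  if (nrow(schedule) == 0L) abort("schedule has no periods")
  if (any(schedule$end_s <= schedule$start_s)) {
    abort("every period must have end_s > start_s")
  }
  if (nrow(schedule) > 1L) {
    gaps <- schedule$start_s[-1L] - schedule$end_s[-nrow(schedule)]
    if (any(abs(gaps) > 1e-9)) {
      abort("periods must be contiguous and non-overlapping")
    }
  }
  stim <- which(schedule$kind == "stimulation")
  for (i in stim) {
    ok_pre <- i > 1L && schedule$kind[i - 1L] == "spontaneous"
    ok_post <- i < nrow(schedule) && schedule$kind[i + 1L] == "spontaneous"
    if (!ok_pre || !ok_post) {
      abort(sprintf(
        "stimulation period %d must be immediately preceded and followed by a spontaneous period",
        schedule$period_index[i]
      ))
    }
    if (schedule$frequency_hz[i] <= 0) {
      abort(sprintf(
        "stimulation period %d has non-positive frequency %s",
        schedule$period_index[i], schedule$frequency_hz[i]
      ))
    }
  }
  invisible(schedule)
}

#' Generate the stimulus event table for a schedule
#'
#' Single pulses are delivered at the period's frequency throughout each
#' stimulation period: the first pulse at the period start, subsequent pulses
#' every `1/frequency_hz` seconds, the last strictly before the period end, so
#' a period of duration `T` at frequency `f` contains `floor(f * T)` pulses.
#'
#' @param schedule A protocol schedule from [make_protocol()].
#' @return A tibble with columns `time_s`, `site`, `period_index`, sorted by
#'   time; empty (zero rows) for a schedule without stimulation periods.
#' @examples
#' sched <- make_protocol(1, sites = "LFP", spont_dur_s = 10, stim_dur_s = 20)
#' generate_events(sched)
#' @export
generate_events <- function(schedule) {
  validate_schedule(schedule)
  stim <- schedule[schedule$kind == "stimulation", , drop = FALSE]
  if (nrow(stim) == 0L) {
    return(tibble(
      time_s = numeric(), site = character(), period_index = integer()
    ))
  }
  rows <- lapply(seq_len(nrow(stim)), function(i) {
    f <- stim$frequency_hz[i]
    dur <- stim$end_s[i] - stim$start_s[i]
    n <- floor(f * dur + 1e-9)
    tibble(
      time_s = stim$start_s[i] + (seq_len(n) - 1) / f,
      site = stim$site[i],
      period_index = stim$period_index[i]
    )
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$time_s), , drop = FALSE]
}
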