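#' Labeling configuration
#'
#' Controls how evoked and spontaneous samples are selected for one
#' stimulation period's separability analysis.
#'
#' @param window_start_ms Start of the evoked window after each pulse, in ms
#'   (default 5: the first 5 ms are excluded to avoid shock-artifact
#'   contamination).
#' @param window_end_ms End (exclusive) of the evoked window in ms (default
#'   195, giving the 190 ms window 5--195 ms; chosen so that windows cannot
#'   overlap at 5 Hz, and much longer than the 20--50 ms evoked potential).
#' @param scheme `"two_group"` (evoked vs pooled spontaneous) or
#'   `"three_group"` (evoked vs preceding vs following spontaneous; only
#'   allowed for stimulation frequencies below 4 Hz, where flanking 2-min
#'   spontaneous periods hold enough data to match the evoked count).
#' @param subset Channel subset variant: `"all"`, `"non_s1"` (drop the
#'   responding S1 electrode) or `"left_hemi"` (keep only left-hemisphere
#'   electrodes).
#' @param spont_draw How spontaneous samples are drawn:
#'   `"contiguous_segments"` (default; non-overlapping segments of the evoked
#'   window length, read as random "time series" of spontaneous activity) or
#'   `"uniform_samples"` (isolated samples uniformly at random).
#' @param points_per_class Optional cap on points per class: evoked windows
#'   are subsampled (seeded) to this many isolated samples and the
#'   spontaneous draw is matched in count and switched to isolated
#'   (`uniform_samples`) draws, so both classes keep the same temporal
#'   structure and the label-shuffle null stays calibrated. `NULL` (default)
#'   uses every evoked sample.
#' @param seed Integer seed for all random draws derived from this config.
#'
#' @return A list of class `ecog_labeling_config`.
#' @export
labeling_config <- function(window_start_ms = 5, window_end_ms = 195,
                            scheme = c("two_group", "three_group"),
                            subset = c("all", "non_s1", "left_hemi"),
                            spont_draw = c("contiguous_segments",
                                           "uniform_samples"),
                            points_per_class = NULL, seed = 1L) {
  if (!(window_start_ms >= 0 && window_start_ms < window_end_ms)) {
    abort("need 0 <= window_start_ms < window_end_ms")
  }
  structure(
    list(
      window_start_ms = window_start_ms,
      window_end_ms = window_end_ms,
      scheme = match.arg(scheme),
      subset = match.arg(subset),
      spont_draw = match.arg(spont_draw),
      points_per_class = points_per_class,
      seed = as.integer(seed)
    ),
    class = "ecog_labeling_config"
  )
}

# inclusive sample range covered by a period [start_s, end_s)
period_sample_range <- function(start_s, end_s, fs_hz) {
  c(as.integer(round(start_s * fs_hz)) + 1L,
    as.integer(round(end_s * fs_hz)))
}

#' Evoked-window sample indices for one stimulation period
#'
#' For each pulse in the period, returns the sample indices in the window
#' `[pulse + window_start_ms, pulse + window_end_ms)`, clipped to the period,
#' without duplicates. Indices are 1-based positions in the session's sample
#' grid.
#'
#' @param events Stimulus event tibble (columns `time_s`, `period_index`).
#' @param period One schedule row (tibble) describing the stimulation period.
#' @param cfg A [labeling_config()].
#' @param fs_hz Sampling rate in Hz.
#' @return Sorted integer vector of sample indices.
#' @export
evoked_indices <- function(events, period, cfg, fs_hz) {
  stopifnot(nrow(period) == 1L)
  if (period$frequency_hz > 0 &&
      1000 / period$frequency_hz < cfg$window_end_ms) {
    abort(sprintf(
      "evoked windows of %g ms overlap at %g Hz (inter-pulse interval %.1f ms)",
      cfg$window_end_ms, period$frequency_hz, 1000 / period$frequency_hz
    ))
  }
  ev <- events[events$time_s >= period$start_s &
                 events$time_s < period$end_s, , drop = FALSE]
  if (nrow(ev) == 0L) return(integer(0))
  w0 <- as.integer(round(cfg$window_start_ms * fs_hz / 1000))
  w1 <- as.integer(round(cfg$window_end_ms * fs_hz / 1000))
  offsets <- seq.int(w0, w1 - 1L)
  pulses <- time_to_sample(ev$time_s, fs_hz)
  idx <- as.integer(outer(pulses, offsets, `+`))
  rng <- period_sample_range(period$start_s, period$end_s, fs_hz)
  sort(unique(idx[idx >= rng[1] & idx <= rng[2]]))
}

# subtract closed integer intervals `cut` (2-col matrix lo,hi) from `base`
subtract_intervals <- function(base, cut) {
  out <- base
  for (k in seq_len(nrow(cut))) {
    lo <- cut[k, 1]; hi <- cut[k, 2]
    nxt <- matrix(integer(0), 0, 2)
    for (i in seq_len(nrow(out))) {
      a <- out[i, 1]; b <- out[i, 2]
      if (hi < a || lo > b) {
        nxt <- rbind(nxt, c(a, b))
      } else {
        if (lo > a) nxt <- rbind(nxt, c(a, lo - 1L))
        if (hi < b) nxt <- rbind(nxt, c(hi + 1L, b))
      }
    }
    out <- nxt
  }
  out
}

# eligible spontaneous sample intervals: inside the given spontaneous
# periods, excluding the window_end_ms carryover after any stimulus pulse
spont_intervals <- function(spont_periods, cfg, fs_hz, events = NULL) {
  base <- t(vapply(
    seq_len(nrow(spont_periods)),
    function(i) period_sample_range(
      spont_periods$start_s[i], spont_periods$end_s[i], fs_hz
    ),
    integer(2)
  ))
  if (!is.null(events) && nrow(events) > 0L) {
    w1 <- as.integer(round(cfg$window_end_ms * fs_hz / 1000))
    p <- time_to_sample(events$time_s, fs_hz)
    base <- subtract_intervals(base, cbind(p, p + w1 - 1L))
  }
  base[base[, 2] >= base[, 1], , drop = FALSE]
}

#' Draw matched spontaneous sample indices
#'
#' Draws exactly `n_required` sample indices from the given spontaneous
#' periods, never within `window_end_ms` after any stimulus pulse. In the
#' default `"contiguous_segments"` mode, non-overlapping segments of the
#' evoked-window length are placed at random until the count is met (the
#' final segment is truncated); `"uniform_samples"` draws isolated samples
#' uniformly without replacement.
#'
#' @param spont_periods Schedule rows (tibble) of spontaneous periods to draw
#'   from -- typically the two periods flanking the analysed stimulation
#'   period.
#' @param n_required Number of indices to return (the evoked count).
#' @param cfg A [labeling_config()].
#' @param fs_hz Sampling rate in Hz.
#' @param events Full stimulus event tibble, used to exclude post-stimulus
#'   carryover at period boundaries (optional).
#' @param seed Seed for this draw (default `cfg$seed`).
#' @return Sorted integer vector of exactly `n_required` indices.
#' @export
sample_spontaneous <- function(spont_periods, n_required, cfg, fs_hz,
                               events = NULL, seed = cfg$seed) {
  if (nrow(spont_periods) == 0L) abort("no spontaneous periods supplied")
  if (any(spont_periods$kind != "spontaneous")) {
    abort("`spont_periods` must contain only spontaneous periods")
  }
  ints <- spont_intervals(spont_periods, cfg, fs_hz, events)
  avail <- sum(ints[, 2] - ints[, 1] + 1L)
  if (avail < n_required) {
    abort(sprintf(
      "insufficient spontaneous data: %d samples available, %d required",
      avail, n_required
    ))
  }
  withr::with_seed(seed, {
    if (cfg$spont_draw == "uniform_samples") {
      pool <- unlist(lapply(seq_len(nrow(ints)), function(i) {
        seq.int(ints[i, 1], ints[i, 2])
      }))
      idx <- sample(pool, n_required)
    } else {
      w0 <- as.integer(round(cfg$window_start_ms * fs_hz / 1000))
      w1 <- as.integer(round(cfg$window_end_ms * fs_hz / 1000))
      seg_len <- w1 - w0
      free <- ints
      idx <- integer(0)
      remaining <- n_required
      while (remaining > 0L) {
        len <- min(seg_len, remaining)
        starts <- pmax(0L, free[, 2] - free[, 1] + 2L - len)
        total <- sum(starts)
        if (total == 0L) {
          abort(sprintf(
            "insufficient contiguous spontaneous data: %d samples still required",
            remaining
          ))
        }
        u <- sample.int(total, 1L)
        k <- which(cumsum(starts) >= u)[1L]
        before <- if (k > 1L) sum(starts[seq_len(k - 1L)]) else 0L
        s <- free[k, 1] + (u - before) - 1L
        idx <- c(idx, seq.int(s, s + len - 1L))
        free <- subtract_intervals(free, cbind(s, s + len - 1L))
        remaining <- remaining - len
      }
    }
    sort(idx)
  })
}

ps_meta <- function(ps) attr(ps, "meta")

ps_matrix <- function(ps) {
  as.matrix(ps[, grep("^PC", names(ps)), drop = FALSE])
}

#' Assemble a labeled point set in component space
#'
#' Selects the given sample indices from a score series, min-max normalizes
#' each component over the pooled selected points (so every component spans
#' \[0, 1\] within this analysis, a constant one mapping to 0.5), and labels
#' them. In the two-group scheme the classes are `evoked` and `spont_pooled`
#' with equal counts; in the three-group scheme, `evoked`, `spont_pre` and
#' `spont_post`, each spontaneous class matched to the evoked count so the
#' three-class chance level stays at 1/3.
#'
#' @param scores An `ecog_scores` series from [project_scores()].
#' @param evoked_idx Evoked sample indices ([evoked_indices()]).
#' @param spont_idx_pre Spontaneous indices (for `two_group`, the pooled
#'   draw may be passed entirely here).
#' @param spont_idx_post Spontaneous indices from the following period
#'   (`three_group`), or further pooled indices (`two_group`); default none.
#' @param cfg A [labeling_config()].
#' @param meta List of condition metadata carried along: `period_index`,
#'   `site`, `frequency_hz` (required for the three-group frequency guard).
#' @return A tibble of class `ecog_pointset` with columns `sample`, `label`
#'   and `PC1..PCd`; condition metadata in `attr(, "meta")`.
#' @export
build_pointset <- function(scores, evoked_idx, spont_idx_pre,
                           spont_idx_post = integer(0), cfg,
                           meta = list()) {
  stopifnot(inherits(scores, "ecog_scores"))
  if (length(evoked_idx) == 0L) abort("evoked index set is empty")
  if (cfg$scheme == "three_group" &&
      !is.null(meta$frequency_hz) && meta$frequency_hz >= 4) {
    abort(sprintf(
      "three_group comparison is not applicable at %g Hz (requires < 4 Hz)",
      meta$frequency_hz
    ))
  }
  all_spont <- c(spont_idx_pre, spont_idx_post)
  if (any(duplicated(c(evoked_idx, all_spont)))) {
    abort("evoked and spontaneous index sets must be disjoint")
  }
  n_e <- length(evoked_idx)
  if (cfg$scheme == "two_group") {
    if (length(all_spont) != n_e) {
      abort(sprintf(
        "class imbalance: %d evoked vs %d spontaneous points",
        n_e, length(all_spont)
      ))
    }
    idx <- c(evoked_idx, all_spont)
    labels <- factor(
      rep(c("evoked", "spont_pooled"), c(n_e, n_e)),
      levels = c("evoked", "spont_pooled")
    )
  } else {
    if (length(spont_idx_pre) != n_e || length(spont_idx_post) != n_e) {
      abort(sprintf(
        "class imbalance: %d evoked vs %d pre / %d post spontaneous points",
        n_e, length(spont_idx_pre), length(spont_idx_post)
      ))
    }
    idx <- c(evoked_idx, spont_idx_pre, spont_idx_post)
    labels <- factor(
      rep(c("evoked", "spont_pre", "spont_post"), each = n_e),
      levels = c("evoked", "spont_pre", "spont_post")
    )
  }
  if (any(idx < 1L) || any(idx > ncol(scores$scores))) {
    abort("point indices fall outside the score series")
  }
  pts <- minmax_rows(scores$scores[, idx, drop = FALSE])
  d <- nrow(pts)
  out <- tibble(sample = as.integer(idx), label = labels)
  pcs <- as_tibble(t(pts), .name_repair = "minimal")
  names(pcs) <- paste0("PC", seq_len(d))
  out <- dplyr::bind_cols(out, pcs)
  attr(out, "meta") <- c(
    meta,
    list(scheme = cfg$scheme, subset = cfg$subset)[
      !c("scheme", "subset") %in% names(meta)
    ]
  )
  class(out) <- c("ecog_pointset", class(out))
  out
}

#' Label one stimulation period end-to-end
#'
#' Convenience driver: computes the evoked-window indices of the stimulation
#' period (optionally subsampled to `cfg$points_per_class`), draws matched
#' spontaneous indices from the two flanking spontaneous periods (pooled for
#' the two-group scheme, separately for the three-group scheme), and builds
#' the labeled point set. The returned point set carries a `pool` attribute
#' describing the spontaneous pool so the separability analysis can redraw
#' spontaneous points during its repetitions.
#'
#' @param scores An `ecog_scores` series covering the session.
#' @param schedule Protocol schedule tibble.
#' @param events Stimulus event tibble.
#' @param period_index Index of the stimulation period to analyse.
#' @param cfg A [labeling_config()].
#' @return An `ecog_pointset` (see [build_pointset()]).
#' @export
label_period <- function(scores, schedule, events, period_index, cfg) {
  validate_schedule(schedule)
  i <- match(period_index, schedule$period_index)
  if (is.na(i) || schedule$kind[i] != "stimulation") {
    abort(sprintf("period %s is not a stimulation period", period_index))
  }
  period <- schedule[i, , drop = FALSE]
  pre <- schedule[i - 1L, , drop = FALSE]
  post <- schedule[i + 1L, , drop = FALSE]
  fs <- scores$fs_hz

  ev_idx <- evoked_indices(events, period, cfg, fs)
  if (length(ev_idx) == 0L) abort("no evoked samples in this period")
  if (!is.null(cfg$points_per_class) &&
      cfg$points_per_class < length(ev_idx)) {
    ev_idx <- withr::with_seed(
      cfg$seed + 250000L + period$period_index,
      sort(sample(ev_idx, cfg$points_per_class))
    )
    # subsampled evoked points are isolated samples; draw the spontaneous
    # class the same way so the two classes stay structurally exchangeable
    # (a label-shuffle null is only calibrated when neither class is a
    # handful of phase-coherent contiguous segments)
    cfg$spont_draw <- "uniform_samples"
  }
  meta <- list(
    period_index = period$period_index,
    site = period$site,
    frequency_hz = period$frequency_hz
  )
  ps <- draw_and_build(
    scores, ev_idx, pre, post, events, cfg, meta,
    seed = cfg$seed + period$period_index
  )
  attr(ps, "pool") <- list(
    scores = scores, evoked_idx = ev_idx, pre = pre, post = post,
    events = events, cfg = cfg, meta = meta,
    base_seed = cfg$seed + period$period_index
  )
  ps
}

# one spontaneous draw + point-set assembly; `seed` decorrelates redraws
draw_and_build <- function(scores, ev_idx, pre, post, events, cfg, meta,
                           seed) {
  fs <- scores$fs_hz
  n_e <- length(ev_idx)
  if (cfg$scheme == "two_group") {
    sp <- sample_spontaneous(
      dplyr::bind_rows(pre, post), n_e, cfg, fs, events, seed = seed
    )
    build_pointset(scores, ev_idx, sp, integer(0), cfg, meta)
  } else {
    sp_pre <- sample_spontaneous(pre, n_e, cfg, fs, events, seed = seed)
    sp_post <- sample_spontaneous(
      post, n_e, cfg, fs, events, seed = seed + 500000L
    )
    build_pointset(scores, ev_idx, sp_pre, sp_post, cfg, meta)
  }
}

redraw_pointset <- function(pool, draw_id) {
  draw_and_build(
    pool$scores, pool$evoked_idx, pool$pre, pool$post, pool$events,
    pool$cfg, pool$meta, seed = pool$base_seed + 1000L * draw_id
  )
}
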