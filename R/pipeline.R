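#' Write a session bundle to a directory
#'
#' One directory = one session: the signal as a little-endian float64 binary
#' array (`signal.bin`, channels x samples, column-major) with a JSON sidecar
#' header (`header.json`), channel metadata, events and schedule as CSV, and
#' a JSON config snapshot sufficient to regenerate the session bit-identically
#' when simulation parameters are supplied.
#'
#' @param session List with elements `recording` ([ecog_recording()]),
#'   `events`, `schedule` and optionally `params` ([sim_params()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- session$recording
  stopifnot(inherits(rec, "ecog_recording"))
  header <- list(
    fs_hz = rec$fs_hz, t0_s = rec$t0_s,
    n_channels = nrow(rec$signal), n_samples = ncol(rec$signal),
    dtype = "float64", endian = "little",
    layout = "channels x samples, column-major"
  )
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dir, "signal.bin"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.double(rec$signal), con, size = 8L, endian = "little")
  readr::write_csv(rec$channels, file.path(dir, "channels.csv"))
  readr::write_csv(session$events, file.path(dir, "events.csv"))
  readr::write_csv(session$schedule, file.path(dir, "schedule.csv"))
  if (!is.null(session$params)) {
    p <- unclass(session$params)
    p$noise_factor <- NULL
    if (is.function(p$freq_gain)) {
      f <- unique(session$schedule$frequency_hz)
      f <- f[f > 0]
      p$freq_gain <- as.list(stats::setNames(
        vapply(f, p$freq_gain, numeric(1)), as.character(f)
      ))
    }
    jsonlite::write_json(p, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a session bundle from a directory
#'
#' Reads and cross-validates the files written by [write_session()]:
#' channel count must match the signal, the schedule must be a valid
#' alternating protocol, and every event must lie inside its stimulation
#' period and inside the recording. Write-then-read round trips are
#' bit-identical.
#'
#' @param dir Session directory.
#' @return List with `recording`, `events`, `schedule` and (when present)
#'   `params` (the config snapshot, as a list).
#' @export
read_session <- function(dir) {
  need <- c("header.json", "signal.bin", "channels.csv", "events.csv",
            "schedule.csv")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      abort(sprintf("session file missing: %s", file.path(dir, f)))
    }
  }
  header <- jsonlite::read_json(file.path(dir, "header.json"),
                                simplifyVector = TRUE)
  n_val <- header$n_channels * header$n_samples
  con <- file(file.path(dir, "signal.bin"), "rb")
  sig <- readBin(con, "double", n = n_val, size = 8L, endian = "little")
  close(con)
  if (length(sig) != n_val) {
    abort(sprintf(
      "signal.bin holds %d values, header promises %d (%d channels x %d samples)",
      length(sig), n_val, header$n_channels, header$n_samples
    ))
  }
  sig <- matrix(sig, nrow = header$n_channels, ncol = header$n_samples)
  channels <- readr::read_csv(
    file.path(dir, "channels.csv"), show_col_types = FALSE,
    col_types = readr::cols(
      name = readr::col_character(), hemisphere = readr::col_character(),
      area = readr::col_character(), responding = readr::col_logical()
    )
  )
  if (nrow(channels) != header$n_channels) {
    abort(sprintf(
      "channel metadata/signal mismatch: channels.csv has %d rows, signal has %d channels",
      nrow(channels), header$n_channels
    ))
  }
  schedule <- readr::read_csv(
    file.path(dir, "schedule.csv"), show_col_types = FALSE,
    col_types = readr::cols(
      period_index = readr::col_integer(), kind = readr::col_character(),
      site = readr::col_character(), frequency_hz = readr::col_double(),
      start_s = readr::col_double(), end_s = readr::col_double()
    )
  )
  validate_schedule(schedule)
  events <- readr::read_csv(
    file.path(dir, "events.csv"), show_col_types = FALSE,
    col_types = readr::cols(
      time_s = readr::col_double(), site = readr::col_character(),
      period_index = readr::col_integer()
    )
  )
  if (nrow(events) > 0L) {
    per <- schedule[match(events$period_index, schedule$period_index), ]
    bad <- which(is.na(per$period_index) |
                   events$time_s < per$start_s |
                   events$time_s >= per$end_s |
                   events$time_s >= header$n_samples / header$fs_hz)
    if (length(bad)) {
      abort(sprintf(
        "event(s) outside their period or the recording: rows %s of events.csv",
        paste(head(bad, 5L), collapse = ", ")
      ))
    }
  }
  rec <- ecog_recording(sig, fs_hz = header$fs_hz, channels = channels,
                        t0_s = header$t0_s)
  params <- NULL
  if (file.exists(file.path(dir, "config.json"))) {
    params <- jsonlite::read_json(file.path(dir, "config.json"),
                                  simplifyVector = TRUE)
  }
  list(recording = rec, events = events, schedule = schedule,
       params = params)
}

variant_table <- function() {
  tibble(
    variant = c("all_2groups", "all_3groups", "non_s1", "left_hemi"),
    scheme = c("two_group", "three_group", "two_group", "two_group"),
    subset = c("all", "all", "non_s1", "left_hemi")
  )
}

subset_channel_names <- function(channels, subset) {
  switch(subset,
    all = channels$name,
    non_s1 = channels$name[!channels$responding],
    left_hemi = channels$name[channels$hemisphere == "left"],
    abort(sprintf("unknown channel subset '%s'", subset))
  )
}

#' Analyse one stimulation period under one analysis variant
#'
#' Composes the analysis chain for a single stimulation period: fit the PCA
#' on the period plus its flanking spontaneous periods (or the whole
#' session), restricted to the variant's channel subset; project; label
#' evoked and matched spontaneous samples; and run the repeated
#' cross-validated kNN separability with its shuffle null.
#'
#' @param rec A preprocessed [ecog_recording()] (artifact-interpolated and
#'   z-scored; no smoothing -- the statistic runs on unfiltered data).
#' @param schedule,events Session schedule and events.
#' @param period_index Stimulation period to analyse.
#' @param variant One of `"all_2groups"`, `"all_3groups"`, `"non_s1"`,
#'   `"left_hemi"`.
#' @param label_cfg A [labeling_config()] (its `scheme`/`subset` are
#'   overridden by the variant).
#' @param knn_cfg A [knn_config()].
#' @param pca_scope `"window"` (default: fit the PCA per analysis window) or
#'   `"session"`.
#' @return An `ecog_separability`, with `attr(, "embedding")` holding the
#'   fitted `ecog_pca`.
#' @export
analyze_period <- function(rec, schedule, events, period_index,
                           variant = "all_2groups",
                           label_cfg = labeling_config(),
                           knn_cfg = knn_config(),
                           pca_scope = c("window", "session")) {
  pca_scope <- match.arg(pca_scope)
  vt <- variant_table()
  vi <- match(variant, vt$variant)
  if (is.na(vi)) {
    abort(sprintf(
      "unknown variant '%s' (use one of %s)",
      variant, paste(vt$variant, collapse = ", ")
    ))
  }
  label_cfg$scheme <- vt$scheme[vi]
  label_cfg$subset <- vt$subset[vi]
  subset <- subset_channel_names(rec$channels, vt$subset[vi])

  i <- match(period_index, schedule$period_index)
  win <- NULL
  if (pca_scope == "window") {
    rng <- period_sample_range(
      schedule$start_s[i - 1L], schedule$end_s[i + 1L], rec$fs_hz
    )
    win <- seq.int(rng[1], min(rng[2], ncol(rec$signal)))
  }
  emb <- fit_pca(rec, channel_subset = subset, samples = win)
  scores <- project_scores(rec, emb)
  ps <- label_period(scores, schedule, events, period_index, label_cfg)
  res <- evaluate_separability(ps, spont_pool = attr(ps, "pool"),
                               cfg = knn_cfg)
  res$meta$variant <- variant
  attr(res, "embedding") <- emb
  res
}

#' Run the full analysis pipeline over a session
#'
#' End-to-end driver: preprocesses the session (artifact interpolation then
#' per-channel z-scoring; no smoothing on the analysis path), then runs every
#' requested analysis variant on every stimulation period, producing a tidy
#' per-period results table, condition summary tables (overall, by site, by
#' frequency), the per-period null distributions and, optionally, component
#' sensitivity analyses. The three-group variant is marked not applicable
#' (`NA` accuracy) for periods at 4 Hz and above.
#'
#' @param session A session directory (read with [read_session()]) or a list
#'   with `recording`, `events`, `schedule`.
#' @param out_dir Optional output directory; when given, writes
#'   `results.csv`, `summary.csv` (condition x variant medians),
#'   `null_accuracies.csv`, `sensitivity.csv` (if computed) and `log.json`
#'   (config and seeds). Re-running with identical seeds reproduces the
#'   files byte for byte.
#' @param variants Analysis variants to run (see [analyze_period()]).
#' @param label_cfg,knn_cfg,pre_cfg Stage configurations.
#' @param pca_scope `"window"` or `"session"` (see [analyze_period()]).
#' @param sensitivity Also run knockout and incremental component analyses on
#'   the first applicable period's all-channels two-group point set
#'   (default FALSE).
#' @return An object of class `ecog_pipeline_result`: list with `results`
#'   (tibble, one row per period x variant), `summaries` (named list of
#'   [summarize_conditions()] outputs), `nulls` (long tibble of null
#'   accuracies), `fits` (the `ecog_separability` objects) and possibly
#'   `sensitivity`.
#' @export
run_pipeline <- function(session, out_dir = NULL,
                         variants = c("all_2groups", "all_3groups",
                                      "non_s1", "left_hemi"),
                         label_cfg = labeling_config(),
                         knn_cfg = knn_config(),
                         pre_cfg = preprocess_config(),
                         pca_scope = "window",
                         sensitivity = FALSE) {
  if (is.character(session)) session <- read_session(session)
  rec <- session$recording
  events <- session$events
  schedule <- session$schedule
  validate_schedule(schedule)

  rec <- remove_artifacts(rec, events, pre_cfg)
  rec <- zscore_recording(rec, pre_cfg)

  stim_idx <- schedule$period_index[schedule$kind == "stimulation"]
  fits <- list()
  rows <- list()
  nulls <- list()
  sens <- NULL
  base_knn_seed <- knn_cfg$seed
  for (vi in seq_along(variants)) {
    v <- variants[vi]
    for (pi in stim_idx) {
      freq <- schedule$frequency_hz[match(pi, schedule$period_index)]
      site <- schedule$site[match(pi, schedule$period_index)]
      key <- sprintf("%s.p%d", v, pi)
      if (v == "all_3groups" && freq >= 4) {
        rows[[key]] <- tibble(
          period_index = pi, site = site, frequency_hz = freq,
          scheme = "three_group", subset = "all", variant = v,
          n_points = NA_integer_, n_classes = NA_integer_,
          accuracy = NA_real_, null_mean = NA_real_, null_sd = NA_real_,
          null_max = NA_real_, p_value = NA_real_, z = NA_real_,
          applicable = FALSE
        )
        next
      }
      knn_cfg$seed <- base_knn_seed + 101L * pi + 7L * vi
      fit <- tryCatch(
        analyze_period(rec, schedule, events, pi, variant = v,
                       label_cfg = label_cfg, knn_cfg = knn_cfg,
                       pca_scope = pca_scope),
        error = function(e) {
          abort(sprintf(
            "pipeline stage 'separability' failed for period %d, variant %s: %s",
            pi, v, conditionMessage(e)
          ))
        }
      )
      fits[[key]] <- fit
      g <- glance(fit)
      g$variant <- v
      g$applicable <- TRUE
      rows[[key]] <- g
      nulls[[key]] <- tibble(
        period_index = pi, variant = v,
        shuffle = seq_along(fit$null_accuracies),
        accuracy = fit$null_accuracies
      )
    }
  }
  knn_cfg$seed <- base_knn_seed
  results <- dplyr::bind_rows(rows)
  nulls <- dplyr::bind_rows(nulls)

  ok <- results[results$applicable, , drop = FALSE]
  summaries <- list(
    all = summarize_conditions(ok, "all"),
    by_site = summarize_conditions(ok, "by_site"),
    by_frequency = summarize_conditions(ok, "by_frequency")
  )
  summary_table <- dplyr::bind_rows(
    summaries$all$table, summaries$by_site$table,
    summaries$by_frequency$table
  )

  if (sensitivity) {
    key <- grep("^all_2groups\\.", names(fits), value = TRUE)[1L]
    if (!is.na(key)) {
      pi <- fits[[key]]$meta$period_index
      emb <- attr(fits[[key]], "embedding")
      lc <- label_cfg
      lc$scheme <- "two_group"; lc$subset <- "all"
      scores <- project_scores(rec, emb)
      ps <- label_period(scores, schedule, events, pi, lc)
      sc <- knn_cfg
      sc$seed <- base_knn_seed + 900001L
      sens <- list(
        knockout = pc_knockout(ps, sc, var_explained = emb$var_explained),
        incremental = pc_incremental(ps, sc,
                                     var_explained = emb$var_explained)
      )
    }
  }

  out <- structure(
    list(results = results, summaries = summaries,
         summary_table = summary_table, nulls = nulls, fits = fits,
         sensitivity = sens),
    class = "ecog_pipeline_result"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(results, file.path(out_dir, "results.csv"))
    readr::write_csv(summary_table, file.path(out_dir, "summary.csv"))
    readr::write_csv(nulls, file.path(out_dir, "null_accuracies.csv"))
    if (!is.null(sens)) {
      readr::write_csv(
        dplyr::bind_rows(
          dplyr::mutate(tidy(sens$knockout), mode = "knockout"),
          dplyr::mutate(tidy(sens$incremental), mode = "incremental")
        ),
        file.path(out_dir, "sensitivity.csv")
      )
    }
    log <- list(
      label_cfg = unclass(label_cfg), knn_cfg = unclass(knn_cfg),
      pre_cfg = unclass(pre_cfg), variants = variants,
      pca_scope = pca_scope,
      n_periods = length(stim_idx)
    )
    jsonlite::write_json(log, file.path(out_dir, "log.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}

#' @export
print.ecog_pipeline_result <- function(x, ...) {
  cat("<ecog_pipeline_result>\n")
  print(x$summary_table)
  invisible(x)
}
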