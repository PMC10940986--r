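#' Summarise separability results across stimulation conditions
#'
#' Groups per-period separability results by stimulation condition and
#' reports the median accuracy per condition and analysis variant (a
#' condition x variant table), plus two-sided Wilcoxon rank-sum comparisons:
#' site vs site for `"by_site"`, pooled low (< 2 Hz) vs high (>= 2 Hz)
#' frequencies for `"by_frequency"`, and variant vs variant for `"all"`.
#' Comparisons are reported uncorrected by default.
#'
#' @param results Either a list of `ecog_separability` objects or a tidy
#'   tibble with columns `accuracy`, `site`, `frequency_hz`, `period_index`
#'   and (optionally) `variant`.
#' @param grouping `"all"`, `"by_site"` or `"by_frequency"`.
#' @param p_adjust Apply Benjamini-Hochberg correction across the emitted
#'   comparisons (default FALSE, matching the uncorrected reporting
#'   convention).
#' @return An object of class `ecog_condition_summary`: list with `table`
#'   (tibble, rows = conditions, columns = variants, plus `n_periods`) and
#'   `comparisons` (tibble with `group_a`, `group_b`, `variant`, `statistic`,
#'   `p_value`).
#' @export
summarize_conditions <- function(results,
                                 grouping = c("all", "by_site",
                                              "by_frequency"),
                                 p_adjust = FALSE) {
  grouping <- match.arg(grouping)
  df <- results_to_tibble(results)
  if (nrow(df) == 0L) abort("no results to summarise")
  if (!"variant" %in% names(df)) df$variant <- "result"

  df$condition <- switch(grouping,
    all = "All",
    by_site = df$site,
    by_frequency = paste0(df$frequency_hz, "Hz")
  )

  tab <- df |>
    dplyr::group_by(.data$condition, .data$variant) |>
    dplyr::summarise(
      median_accuracy = median(.data$accuracy),
      n_periods = dplyr::n(),
      .groups = "drop"
    )
  empty <- setdiff(unique(df$condition), unique(tab$condition))
  if (length(empty)) {
    warn(paste0("omitting empty group(s): ", paste(empty, collapse = ", ")))
  }
  wide <- tab |>
    tidyr::pivot_wider(
      id_cols = "condition",
      names_from = "variant",
      values_from = "median_accuracy"
    ) |>
    dplyr::left_join(
      tab |>
        dplyr::group_by(.data$condition) |>
        dplyr::summarise(n_periods = max(.data$n_periods), .groups = "drop"),
      by = "condition"
    )
  if (grouping == "by_frequency") {
    wide <- wide[order(as.numeric(sub("Hz$", "", wide$condition))), ]
  }

  comparisons <- switch(grouping,
    by_site = pairwise_ranksum(df, df$site),
    by_frequency = pairwise_ranksum(
      df, ifelse(df$frequency_hz < 2, "<2Hz", ">=2Hz")
    ),
    all = variant_ranksum(df)
  )
  if (p_adjust && nrow(comparisons) > 0L) {
    comparisons$p_value <- stats::p.adjust(comparisons$p_value,
                                           method = "BH")
  }
  structure(
    list(table = wide, comparisons = comparisons, grouping = grouping),
    class = "ecog_condition_summary"
  )
}

results_to_tibble <- function(results) {
  if (inherits(results, "data.frame")) {
    return(as_tibble(results))
  }
  if (inherits(results, "ecog_separability")) results <- list(results)
  dplyr::bind_rows(lapply(results, glance))
}

# per variant: rank-sum between every pair of the two (or more) groups in `g`
pairwise_ranksum <- function(df, g) {
  df$.group <- g
  rows <- list()
  for (v in unique(df$variant)) {
    dv <- df[df$variant == v, , drop = FALSE]
    gr <- unique(dv$.group)
    if (length(gr) < 2L) next
    for (i in seq_len(length(gr) - 1L)) {
      for (j in seq.int(i + 1L, length(gr))) {
        a <- dv$accuracy[dv$.group == gr[i]]
        b <- dv$accuracy[dv$.group == gr[j]]
        w <- suppressWarnings(wilcox.test(a, b))
        rows[[length(rows) + 1L]] <- tibble(
          group_a = gr[i], group_b = gr[j], variant = v,
          statistic = unname(w$statistic), p_value = w$p.value
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(
      group_a = character(), group_b = character(), variant = character(),
      statistic = numeric(), p_value = numeric()
    ))
  }
  dplyr::bind_rows(rows)
}

variant_ranksum <- function(df) {
  df$.tmp_variant <- df$variant
  df$variant <- "all"
  out <- pairwise_ranksum(df, df$.tmp_variant)
  out$variant <- NULL
  out
}

#' @export
print.ecog_condition_summary <- function(x, ...) {
  cat(sprintf("<ecog_condition_summary> grouping: %s\n", x$grouping))
  print(x$table)
  if (nrow(x$comparisons)) {
    cat("comparisons (two-sided Wilcoxon rank-sum):\n")
    print(x$comparisons)
  }
  invisible(x)
}
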