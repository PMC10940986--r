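#' Tidy a separability result
#'
#' One row per repetition of the cross-validated evaluation.
#'
#' @param x An `ecog_separability` object.
#' @param ... Unused.
#' @return A tibble with columns `rep` and `accuracy`.
#' @method tidy ecog_separability
#' @export
tidy.ecog_separability <- function(x, ...) {
  tibble(rep = seq_along(x$rep_accuracies), accuracy = x$rep_accuracies)
}

#' One-row summary of a separability result
#'
#' @param x An `ecog_separability` object.
#' @param ... Unused.
#' @return A one-row tibble with condition metadata, the summary accuracy,
#'   null statistics and the empirical p-value.
#' @method glance ecog_separability
#' @export
glance.ecog_separability <- function(x, ...) {
  m <- x$meta
  tibble(
    period_index = m$period_index %||% NA_integer_,
    site = m$site %||% NA_character_,
    frequency_hz = m$frequency_hz %||% NA_real_,
    scheme = m$scheme %||% NA_character_,
    subset = m$subset %||% NA_character_,
    n_points = x$n,
    n_classes = x$n_classes,
    accuracy = x$accuracy,
    null_mean = x$null_mean,
    null_sd = x$null_sd,
    null_max = if (is.null(x$null_accuracies)) NA_real_
               else max(x$null_accuracies),
    p_value = x$empirical_p,
    z = x$z
  )
}

#' Tidy a sensitivity analysis
#'
#' @param x An `ecog_sensitivity` object.
#' @param ... Unused.
#' @return For knockout mode, one row per removed component
#'   (`component`, `accuracy`, `accuracy_drop`, `var_explained`); for
#'   incremental mode, one row per number of included components
#'   (`n_components`, `accuracy`, `cum_var_explained`).
#' @method tidy ecog_sensitivity
#' @export
tidy.ecog_sensitivity <- function(x, ...) {
  ve <- x$var_explained %||% rep(NA_real_, x$d)
  if (x$mode == "knockout") {
    tibble(
      component = seq_len(x$d),
      accuracy = x$knockout_acc,
      accuracy_drop = x$full_acc - x$knockout_acc,
      var_explained = ve
    )
  } else {
    tibble(
      n_components = seq_len(x$d),
      accuracy = x$incremental_acc,
      cum_var_explained = cumsum(ve)
    )
  }
}

#' One-row summary of a sensitivity analysis
#'
#' @param x An `ecog_sensitivity` object.
#' @param ... Unused.
#' @return A one-row tibble with the mode, dimension, full accuracy and the
#'   variance/accuracy-drop correlation (knockout mode).
#' @method glance ecog_sensitivity
#' @export
glance.ecog_sensitivity <- function(x, ...) {
  tibble(
    mode = x$mode,
    d = x$d,
    full_accuracy = x$full_acc,
    var_acc_corr = x$var_acc_corr
  )
}
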