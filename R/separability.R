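#' kNN separability configuration
#'
#' @param k Number of nearest neighbours (default 5).
#' @param folds Cross-validation folds (default 5).
#' @param reps Repetitions of the cross-validated evaluation (default 100);
#'   the reported accuracy is the mean over repetitions, so the default
#'   settings represent `reps * folds = 500` randomizations of test and
#'   training data.
#' @param resample_every Redraw the spontaneous points from their pool every
#'   this many repetitions (default 10), so the accuracy does not reflect one
#'   specific subset of spontaneous activity. Must divide `reps`.
#' @param shuffle_reps Label permutations for the chance-level null
#'   distribution (default 100).
#' @param metric Distance metric; only `"euclidean"` is supported.
#' @param seed Integer seed; a fixed config yields identical results.
#'
#' @return A list of class `ecog_knn_config`.
#' @export
knn_config <- function(k = 5L, folds = 5L, reps = 100L,
                       resample_every = 10L, shuffle_reps = 100L,
                       metric = "euclidean", seed = 1L) {
  if (folds < 2L) abort("`folds` must be at least 2")
  if (reps < 1L) abort("`reps` must be at least 1")
  if (reps >= resample_every && reps %% resample_every != 0L) {
    abort("`reps` must be a multiple of `resample_every`")
  }
  metric <- match.arg(metric, "euclidean")
  structure(
    list(
      k = as.integer(k), folds = as.integer(folds), reps = as.integer(reps),
      resample_every = as.integer(resample_every),
      shuffle_reps = as.integer(shuffle_reps),
      metric = metric, seed = as.integer(seed)
    ),
    class = "ecog_knn_config"
  )
}

#' k-nearest-neighbour prediction
#'
#' Labels each query point by majority vote among its `k` nearest training
#' points under Euclidean distance. Fully deterministic: ties in distance are
#' broken by lower training-point index, and ties in the vote (possible for
#' three classes) by the label of the nearest neighbour belonging to a tied
#' class.
#'
#' @param train_points Numeric matrix, n_train x d.
#' @param train_labels Factor (or vector) of n_train labels.
#' @param test_points Numeric matrix, n_test x d (same d).
#' @param cfg A [knn_config()] (only `k` is used).
#' @return Factor of predicted labels, length n_test.
#' @export
knn_predict <- function(train_points, train_labels, test_points,
                        cfg = knn_config()) {
  train_points <- as.matrix(train_points)
  test_points <- as.matrix(test_points)
  if (ncol(train_points) != ncol(test_points)) {
    abort("train and test points must have the same dimension")
  }
  if (cfg$k > nrow(train_points)) {
    abort(sprintf(
      "k = %d exceeds the training-set size %d", cfg$k, nrow(train_points)
    ))
  }
  train_labels <- as.factor(train_labels)
  lv <- levels(train_labels)
  li <- as.integer(train_labels)
  d2 <- pairwise_sqdist(test_points, train_points)
  pred <- integer(nrow(test_points))
  for (i in seq_len(nrow(test_points))) {
    ord <- order(d2[i, ])  # stable: distance ties fall to the lower index
    nn <- ord[seq_len(cfg$k)]
    counts <- tabulate(li[nn], nbins = length(lv))
    tied <- which(counts == max(counts))
    if (length(tied) == 1L) {
      pred[i] <- tied
    } else {
      # vote tie: the tied class whose member is nearest wins
      pred[i] <- li[nn][which(li[nn] %in% tied)[1L]]
    }
  }
  factor(lv[pred], levels = lv)
}

# squared Euclidean distances, rows of a vs rows of b
pairwise_sqdist <- function(a, b) {
  d2 <- matrix(rowSums(a^2), nrow(a), nrow(b)) +
    matrix(rowSums(b^2), nrow(a), nrow(b), byrow = TRUE) -
    2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# stratified fold assignment (uses the current RNG stream)
stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    i <- which(labels == cl)
    if (length(i) < folds) {
      abort(sprintf(
        "class '%s' has %d points, fewer than %d folds",
        cl, length(i), folds
      ))
    }
    fold[i[sample.int(length(i))]] <- rep_len(seq_len(folds), length(i))
  }
  fold
}

# one stratified k-fold cross-validated evaluation; returns per-fold accuracy
cv_fold_accuracies <- function(points, labels, cfg) {
  fold <- stratified_folds(labels, cfg$folds)
  vapply(seq_len(cfg$folds), function(f) {
    te <- fold == f
    pred <- knn_predict(
      points[!te, , drop = FALSE], labels[!te],
      points[te, , drop = FALSE], cfg
    )
    mean(pred == labels[te])
  }, numeric(1))
}

#' Repeated cross-validated kNN separability with permutation null
#'
#' The core statistic: how separable are evoked and spontaneous points in
#' component space? Each repetition performs one stratified k-fold
#' cross-validated kNN evaluation; when a spontaneous pool is supplied, the
#' spontaneous points are redrawn every `resample_every` repetitions. The
#' summary accuracy is the mean over repetitions. Significance is assessed
#' against a label-shuffle null ([shuffle_null()]) computed on the same
#' points.
#'
#' @param ps An `ecog_pointset` from [build_pointset()] or [label_period()].
#' @param spont_pool Spontaneous pool for redraws: the `pool` attribute
#'   attached by [label_period()], or `NULL` to keep the point set fixed.
#'   Defaults to the point set's own pool when present.
#' @param cfg A [knn_config()].
#' @param null Compute the shuffle null (default TRUE).
#' @return An object of class `ecog_separability` with fields
#'   `rep_accuracies`, `fold_accuracies` (reps x folds), `accuracy`,
#'   `null_accuracies`, `null_mean`, `null_sd`, `empirical_p`, `z`, `n`,
#'   `meta`.
#' @export
evaluate_separability <- function(ps, spont_pool = attr(ps, "pool"),
                                  cfg = knn_config(), null = TRUE) {
  pts <- ps_matrix(ps)
  labels <- ps$label
  check_class_sizes(labels, cfg)
  fold_acc <- matrix(NA_real_, cfg$reps, cfg$folds)
  withr::with_seed(cfg$seed, {
    cur_pts <- pts
    cur_lab <- labels
    for (r in seq_len(cfg$reps)) {
      if (!is.null(spont_pool) && r > 1L &&
          (r - 1L) %% cfg$resample_every == 0L) {
        nps <- redraw_pointset(spont_pool, draw_id = r)
        cur_pts <- ps_matrix(nps)
        cur_lab <- nps$label
      }
      fold_acc[r, ] <- cv_fold_accuracies(cur_pts, cur_lab, cfg)
    }
  })
  rep_acc <- rowMeans(fold_acc)
  res <- structure(
    list(
      rep_accuracies = rep_acc,
      fold_accuracies = fold_acc,
      accuracy = mean(rep_acc),
      null_accuracies = NULL, null_mean = NA_real_, null_sd = NA_real_,
      empirical_p = NA_real_, z = NA_real_,
      n = nrow(pts),
      n_classes = nlevels(labels),
      meta = ps_meta(ps) %||% list(),
      cfg = cfg
    ),
    class = "ecog_separability"
  )
  if (null) {
    res$null_accuracies <- shuffle_null(ps, cfg)
    res$null_mean <- mean(res$null_accuracies)
    res$null_sd <- sd(res$null_accuracies)
    res$empirical_p <- empirical_significance(res)
    res$z <- (res$accuracy - res$null_mean) / res$null_sd
  }
  res
}

check_class_sizes <- function(labels, cfg) {
  cnt <- table(labels)
  if (any(cnt < cfg$folds)) {
    abort(sprintf(
      "each class needs at least %d points for %d-fold cross-validation",
      cfg$folds, cfg$folds
    ))
  }
  invisible(cnt)
}

#' Label-shuffle permutation null for the separability statistic
#'
#' Estimates the chance level of the separability analysis: class labels are
#' permuted among the same points (class counts preserved) and each
#' permutation is scored by one full cross-validated kNN evaluation. For
#' balanced G-class data the null concentrates near 1/G.
#'
#' @inheritParams evaluate_separability
#' @return Numeric vector of `cfg$shuffle_reps` null accuracies.
#' @export
shuffle_null <- function(ps, cfg = knn_config()) {
  pts <- ps_matrix(ps)
  labels <- ps$label
  check_class_sizes(labels, cfg)
  withr::with_seed(cfg$seed + 1L, {
    vapply(seq_len(cfg$shuffle_reps), function(s) {
      perm <- labels[sample.int(length(labels))]
      mean(cv_fold_accuracies(pts, perm, cfg))
    }, numeric(1))
  })
}

#' Empirical significance against the shuffle null
#'
#' Add-one-corrected permutation p-value:
#' `p = (1 + #\{null >= observed\}) / (1 + n_null)`, so p is never exactly 0.
#'
#' @param result An `ecog_separability` with a computed null.
#' @return The empirical p-value (single number in (0, 1\]).
#' @export
empirical_significance <- function(result) {
  if (is.null(result$null_accuracies) ||
      length(result$null_accuracies) == 0L) {
    abort("result carries no null distribution")
  }
  (1 + sum(result$null_accuracies >= result$accuracy)) /
    (1 + length(result$null_accuracies))
}

#' @export
print.ecog_separability <- function(x, ...) {
  m <- x$meta
  hdr <- if (length(m)) {
    sprintf(
      " [period %s, %s, %g Hz, %s/%s]",
      m$period_index %||% "?", m$site %||% "?", m$frequency_hz %||% NA,
      m$subset %||% "?", m$scheme %||% "?"
    )
  } else ""
  cat(sprintf("<ecog_separability>%s\n", hdr))
  cat(sprintf(
    "  accuracy %.2f%% over %d reps x %d folds (n = %d, %d classes)\n",
    100 * x$accuracy, length(x$rep_accuracies), ncol(x$fold_accuracies),
    x$n, x$n_classes
  ))
  if (!is.null(x$null_accuracies)) {
    cat(sprintf(
      "  shuffle null %.2f%% +/- %.2f%% (%d shuffles), p = %.4f\n",
      100 * x$null_mean, 100 * x$null_sd, length(x$null_accuracies),
      x$empirical_p
    ))
  }
  invisible(x)
}

# drop or keep components of a point set (keeps labels/meta, no renormalizing:
# the remaining coordinates were already scaled to [0, 1] jointly)
select_components <- function(ps, keep) {
  pc_cols <- grep("^PC", names(ps), value = TRUE)
  out <- ps[, c("sample", "label", pc_cols[keep]), drop = FALSE]
  names(out) <- c("sample", "label", paste0("PC", seq_along(keep)))
  for (a in c("meta", "pool")) attr(out, a) <- attr(ps, a)
  class(out) <- class(ps)
  out
}

#' Per-component knockout sensitivity
#'
#' Re-runs the separability analysis with each principal component removed in
#' turn. A component whose knockout barely moves the accuracy contributes
#' little discriminative information; in distributed, high-dimensional
#' activity no single component dominates.
#'
#' @param ps An `ecog_pointset`.
#' @param cfg A [knn_config()].
#' @param var_explained Optional per-component variance-explained fractions
#'   (from the fitted `ecog_pca`); enables the Pearson correlation between a
#'   component's variance and its knockout accuracy drop.
#' @return Object of class `ecog_sensitivity` with `full_acc`,
#'   `knockout_acc` (length d) and, when variances are given,
#'   `var_acc_corr`.
#' @export
pc_knockout <- function(ps, cfg = knn_config(), var_explained = NULL) {
  d <- length(grep("^PC", names(ps)))
  if (d < 2L) abort("need at least 2 components for a knockout analysis")
  full <- evaluate_separability(ps, spont_pool = NULL, cfg, null = FALSE)
  ko <- vapply(seq_len(d), function(j) {
    psj <- select_components(ps, setdiff(seq_len(d), j))
    evaluate_separability(psj, spont_pool = NULL, cfg, null = FALSE)$accuracy
  }, numeric(1))
  corr <- if (!is.null(var_explained)) {
    cor(var_explained, full$accuracy - ko)
  } else {
    NA_real_
  }
  structure(
    list(
      mode = "knockout", d = d, full_acc = full$accuracy,
      knockout_acc = ko, incremental_acc = NULL,
      var_explained = var_explained, var_acc_corr = corr,
      meta = ps_meta(ps) %||% list()
    ),
    class = "ecog_sensitivity"
  )
}

#' Incremental-component sensitivity
#'
#' Separability using only the leading `m` components, for `m = 1..d`. The
#' final entry is the full-space analysis (identical computation and seed).
#'
#' @inheritParams pc_knockout
#' @return Object of class `ecog_sensitivity` with `incremental_acc`
#'   (length d).
#' @export
pc_incremental <- function(ps, cfg = knn_config(), var_explained = NULL) {
  d <- length(grep("^PC", names(ps)))
  if (d < 1L) abort("point set has no components")
  inc <- vapply(seq_len(d), function(m) {
    psm <- select_components(ps, seq_len(m))
    evaluate_separability(psm, spont_pool = NULL, cfg, null = FALSE)$accuracy
  }, numeric(1))
  structure(
    list(
      mode = "incremental", d = d, full_acc = inc[d],
      knockout_acc = NULL, incremental_acc = inc,
      var_explained = var_explained, var_acc_corr = NA_real_,
      meta = ps_meta(ps) %||% list()
    ),
    class = "ecog_sensitivity"
  )
}

#' @export
print.ecog_sensitivity <- function(x, ...) {
  cat(sprintf(
    "<ecog_sensitivity> %s over %d components (full accuracy %.2f%%)\n",
    x$mode, x$d, 100 * x$full_acc
  ))
  v <- if (x$mode == "knockout") x$knockout_acc else x$incremental_acc
  cat(" ", paste(sprintf("%.3f", v), collapse = " "), "\n")
  if (!is.na(x$var_acc_corr)) {
    cat(sprintf("  variance/accuracy-drop Pearson r = %.3f\n",
                x$var_acc_corr))
  }
  invisible(x)
}
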