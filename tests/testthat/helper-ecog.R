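# shared fixtures and independent oracles, built in code at test time

# small synthetic session: one stimulation period flanked by spontaneous
quick_session <- function(seed = 1, freq = 1, sites = "LFP",
                          spont = 30, stim = 60, ...) {
  sched <- make_protocol(freq, sites = sites,
                         spont_dur_s = spont, stim_dur_s = stim)
  simulate_session(sim_params(seed = seed, ...), sched)
}

# recording wrapper around an arbitrary matrix
rec_of <- function(mat, fs = 1000) {
  n <- nrow(mat)
  ch <- tibble::tibble(
    name = paste0("ch", seq_len(n)),
    hemisphere = rep(c("left", "right"), each = ceiling(n / 2))[seq_len(n)],
    area = rep(c("M1", "S1", "V1", "A1"), length.out = n),
    responding = c(TRUE, rep(FALSE, n - 1L))
  )
  ecog_recording(mat, fs_hz = fs, channels = ch)
}

# labeled point set assembled directly from coordinates
make_ps <- function(pts, labels, meta = list()) {
  pts <- as.matrix(pts)
  out <- tibble::tibble(
    sample = seq_len(nrow(pts)),
    label = factor(labels)
  )
  pcs <- tibble::as_tibble(as.data.frame(pts), .name_repair = "minimal")
  names(pcs) <- paste0("PC", seq_len(ncol(pts)))
  out <- dplyr::bind_cols(out, pcs)
  attr(out, "meta") <- meta
  class(out) <- c("ecog_pointset", class(out))
  out
}

# two gaussian clouds in d dimensions, second shifted along `dir`
two_cloud_ps <- function(n_per_class, d, shift, dir = NULL, seed = 1,
                         sd = 1) {
  withr::with_seed(seed, {
    dir <- dir %||% rep(1, d) / sqrt(d)
    a <- matrix(rnorm(n_per_class * d, sd = sd), n_per_class, d)
    b <- matrix(rnorm(n_per_class * d, sd = sd), n_per_class, d) +
      matrix(shift * dir, n_per_class, d, byrow = TRUE)
    make_ps(rbind(a, b), rep(c("evoked", "spont_pooled"), each = n_per_class))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive-search kNN oracle, written independently of the package:
# plain loops, explicit distance sort with index tie-break, explicit vote
oracle_knn <- function(train, labels, test, k) {
  labels <- factor(labels)
  lv <- levels(labels)
  li <- as.integer(labels)
  out <- character(nrow(test))
  for (i in seq_len(nrow(test))) {
    d <- numeric(nrow(train))
    for (j in seq_len(nrow(train))) {
      d[j] <- sum((train[j, ] - test[i, ])^2)
    }
    ord <- order(d, seq_along(d))
    nn <- ord[1:k]
    votes <- integer(length(lv))
    for (j in nn) votes[li[j]] <- votes[li[j]] + 1L
    best <- which(votes == max(votes))
    if (length(best) == 1L) {
      out[i] <- lv[best]
    } else {
      for (j in nn) {
        if (li[j] %in% best) {
          out[i] <- lv[li[j]]
          break
        }
      }
    }
  }
  factor(out, levels = lv)
}
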