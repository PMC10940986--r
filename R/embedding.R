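#' Fit a PCA embedding over channels
#'
#' Principal component analysis of the cross-channel activity distribution:
#' each time sample is a point in channel space and the components are the
#' eigenvectors of the channel covariance, in descending eigenvalue order.
#' All components are retained (full rank), so projection is a rotation, not
#' a reduction. The sign of each component is fixed deterministically so that
#' its largest-magnitude loading is positive.
#'
#' @param rec An [ecog_recording()] (typically artifact-interpolated and
#'   z-scored).
#' @param channel_subset Channel names to fit on (default: all). Subset fits
#'   are fresh decompositions of the retained channels' data -- the analysis
#'   variants that exclude electrodes re-fit the PCA rather than truncating
#'   the full-montage basis.
#' @param samples Optional integer vector of sample indices to fit on (e.g.
#'   one stimulation period plus its flanking spontaneous periods); default
#'   is the whole session.
#'
#' @return An object of class `ecog_pca`: list with `basis` (channels x
#'   components, orthonormal), `var_explained` (fractions summing to 1),
#'   `channel_subset`, `center` (per-channel means removed before fitting).
#' @export
fit_pca <- function(rec, channel_subset = NULL, samples = NULL) {
  stopifnot(inherits(rec, "ecog_recording"))
  channel_subset <- channel_subset %||% rec$channels$name
  if (length(channel_subset) < 1L) abort("`channel_subset` must be non-empty")
  missing <- setdiff(channel_subset, rec$channels$name)
  if (length(missing)) {
    abort(paste0("unknown channel(s): ", paste(missing, collapse = ", ")))
  }
  x <- rec$signal[channel_subset, , drop = FALSE]
  if (!is.null(samples)) x <- x[, samples, drop = FALSE]
  if (ncol(x) < length(channel_subset)) {
    abort("need at least as many samples as channels to fit the PCA")
  }
  pr <- prcomp(t(x), center = TRUE, scale. = FALSE)
  basis <- pr$rotation
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(basis))) {
    i <- which.max(abs(basis[, j]))
    if (basis[i, j] < 0) basis[, j] <- -basis[, j]
  }
  structure(
    list(
      basis = basis,
      var_explained = pr$sdev^2 / sum(pr$sdev^2),
      channel_subset = channel_subset,
      center = pr$center
    ),
    class = "ecog_pca"
  )
}

#' @export
print.ecog_pca <- function(x, ...) {
  cat(sprintf(
    "<ecog_pca> %d channels -> %d components\n",
    nrow(x$basis), ncol(x$basis)
  ))
  cat("var explained:",
      paste(sprintf("%.3f", x$var_explained), collapse = " "), "\n")
  invisible(x)
}

#' Project a recording onto a PCA basis
#'
#' Produces the score time series: for every sample, the coordinates of the
#' cross-channel activity vector in component space,
#' `scores = t(basis) %*% (signal - center)`. Sample timing is preserved 1:1.
#'
#' @param rec An [ecog_recording()] containing every channel of the embedding.
#' @param emb An `ecog_pca` from [fit_pca()].
#' @return An object of class `ecog_scores`: list with `scores` (components x
#'   samples), `fs_hz`, `t0_s` and `normalized` (FALSE).
#' @export
project_scores <- function(rec, emb) {
  stopifnot(inherits(rec, "ecog_recording"), inherits(emb, "ecog_pca"))
  missing <- setdiff(emb$channel_subset, rec$channels$name)
  if (length(missing)) {
    abort(paste0(
      "recording lacks channel(s) required by the embedding: ",
      paste(missing, collapse = ", ")
    ))
  }
  x <- rec$signal[emb$channel_subset, , drop = FALSE] - emb$center
  structure(
    list(
      scores = crossprod(emb$basis, x),
      fs_hz = rec$fs_hz,
      t0_s = rec$t0_s,
      normalized = FALSE
    ),
    class = "ecog_scores"
  )
}

#' @export
print.ecog_scores <- function(x, ...) {
  cat(sprintf(
    "<ecog_scores> %d components x %d samples at %g Hz%s\n",
    nrow(x$scores), ncol(x$scores), x$fs_hz,
    if (x$normalized) " (min-max normalized)" else ""
  ))
  invisible(x)
}

minmax_rows <- function(m) {
  for (j in seq_len(nrow(m))) {
    rng <- range(m[j, ])
    if (rng[1] == rng[2]) {
      m[j, ] <- 0.5  # constant component carries no information
    } else {
      m[j, ] <- (m[j, ] - rng[1]) / (rng[2] - rng[1])
    }
  }
  m
}

#' Min-max normalize score series per component
#'
#' Rescales each component's score series to \[0, 1\] so that no component is
#' given higher or lower weight in the nearest-neighbour analysis regardless
#' of its variance. A constant component maps to 0.5 everywhere.
#'
#' Note that [build_pointset()] applies the same rescaling over just the
#' points entering one analysis; this function normalizes a whole series (for
#' plots or for session-wide analyses).
#'
#' @param s An `ecog_scores` object from [project_scores()].
#' @return The series with each row spanning exactly \[0, 1\] and
#'   `normalized = TRUE`.
#' @export
minmax_normalize <- function(s) {
  stopifnot(inherits(s, "ecog_scores"))
  if (ncol(s$scores) == 0L) abort("score series is empty")
  s$scores <- minmax_rows(s$scores)
  s$normalized <- TRUE
  s
}
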