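# Statistical total correlation spectroscopy: correlation of intensities at
# one spectral position against all others across samples. Resonances of
# the same molecule co-vary with concentration and correlate near 1, which
# is what makes STOCSY useful for assignment.

# Resolve a ppm value to its (half-open) bin index.
.driver_bin <- function(fm, driver_ppm) {
  hit <- which(fm$bins$lo <= driver_ppm & driver_ppm < fm$bins$hi)
  if (length(hit) != 1L) {
    below <- max(fm$bins$hi[fm$bins$hi <= driver_ppm], -Inf)
    above <- min(fm$bins$lo[fm$bins$lo > driver_ppm], Inf)
    stop("driver ", driver_ppm, " ppm falls in no bin; nearest bin edges are ",
         below, " and ", above, " ppm")
  }
  hit
}

#' One-dimensional STOCSY from a driver resonance
#'
#' Pearson correlation and covariance of the driver bin's intensities
#' against every bin across samples. Computed on the normalized,
#' uncentered bin matrix (centering is implicit in Pearson correlation).
#'
#' @param fm a `feature_matrix` (uncentered).
#' @param driver_ppm chemical shift of the driver resonance; resolved to
#'   the bin whose interval contains it.
#' @return a `stocsy_result`: `driver_ppm`, `driver_bin`, data frame
#'   `profile` (`ppm`, `correlation`, `covariance`).
#' @export
stocsy_1d <- function(fm, driver_ppm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$X) < 3L) stop("STOCSY needs at least 3 samples")
  if (isTRUE(fm$centered)) fm <- uncenter(fm)
  j <- .driver_bin(fm, driver_ppm)
  d <- fm$X[, j]
  covs <- as.vector(stats::cov(fm$X, d))
  sds <- apply(fm$X, 2, stats::sd)
  corrs <- rep(0, ncol(fm$X))
  ok <- sds > 0
  corrs[ok] <- covs[ok] / (sds[ok] * stats::sd(d))
  structure(list(driver_ppm = driver_ppm, driver_bin = j,
                 profile = data.frame(ppm = fm$ppm, correlation = corrs,
                                      covariance = covs)),
            class = "stocsy_result")
}

#' Full feature-by-feature STOCSY correlation matrix
#'
#' @param fm a `feature_matrix`.
#' @param max_features guard against accidental huge allocations; restrict
#'   the ppm window or raise the cap for wider matrices.
#' @return symmetric correlation matrix with unit diagonal, dimnames =
#'   bin midpoints (ppm).
#' @export
stocsy_2d <- function(fm, max_features = 3000) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$X) < 3L) stop("STOCSY needs at least 3 samples")
  if (ncol(fm$X) > max_features) {
    stop(ncol(fm$X), " features exceed the cap of ", max_features,
         "; restrict the ppm window or raise max_features")
  }
  if (isTRUE(fm$centered)) fm <- uncenter(fm)
  R <- suppressWarnings(stats::cor(fm$X))  # zero-variance bins give NA
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  dimnames(R) <- list(fm$ppm, fm$ppm)
  R
}
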