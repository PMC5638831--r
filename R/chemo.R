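# Multivariate modelling: PCA, orthogonal signal correction, NIPALS PLS-DA,
# repeated two-fold cross-validated Q2Y, and permutation validation.

#' Principal component analysis of a centered feature matrix
#'
#' SVD-based PCA with a deterministic sign convention (the largest-magnitude
#' element of each loading vector is positive).
#'
#' @param fm a centered `feature_matrix` (or centered matrix).
#' @param k number of components, `1 <= k <= min(n - 1, p)`.
#' @return a `pca_model`: `scores` (n x k), `loadings` (p x k),
#'   `explained_variance_ratio`.
#' @export
pca <- function(fm, k) {
  X <- as_feature_X(fm)
  if (max(abs(colMeans(X))) > 1e-8 * (max(abs(X)) + 1e-300)) {
    stop("pca requires a mean-centered matrix; see mean_center()")
  }
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > kmax) {
    stop("k must be between 1 and min(n - 1, p) = ", kmax)
  }
  sv <- svd(X)
  evr <- sv$d^2 / sum(sv$d^2)
  V <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) V[, j] <- V[, j] * sign_convention(V[, j])
  scores <- X %*% V
  structure(list(scores = scores, loadings = V,
                 explained_variance_ratio = evr[seq_len(k)]),
            class = "pca_model")
}

#' Orthogonal signal correction
#'
#' Removes from a centered matrix `X` the dominant variation orthogonal to
#' class membership `Y`. Per component: start from the first principal
#' component score, project it onto the orthogonal complement of `Y`,
#' regress `X` onto the score for a weight vector, and iterate to
#' convergence; the converged, `Y`-orthogonalized score and its loading are
#' then deflated from `X`. The stored weights let the same correction be
#' applied to new (e.g. held-out) samples via [apply_osc()].
#'
#' @param X centered numeric matrix (samples x features).
#' @param Y class-membership (dummy) matrix, columns summing to group sizes;
#'   a factor or label vector is also accepted.
#' @param n_osc number of orthogonal components to remove.
#' @param tol relative convergence tolerance on the score vector.
#' @param max_iter iteration cap per component; non-convergence is flagged
#'   and reported, not fatal.
#' @return list with `X` (filtered matrix) and `filter` (an `osc_filter`:
#'   `weights`, `loadings`, `scores`, `r2x_removed`, `converged`,
#'   `iterations`).
#' @export
osc_filter <- function(X, Y, n_osc = 1, tol = 1e-8, max_iter = 100) {
  X <- as_feature_X(X)
  if (!is.matrix(Y)) Y <- class_matrix(Y)
  stopifnot(nrow(Y) == nrow(X), n_osc >= 1)
  ssx0 <- sum(X^2)
  if (ssx0 == 0) stop("X has no variance")
  # projector onto the orthogonal complement of col(Y)
  YtYinv <- solve(crossprod(Y))
  orth_y <- function(t) t - Y %*% (YtYinv %*% crossprod(Y, t))
  p <- ncol(X)
  W <- matrix(0, p, n_osc); P <- matrix(0, p, n_osc)
  Tm <- matrix(0, nrow(X), n_osc)
  conv <- logical(n_osc); iters <- integer(n_osc)
  r2x <- 0
  for (j in seq_len(n_osc)) {
    sv <- svd(X, nu = 1, nv = 0)
    t <- sv$u[, 1] * sv$d[1]
    for (it in seq_len(max_iter)) {
      t_orth <- orth_y(t)
      w <- crossprod(X, t_orth)
      nw <- sqrt(sum(w^2))
      if (nw == 0) break
      w <- w / nw
      t_new <- X %*% w
      delta <- sqrt(sum((t_new - t)^2) / sum(t_new^2))
      t <- t_new
      if (delta < tol) break
    }
    iters[j] <- it
    if (nw == 0 || sum(orth_y(X %*% w)^2) < 1e-10 * ssx0) {
      # no Y-orthogonal variation left: null component, nothing removed
      conv[j] <- TRUE
      next
    }
    conv[j] <- it < max_iter
    if (!conv[j]) {
      warning("OSC component ", j, " did not converge in ", max_iter,
              " iterations (last relative change ", signif(delta, 3), ")")
    }
    s <- sign_convention(w)
    w <- w * s
    t <- orth_y(X %*% w)  # guarantee orthogonality to Y exactly
    pj <- crossprod(X, t) / sum(t^2)
    X <- X - tcrossprod(t, pj)
    W[, j] <- w; P[, j] <- pj; Tm[, j] <- t
    r2x <- r2x + sum(t^2) * sum(pj^2) / ssx0
  }
  filter <- structure(list(n_removed = n_osc, weights = W, loadings = P,
                           scores = Tm, r2x_removed = r2x,
                           converged = conv, iterations = iters),
                      class = "osc_filter")
  list(X = X, filter = filter)
}

#' Apply a fitted OSC filter to new samples
#'
#' @param filter an `osc_filter` from [osc_filter()].
#' @param Xnew matrix centered with the training column means.
#' @return the corrected matrix.
#' @export
apply_osc <- function(filter, Xnew) {
  stopifnot(inherits(filter, "osc_filter"))
  for (j in seq_len(filter$n_removed)) {
    t <- Xnew %*% filter$weights[, j]
    Xnew <- Xnew - tcrossprod(t, filter$loadings[, j, drop = FALSE])
  }
  Xnew
}

# Minimal NIPALS PLS2 core: X deflated, Y not. Assumes X, Y centered.
# Returns weights W, X-loadings P, Y-loadings Q, scores T, coefficients B.
.nipals_pls <- function(X, Y, ncomp, tol = 1e-10, max_iter = 200) {
  p <- ncol(X); h <- ncol(Y); n <- nrow(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, h, ncomp); Tm <- matrix(0, n, ncomp)
  Xd <- X
  used <- 0L
  for (k in seq_len(ncomp)) {
    u <- Y[, which.max(colSums(Y^2))]
    t_old <- rep(0, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) break
      w <- w / nw
      tt <- Xd %*% w
      stt <- sum(tt^2)
      if (stt < 1e-300) break
      q <- crossprod(Y, tt) / stt
      u <- Y %*% q / sum(q^2)
      if (sum((tt - t_old)^2) <= tol^2 * stt) break
      t_old <- tt
    }
    if (nw < 1e-300 || sum(tt^2) < 1e-12 * sum(X^2) / n) break  # rank exhausted
    s <- sign_convention(as.vector(w))
    w <- w * s; tt <- tt * s
    stt <- sum(tt^2)
    pk <- crossprod(Xd, tt) / stt
    qk <- crossprod(Y, tt) / stt
    Xd <- Xd - tcrossprod(tt, pk)
    W[, k] <- w; P[, k] <- pk; Q[, k] <- qk; Tm[, k] <- tt
    used <- k
  }
  if (used == 0L) stop("PLS found no usable component (zero-variance X?)")
  idx <- seq_len(used)
  W <- W[, idx, drop = FALSE]; P <- P[, idx, drop = FALSE]
  Q <- Q[, idx, drop = FALSE]; Tm <- Tm[, idx, drop = FALSE]
  B <- W %*% solve(crossprod(P, W), t(Q))
  list(W = W, P = P, Q = Q, T = Tm, B = B, ncomp = used)
}

#' Fit a PLS-DA model (NIPALS, X-only deflation)
#'
#' Partial least squares regression of a dummy-coded class matrix on the
#' feature matrix, the discriminant workhorse applied after OSC filtering.
#' `X` and `Y` are centered internally (means stored); successive score
#' vectors are mutually orthogonal, and the training-data R2Y is
#' non-decreasing in the number of components.
#'
#' @param X feature matrix (samples x features) or `feature_matrix`.
#' @param y group labels (factor/character), or an uncentered dummy matrix.
#' @param ncomp number of PLS components.
#' @return a `plsda_model`: `x_weights`, `x_loadings`, `y_loadings`,
#'   `scores`, `coefficients`, `x_means`, `y_means`, `r2y` (cumulative per
#'   component), `groups`.
#' @export
plsda_fit <- function(X, y, ncomp = 2) {
  X <- as_feature_X(X)
  Y <- if (is.matrix(y)) y else class_matrix(y)
  stopifnot(nrow(Y) == nrow(X), ncomp >= 1)
  if (all(apply(X, 2, stats::var) == 0)) stop("X has zero variance")
  cx <- center_cols(X); cy <- center_cols(Y)
  fit <- .nipals_pls(cx$X, cy$X, ncomp)
  Yhat <- fit$T %*% t(fit$Q)
  sstot <- sum(cy$X^2)
  r2y <- vapply(seq_len(fit$ncomp), function(k) {
    Yk <- fit$T[, seq_len(k), drop = FALSE] %*%
      t(fit$Q[, seq_len(k), drop = FALSE])
    1 - sum((cy$X - Yk)^2) / sstot
  }, 0)
  structure(list(n_components = fit$ncomp, x_weights = fit$W,
                 x_loadings = fit$P, y_loadings = fit$Q, scores = fit$T,
                 coefficients = fit$B, x_means = cx$means,
                 y_means = cy$means, r2y = r2y,
                 groups = colnames(Y)),
            class = "plsda_model")
}

#' Predict class responses from a PLS-DA model
#'
#' @param object a `plsda_model`.
#' @param newdata matrix on the scale of the training data (uncentered).
#' @param ... unused.
#' @return list with `y` (predicted class-membership values) and `class`
#'   (argmax label).
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  newdata <- as_feature_X(newdata)
  Yhat <- sweep(newdata, 2L, object$x_means, "-") %*% object$coefficients
  Yhat <- sweep(Yhat, 2L, object$y_means, "+")
  colnames(Yhat) <- object$groups
  list(y = Yhat, class = object$groups[max.col(Yhat)])
}

# PRESS and SS contributions of one train/test split (centering, optional
# OSC and the PLS fit all confined to the training half).
.fold_press <- function(X, Y, train, test, ncomp, n_osc) {
  mx <- colMeans(X[train, , drop = FALSE])
  Xtr <- sweep(X[train, , drop = FALSE], 2L, mx, "-")
  Xte <- sweep(X[test, , drop = FALSE], 2L, mx, "-")
  if (n_osc > 0) {
    o <- suppressWarnings(
      osc_filter(Xtr, Y[train, , drop = FALSE], n_osc = n_osc))
    Xtr <- o$X
    Xte <- apply_osc(o$filter, Xte)
  }
  my <- colMeans(Y[train, , drop = FALSE])
  Ytr <- sweep(Y[train, , drop = FALSE], 2L, my, "-")
  fit <- .nipals_pls(Xtr, Ytr, ncomp)
  Yte_c <- sweep(Y[test, , drop = FALSE], 2L, my, "-")
  c(press = sum((Yte_c - Xte %*% fit$B)^2), ss = sum(Yte_c^2))
}

# Stratified fold assignment: within each group, samples are shuffled and
# dealt round-robin into `folds` folds.
.stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (g in unique(y)) {
    idx <- sample(which(y == g))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

# Core Q2Y computation; assumes the RNG state is already set.
.q2_core <- function(X, Y, ylab, ncomp, repeats, folds, n_osc) {
  press <- 0; ss <- 0
  for (r in seq_len(repeats)) {
    fa <- .stratified_folds(ylab, folds)
    for (f in seq_len(folds)) {
      test <- which(fa == f)
      ps <- .fold_press(X, Y, which(fa != f), test, ncomp, n_osc)
      press <- press + ps[["press"]]
      ss <- ss + ps[["ss"]]
    }
  }
  1 - press / ss
}

#' Cross-validated Q2Y by repeated stratified two-fold cross-validation
#'
#' The data are split repeatedly into `folds` stratified folds; each held-out
#' fold is predicted by a model fit on the rest (mean-centering and, if
#' requested, OSC are re-fit inside the training fold only, so no
#' information leaks into the held-out samples). PRESS is pooled over all
#' repeats and folds: Q2Y = 1 - PRESS / SS_total. Values above 0.5 are the
#' conventional threshold for a significant group difference.
#'
#' @param X feature matrix or `feature_matrix`.
#' @param y group labels.
#' @param ncomp PLS components.
#' @param repeats number of random fold assignments.
#' @param folds folds per repeat (2 = the classical repeated 2CV).
#' @param seed RNG seed (determinism: same seed, same Q2Y).
#' @param n_osc OSC components re-fit inside each training fold (0 = none).
#' @return the pooled Q2Y (scalar).
#' @export
cross_validate_q2 <- function(X, y, ncomp = 2, repeats = 50, folds = 2,
                              seed = 1, n_osc = 0) {
  X <- as_feature_X(X)
  ylab <- as.character(y)
  if (min(table(ylab)) < folds) {
    stop("every group needs at least `folds` = ", folds, " members")
  }
  Y <- class_matrix(ylab)
  set.seed(as.integer(seed))
  .q2_core(X, Y, ylab, ncomp, repeats, folds, n_osc)
}

#' Permutation test of an (OSC-)PLS-DA model
#'
#' The validation statistic is the cross-validated Q2Y (with a reduced
#' number of CV repeats per permutation to keep thousands of permutations
#' tractable). Group labels are permuted without replacement `n_perm` times
#' and the statistic recomputed each time; the empirical p-value is
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`, which cannot reach zero and
#' whose floor at 2000 permutations is 1/2001 (about 5e-04). The full-data
#' R2Y and a higher-repeat Q2Y are reported alongside.
#'
#' @param X feature matrix or `feature_matrix`.
#' @param y group labels.
#' @param ncomp PLS components.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param n_osc OSC components (re-fit within CV training folds).
#' @param cv_repeats CV repeats used for the statistic (observed and
#'   permuted alike, so the comparison is like-for-like).
#' @param full_repeats CV repeats for the reported headline Q2Y.
#' @param folds CV folds.
#' @return a `model_validation`: `r2y`, `q2y`, `observed_stat`, `p_perm`,
#'   `null_stats`, `n_perm`, `cv_repeats`, `folds`.
#' @export
permutation_test <- function(X, y, ncomp = 2, n_perm = 2000, seed = 1,
                             n_osc = 0, cv_repeats = 7, full_repeats = 50,
                             folds = 2) {
  X <- as_feature_X(X)
  stopifnot(n_perm >= 1)
  ylab <- as.character(y)
  Y <- class_matrix(ylab)
  set.seed(as.integer(seed))
  observed <- .q2_core(X, Y, ylab, ncomp, cv_repeats, folds, n_osc)
  null_stats <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yp <- sample(ylab)
    null_stats[b] <- .q2_core(X, class_matrix(yp), yp, ncomp, cv_repeats,
                              folds, n_osc)
  }
  p_perm <- (1 + sum(null_stats >= observed)) / (n_perm + 1)
  q2y <- .q2_core(X, Y, ylab, ncomp, full_repeats, folds, n_osc)
  # headline R2Y on the full data (after full-data OSC when enabled)
  Xc <- center_cols(X)$X
  if (n_osc > 0) Xc <- suppressWarnings(osc_filter(Xc, ylab, n_osc))$X
  r2y <- utils::tail(plsda_fit(Xc, ylab, ncomp)$r2y, 1)
  structure(list(r2y = r2y, q2y = q2y, observed_stat = observed,
                 p_perm = p_perm, null_stats = null_stats, n_perm = n_perm,
                 cv_repeats = cv_repeats, folds = folds),
            class = "model_validation")
}

#' @export
print.model_validation <- function(x, ...) {
  cat(sprintf("<model_validation> R2Y = %.3f, Q2Y = %.3f, p(perm) = %.4g (%d permutations, %d-fold CV x %d repeats)\n",
              x$r2y, x$q2y, x$p_perm, x$n_perm, x$folds, x$cv_repeats))
  invisible(x)
}

#' S-plot: covariance vs correlation of each feature with the first score
#'
#' For each feature j, `cov_j = cov(t1, X_j)` and `corr_j = corr(t1, X_j)`
#' where t1 is the first predictive PLS score. Features in the upper-right
#' (high covariance, high correlation) are influential and reliable.
#' Zero-variance features get correlation 0 with a warning.
#'
#' @param model a `plsda_model` fit on `X`.
#' @param X the matrix the model was fit on (or `feature_matrix`).
#' @return data frame with `feature`, `covariance`, `correlation`.
#' @export
splot <- function(model, X) {
  stopifnot(inherits(model, "plsda_model"))
  X <- as_feature_X(X)
  t1 <- model$scores[, 1]
  covs <- as.vector(stats::cov(X, t1))
  sds <- apply(X, 2, stats::sd)
  corrs <- rep(0, ncol(X))
  zero <- sds == 0
  if (any(zero)) warning(sum(zero), " zero-variance feature(s); correlation set to 0")
  corrs[!zero] <- covs[!zero] / (sds[!zero] * stats::sd(t1))
  data.frame(feature = colnames(X) %||% seq_len(ncol(X)),
             covariance = covs, correlation = corrs)
}

#' Two-sided Pearson critical value |r| at level alpha
#' @param n sample size (>= 4).
#' @param alpha significance level.
#' @return the critical |r| with n - 2 degrees of freedom.
#' @export
pearson_critical_r <- function(n, alpha = 0.05) {
  if (n < 4) stop("need n >= 4 for a useful critical value")
  df <- n - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  tcrit / sqrt(tcrit^2 + df)
}

#' Correlation-coded loading pseudo-spectrum
#'
#' Per-feature covariance with the first predictive score (the "height" of
#' the pseudo-spectrum, on the back-scaled intensity axis) colored by the
#' absolute correlation, with a significance flag at the Pearson critical
#' |r| for `alpha` and n - 2 df. Rendering is restricted to the configured
#' ppm windows (default 0.4-4.3 and 5.7-9.4 ppm, skipping the water gap).
#'
#' @param model a `plsda_model`.
#' @param fm the `feature_matrix` the model was fit on (provides ppm).
#' @param alpha significance level for the correlation cutoff.
#' @param windows list of `c(lo, hi)` ppm windows to render.
#' @return data frame `ppm`, `covariance`, `correlation`, `abs_correlation`,
#'   `significant`; attribute `cutoff` carries the critical |r|.
#' @export
correlation_loadings <- function(model, fm, alpha = 0.05,
                                 windows = list(c(0.4, 4.3), c(5.7, 9.4))) {
  stopifnot(inherits(fm, "feature_matrix"))
  n <- nrow(fm$X)
  cutoff <- pearson_critical_r(n, alpha)
  sp <- splot(model, fm$X)
  df <- data.frame(ppm = fm$ppm, covariance = sp$covariance,
                   correlation = sp$correlation,
                   abs_correlation = abs(sp$correlation))
  df$significant <- df$abs_correlation > cutoff
  keep <- Reduce(`|`, lapply(windows, function(w) df$ppm >= w[1] & df$ppm <= w[2]))
  df <- df[keep, ]
  attr(df, "cutoff") <- cutoff
  df
}
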