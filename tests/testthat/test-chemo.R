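# PCA, OSC, PLS-DA, cross-validated Q2Y and permutation validation.

test_that("pca matches an eigendecomposition oracle and reconstructs exactly", {
  set.seed(11)
  Xc <- scale(matrix(rnorm(100), 10, 10), scale = FALSE)
  pm <- wormetab::pca(Xc, 3)
  ev <- eigen(crossprod(Xc))
  oracle_scores <- Xc %*% ev$vectors[, 1:3]
  for (k in 1:3) {
    d <- min(max(abs(pm$scores[, k] - oracle_scores[, k])),
             max(abs(pm$scores[, k] + oracle_scores[, k])))
    expect_lt(d, 1e-8)
  }
  # completeness: all components reconstruct X
  Xr <- scale(matrix(rnorm(20 * 50), 20, 50), scale = FALSE)
  pf <- wormetab::pca(Xr, 19)
  expect_lt(max(abs(pf$scores %*% t(pf$loadings) - Xr)), 1e-8)
  # rank-1 matrix: first component explains everything
  X1 <- scale(outer(rnorm(8), rnorm(6)), scale = FALSE)
  expect_equal(wormetab::pca(X1, 1)$explained_variance_ratio[1], 1,
               tolerance = 1e-10)
  expect_error(wormetab::pca(Xc, 12), "between 1 and")
  expect_error(wormetab::pca(matrix(1:9, 3), 1), "centered")
})

test_that("pca explained ratios are non-increasing and loadings orthonormal", {
  set.seed(12)
  Xc <- scale(matrix(rnorm(15 * 30), 15, 30), scale = FALSE)
  pm <- wormetab::pca(Xc, 5)
  expect_true(all(diff(pm$explained_variance_ratio) <= 1e-12))
  G <- crossprod(pm$loadings)
  expect_lt(max(abs(G - diag(5))), 1e-8)
})

test_that("OSC-removed scores are orthogonal to class membership", {
  set.seed(21)
  for (rep in 1:5) {
    X <- scale(matrix(rnorm(20 * 30), 20, 30), scale = FALSE)
    y <- rep(c("A", "B"), each = 10)
    o <- suppressWarnings(osc_filter(X, y, n_osc = 2))
    Y <- wormetab:::class_matrix(y)
    for (j in 1:2) {
      t <- o$filter$scores[, j]
      expect_lt(sqrt(sum(crossprod(Y, t)^2)) /
                  (sqrt(sum(t^2)) * norm(Y, "F") + 1e-300), 1e-6)
    }
    expect_gte(o$filter$r2x_removed, 0)
    expect_lt(o$filter$r2x_removed, 1)
    # OSC never increases the Frobenius norm
    expect_lte(sum(o$X^2), sum(X^2) + 1e-10)
  }
})

test_that("OSC removes nothing when X is an exact function of class", {
  set.seed(22)
  y <- rep(c("A", "B"), each = 8)
  d <- ifelse(y == "A", 1, -1)
  X <- outer(d, rnorm(25)) + matrix(rnorm(16 * 25, 0, 1e-4), 16, 25)
  Xc <- scale(X, scale = FALSE)
  o <- suppressWarnings(osc_filter(Xc, y))
  expect_lt(o$filter$r2x_removed, 0.05)
  q_before <- cross_validate_q2(Xc, y, 1, repeats = 10, seed = 1)
  q_after <- cross_validate_q2(o$X, y, 1, repeats = 10, seed = 1)
  expect_lt(abs(q_after - q_before), 0.05)
})

test_that("OSC captures a strong class-orthogonal confounder", {
  hits <- vapply(1:10, function(sd) {
    set.seed(600 + sd)
    n <- 20; p <- 40
    y <- rep(c("A", "B"), each = n / 2)
    d <- ifelse(y == "A", 1, -1)
    conf <- rnorm(n)
    conf <- conf - mean(conf)
    conf <- conf - d * sum(conf * d) / sum(d * d)  # orthogonal to class
    X <- outer(d, c(rep(1, 5), rep(0, p - 5))) +
      8 * outer(conf, rnorm(p)) + matrix(rnorm(n * p, 0, 0.3), n, p)
    Xc <- scale(X, scale = FALSE)
    o <- suppressWarnings(osc_filter(Xc, y))
    r_conf <- abs(cor(o$filter$scores[, 1], conf))
    q_before <- cross_validate_q2(Xc, y, 1, repeats = 10, seed = 1)
    q_after <- cross_validate_q2(Xc, y, 1, repeats = 10, seed = 1, n_osc = 1)
    (r_conf > 0.95) && (q_after > q_before)
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("PLS-DA separable case reaches R2Y = 1 and R2Y is monotone in k", {
  y <- rep(c("A", "B"), each = 6)
  X <- cbind(ifelse(y == "A", 1, -1), matrix(0, 12, 4))
  fit <- plsda_fit(X, y, 1)
  expect_equal(utils::tail(fit$r2y, 1), 1, tolerance = 1e-6)

  set.seed(31)
  Xr <- matrix(rnorm(12 * 10), 12, 10)
  fr <- plsda_fit(Xr, y, 4)
  expect_true(all(diff(fr$r2y) >= -1e-10))
  # successive scores mutually orthogonal
  G <- crossprod(fr$scores)
  expect_lt(max(abs(G - diag(diag(G)))) / max(diag(G)), 1e-8)
  expect_error(plsda_fit(matrix(1, 8, 3), rep(c("A", "B"), each = 4)),
               "zero variance")
})

test_that("PLS-DA agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(32)
  X <- matrix(rnorm(12 * 8), 12, 8, dimnames = list(NULL, paste0("v", 1:8)))
  y <- rep(c("A", "B"), each = 6)
  fit <- plsda_fit(X, y, 2)
  mine <- predict(fit, X)$y
  Y <- wormetab:::class_matrix(y)
  mo <- mixOmics::pls(X, Y, ncomp = 2, scale = FALSE, mode = "regression")
  oracle <- predict(mo, X)$predict[, , 2]
  expect_lt(max(abs(mine - oracle)), 1e-6)
})

test_that("Q2Y is deterministic, high for strong effects, low for null labels", {
  set.seed(41)
  y <- rep(c("A", "B"), each = 10)
  d <- ifelse(y == "A", 1, -1)
  X <- outer(d, c(rep(4, 10), rep(0, 50))) +
    matrix(rnorm(20 * 60, 0, 0.5), 20, 60)
  q1 <- cross_validate_q2(X, y, 2, repeats = 20, seed = 7)
  q2 <- cross_validate_q2(X, y, 2, repeats = 20, seed = 7)
  expect_identical(q1, q2)
  expect_gt(q1, 0.5)

  qn <- vapply(1:5, function(sd) {
    set.seed(700 + sd)
    cross_validate_q2(matrix(rnorm(16 * 60), 16, 60),
                      rep(c("A", "B"), each = 8), 1, repeats = 20, seed = 1)
  }, 0)
  expect_lte(mean(qn), 0.05)
  expect_error(cross_validate_q2(X, c(rep("A", 19), "B"), 1),
               "at least")
})

test_that("Q2Y never exceeds R2Y", {
  set.seed(42)
  for (rep in 1:3) {
    n <- 16; p <- 25
    y <- rep(c("A", "B"), each = n / 2)
    X <- outer(ifelse(y == "A", 1, -1), rnorm(p)) +
      matrix(rnorm(n * p, 0, runif(1, 0.5, 3)), n, p)
    r2 <- utils::tail(plsda_fit(X, y, 2)$r2y, 1)
    q2 <- cross_validate_q2(X, y, 2, repeats = 20, seed = rep)
    expect_lte(q2, r2)
  }
})

test_that("permutation p follows the (b + 1) / (n + 1) rule", {
  set.seed(51)
  y <- rep(c("A", "B"), each = 6)
  X <- matrix(rnorm(12 * 15), 12, 15)
  mv <- permutation_test(X, y, 1, n_perm = 19, seed = 3, cv_repeats = 3,
                         full_repeats = 5)
  expect_equal(mv$p_perm,
               (1 + sum(mv$null_stats >= mv$observed_stat)) / (19 + 1))
  expect_length(mv$null_stats, 19)
  expect_gte(mv$p_perm, 1 / 20)
  expect_lte(mv$p_perm, 1)
  # n_perm = 1 with a null at least as good as the observed gives p = 1
  mv1 <- permutation_test(X, y, 1, n_perm = 1, seed = 4, cv_repeats = 3,
                          full_repeats = 3)
  if (mv1$null_stats[1] >= mv1$observed_stat) expect_equal(mv1$p_perm, 1)
})

test_that("S-plot covariance and correlation share signs; driver feature has r = 1", {
  set.seed(61)
  y <- rep(c("A", "B"), each = 8)
  X <- outer(ifelse(y == "A", 1, -1), rnorm(12)) +
    matrix(rnorm(16 * 12, 0, 0.4), 16, 12)
  fit <- plsda_fit(X, y, 1)
  X2 <- cbind(t1 = fit$scores[, 1], X, flat = rep(1, 16))
  expect_warning(sp <- splot(fit, X2), "zero-variance")
  expect_equal(sp$correlation[1], 1, tolerance = 1e-10)
  expect_equal(sp$correlation[ncol(X2)], 0)
  nz <- sp$correlation != 0
  expect_true(all(sign(sp$covariance[nz]) == sign(sp$correlation[nz])))
})

test_that("pure-noise features rarely exceed the null correlation bound", {
  # at n = 50 a noise feature uninvolved in the fit passes |r| = 0.4 with
  # probability < 1%
  set.seed(62)
  y <- rep(c("A", "B"), each = 25)
  Xsig <- outer(ifelse(y == "A", 1, -1), rep(1, 5)) +
    matrix(rnorm(50 * 5, 0, 0.3), 50, 5)
  fit <- plsda_fit(Xsig, y, 1)
  noise <- matrix(rnorm(50 * 200), 50, 200)
  corrs <- splot(fit, cbind(Xsig, noise))$correlation[-(1:5)]
  expect_gte(mean(abs(corrs) < 0.4), 0.98)
})

test_that("correlation loading cutoff matches the t-inversion and windows apply", {
  expect_equal(pearson_critical_r(10, 0.05), 0.632, tolerance = 5e-4)
  # oracle: r = t / sqrt(t^2 + df)
  tcrit <- qt(0.975, 8)
  expect_equal(pearson_critical_r(10, 0.05), tcrit / sqrt(tcrit^2 + 8),
               tolerance = 1e-12)
  expect_error(pearson_critical_r(3), "n >= 4")

  set.seed(63)
  y <- rep(c("A", "B"), each = 5)
  fm <- toy_feature_matrix(matrix(rnorm(10 * 40), 10, 40),
                           mids = seq(0.5, 9.5, length.out = 40),
                           groups = y)
  fit <- plsda_fit(fm$X, y, 1)
  cl <- correlation_loadings(fit, fm)
  expect_false(any(cl$ppm > 4.3 & cl$ppm < 5.7))
  expect_true(all(cl$significant == (cl$abs_correlation >
                                       attr(cl, "cutoff"))))
})
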