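# Import, exclusion, adaptive binning, PQN and centering.

test_that("read_spectra reports malformed rows, missing files and duplicates", {
  dir <- withr::local_tempdir()
  writeLines(c("1.0 5.0", "2.0 6.0", "not a number", "4.0 8.0"),
             file.path(dir, "bad.txt"))
  writeLines(c("1.0 5.0", "2.0 6.0"), file.path(dir, "ok.txt"))

  write.csv(data.frame(sample_id = "s1", group = "A", file = "bad.txt"),
            file.path(dir, "m1.csv"), row.names = FALSE)
  expect_error(read_spectra(file.path(dir, "m1.csv")), "line 3")

  write.csv(data.frame(sample_id = "s1", group = "A", file = "gone.txt"),
            file.path(dir, "m2.csv"), row.names = FALSE)
  expect_error(read_spectra(file.path(dir, "m2.csv")), "gone.txt")

  write.csv(data.frame(sample_id = c("s1", "s1"), group = "A",
                       file = "ok.txt"),
            file.path(dir, "m3.csv"), row.names = FALSE)
  expect_error(read_spectra(file.path(dir, "m3.csv")), "duplicate")
})

test_that("spectra on offset axes are resampled with the integral preserved", {
  dir <- withr::local_tempdir()
  ppm <- seq(0, 10, length.out = 4096)
  y <- dcauchy(ppm, 5, 0.05) + dcauchy(ppm, 2, 0.1)
  step <- diff(ppm)[1]
  ppm2 <- ppm + step / 2  # half a grid step off
  y2 <- dcauchy(ppm2, 5, 0.05) + dcauchy(ppm2, 2, 0.1)
  write.table(data.frame(ppm, y), file.path(dir, "a.txt"),
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(ppm2, y2), file.path(dir, "b.txt"),
              row.names = FALSE, col.names = FALSE)
  write.csv(data.frame(sample_id = c("a", "b"), group = "G",
                       file = c("a.txt", "b.txt")),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  set <- read_spectra(file.path(dir, "manifest.csv"))
  expect_equal(set$ppm, ppm)  # first spectrum's axis wins
  i1 <- pracma::trapz(set$ppm, set$X[1, ])
  i2 <- pracma::trapz(set$ppm, set$X[2, ])
  expect_lt(abs(i2 - i1) / i1, 0.005)
})

test_that("exclude_region drops the water band and validates its arguments", {
  set <- flat_spectra_set()
  out <- exclude_region(set, 4.70, 5.25)
  expect_false(any(out$ppm >= 4.70 & out$ppm <= 5.25))
  expect_equal(out$excluded_regions, list(c(4.70, 5.25)))
  expect_equal(ncol(out$X), length(out$ppm))

  expect_error(exclude_region(set, 5.25, 4.70), "lo < hi")
  expect_identical(exclude_region(set, -1, -0.5), set)  # outside axis: no-op
  expect_error(exclude_region(set, -1, 11), "whole axis")
})

test_that("baseline offsets are estimated and removed", {
  set <- flat_spectra_set(0)
  set$X[1, ] <- set$X[1, ] + 0.7
  set$X[2, ] <- set$X[2, ] - 0.3
  out <- correct_baseline(set)
  expect_equal(unname(out$baseline_offsets), c(0.7, -0.3), tolerance = 1e-12)
  expect_equal(max(abs(out$X)), 0)
})

test_that("adaptive binning of a flat spectrum gives uniform bins at the target width", {
  set <- exclude_region(flat_spectra_set(), 4.70, 5.25)
  bt <- adaptive_bin(set, 0.2, 8.8, 0.015)
  # (4.5 + 3.55) / 0.015 ~ 537 uniform bins
  expect_gte(nrow(bt$bins), 535)
  expect_lte(nrow(bt$bins), 539)
  w <- bt$bins$hi - bt$bins$lo
  expect_true(mean(w) > 0.5 * 0.015 && mean(w) < 2 * 0.015)
  # repeated call identical
  expect_identical(bt$bins, adaptive_bin(set, 0.2, 8.8, 0.015)$bins)
  expect_error(adaptive_bin(set, 3.0, 3.0001), "fewer than 8")
})

test_that("a bin boundary falls in the valley between two separated peaks", {
  ppm <- seq(0, 10, length.out = 2^14)
  gamma <- 0.004
  y <- dcauchy(ppm, 3.00, gamma) + dcauchy(ppm, 3.10, gamma)
  set <- structure(list(ppm = ppm, X = rbind(y, y),
                        manifest = data.frame(sample_id = c("a", "b"),
                                              group = "G"),
                        excluded_regions = list()),
                   class = "spectra_set")
  bt <- adaptive_bin(set, 2.5, 3.6, 0.015)
  edges <- c(bt$bins$lo, bt$bins$hi[nrow(bt$bins)])
  expect_true(any(edges > 3.03 & edges < 3.07))
  # each peak's mass is captured >= 95% by bins on its own side of 3.05;
  # oracle: the analytic Lorentzian CDF
  left <- bt$bins$hi <= 3.05 + 1e-9
  got_left <- sum(bt$X[1, left])
  want_left <- (pcauchy(3.05, 3.00, gamma) - pcauchy(2.5, 3.00, gamma)) +
    (pcauchy(3.05, 3.10, gamma) - pcauchy(2.5, 3.10, gamma))
  expect_gt(got_left / want_left, 0.95)
})

test_that("binning conserves the total integral over the binned range", {
  sim <- two_group_sim(seed = 2, n = 2, n_met = 8)
  set <- exclude_region(sim$spectra, 4.70, 5.25)
  bt <- adaptive_bin(set)
  for (i in 1:2) {
    keep1 <- set$ppm >= 0.2 & set$ppm <= 4.70
    keep2 <- set$ppm >= 5.25 & set$ppm <= 8.8
    want <- pracma::trapz(set$ppm[keep1], set$X[i, keep1]) +
      pracma::trapz(set$ppm[keep2], set$X[i, keep2])
    expect_lt(abs(sum(bt$X[i, ]) - want) / abs(want), 1e-6)
  }
})

test_that("no bin intersects an excluded region", {
  sim <- two_group_sim(seed = 3, n = 2, n_met = 8)
  set <- exclude_region(sim$spectra, 4.70, 5.25)
  set <- exclude_region(set, 2.0, 2.2)
  bt <- adaptive_bin(set)
  for (r in list(c(4.70, 5.25), c(2.0, 2.2))) {
    expect_false(any(bt$bins$lo < r[2] - 1e-9 & bt$bins$hi > r[1] + 1e-9))
  }
})

test_that("PQN quotients are analytic on constructed samples", {
  ref <- c(1, 2, 3, 4, 5)
  bt <- toy_bin_table(rbind(3 * ref, ref, 0.5 * ref))
  fm <- pqn_normalize(bt, reference = ref)
  expect_equal(unname(fm$quotients), c(3, 1, 0.5), tolerance = 1e-12)
  # after normalization every sample equals the reference
  expect_equal(unname(fm$X[1, ]), ref, tolerance = 1e-12)
  expect_error(pqn_normalize(toy_bin_table(rbind(ref, 0 * ref)),
                             reference = ref), "all zero")
})

test_that("PQN with a frozen reference is an exact fixed point", {
  set.seed(1)
  X <- exp(matrix(rnorm(60, 0, 0.3), 6, 10)) *
    rep(exp(rnorm(6, 0, 0.5)), 10)
  ref <- apply(X, 2, median)
  fm1 <- pqn_normalize(toy_bin_table(X), reference = ref)
  fm2 <- pqn_normalize(fm1, reference = ref)
  expect_equal(fm1$X, fm2$X, tolerance = 1e-12)
})

test_that("re-normalizing an already PQN-normalized matrix is a near no-op", {
  set.seed(4)
  base <- exp(rnorm(40, 0, 1))
  X <- outer(exp(rnorm(12, 0, 0.5)), base) *
    exp(matrix(rnorm(12 * 40, 0, 0.05), 12, 40))
  fm1 <- pqn_normalize(toy_bin_table(X))
  fm2 <- pqn_normalize(fm1)
  # residual re-normalization factors stay within a few percent of 1
  expect_lt(max(abs(fm2$quotients - 1)), 0.05)
  # with no within-sample variation at all the factors are exactly 1
  X0 <- outer(c(2, 0.5, 1, 3), base)
  fm0 <- pqn_normalize(toy_bin_table(X0))
  expect_equal(unname(pqn_normalize(fm0)$quotients), rep(1, 4),
               tolerance = 1e-12)
})

test_that("PQN recovers simulated dilution factors", {
  rho <- vapply(1:3, function(sd) {
    sim <- simulate_study(
      default_library(12),
      study_design(c(A = 10, B = 10), dilution_sd_log = 0.3,
                   seed = 500 + sd))
    fm <- preprocess_sim(sim)
    cor(fm$quotients, sim$truth$dilutions, method = "spearman")
  }, 0)
  expect_true(all(rho > 0.95))
})

test_that("mean centering is exact, reversible and guarded", {
  fm <- toy_feature_matrix(rbind(c(1, 5), c(3, 7)))
  cf <- mean_center(fm)
  expect_equal(unname(cf$X[, 1]), c(-1, 1))
  expect_lt(max(abs(colSums(cf$X))), 1e-10 * max(abs(fm$X)))
  back <- uncenter(cf)
  expect_equal(back$X, fm$X, tolerance = 1e-12)
  expect_error(mean_center(cf), "already centered")
  expect_error(mean_center(toy_feature_matrix(matrix(1:3, 1))),
               "single-sample")
})
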