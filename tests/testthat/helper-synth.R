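# Shared fixtures, all generated in code.

# Simulate -> baseline-correct -> water-exclude -> bin -> PQN.
preprocess_sim <- function(sim, lo = 0.2, hi = 8.8) {
  s <- correct_baseline(sim$spectra)
  s <- exclude_region(s, 4.70, 5.25)
  pqn_normalize(adaptive_bin(s, lo, hi))
}

# A small two-group study with designated affected metabolites.
two_group_sim <- function(seed, effects = list(lactate = c(EXP = 4)),
                          n = 10, n_met = 12, ...) {
  lib <- default_library(n_met)
  des <- study_design(stats::setNames(c(n, n), c("CON", "EXP")),
                      effects = effects, seed = seed, ...)
  simulate_study(lib, des)
}

# Hand-built bin_table for analytic normalization tests.
toy_bin_table <- function(X, mids = seq_len(ncol(X))) {
  structure(list(
    bins = data.frame(lo = mids - 0.5, hi = mids + 0.5, mid = mids),
    X = X,
    manifest = data.frame(sample_id = rownames(X) %||%
                            paste0("s", seq_len(nrow(X))),
                          group = "G"),
    excluded_regions = list()), class = "bin_table")
}

# Hand-built feature_matrix (already "normalized").
toy_feature_matrix <- function(X, mids = seq_len(ncol(X)),
                               groups = rep("G", nrow(X))) {
  structure(list(
    X = X, ppm = mids,
    bins = data.frame(lo = mids - 0.5, hi = mids + 0.5, mid = mids),
    quotients = rep(1, nrow(X)),
    manifest = data.frame(sample_id = paste0("s", seq_len(nrow(X))),
                          group = groups),
    centered = FALSE, col_means = NULL), class = "feature_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flat (constant-intensity) spectra set over 0-10 ppm.
flat_spectra_set <- function(value = 1, n_points = 2^14) {
  ppm <- seq(0, 10, length.out = n_points)
  structure(list(ppm = ppm,
                 X = rbind(rep(value, n_points), rep(value, n_points)),
                 manifest = data.frame(sample_id = c("a", "b"), group = "G"),
                 excluded_regions = list()),
            class = "spectra_set")
}
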