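# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' A single master seed spawns independent named substreams (concentrations,
#' dilutions, jitter, noise, ...) so that enabling or disabling one noise
#' source does not perturb the draws of the others. The mapping is a fixed
#' integer hash; it is deterministic across platforms and stays within the
#' 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed master integer seed.
#' @param name character stream label.
#' @return an integer seed.
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

# Dummy-code a grouping vector into a class-membership matrix whose columns
# sum to the group sizes.
class_matrix <- function(y) {
  f <- factor(y)
  Y <- stats::model.matrix(~ 0 + f)
  colnames(Y) <- levels(f)
  rownames(Y) <- names(y)
  Y
}

# Column-center a matrix, returning the centered matrix and the means.
center_cols <- function(X) {
  mu <- colMeans(X)
  list(X = sweep(X, 2L, mu, "-"), means = mu)
}

# Evaluate the cumulative trapezoidal integral of y over x at arbitrary
# positions (linear interpolation between grid points, so integrals over
# adjacent intervals are exactly additive).
cum_integral_at <- function(x, y, at) {
  ct <- c(0, pracma::cumtrapz(x, y))[-1]
  stats::approx(x, ct, xout = at, rule = 2)$y
}

# Extract the numeric matrix from a feature_matrix / bin_table / matrix.
as_feature_X <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "feature_matrix") || inherits(x, "bin_table")) return(x$X)
  stop("cannot extract a sample x feature matrix from an object of class ",
       paste(class(x), collapse = "/"))
}

# Deterministic sign convention: flip a vector so that its largest-magnitude
# element is positive. Returns +1 or -1.
sign_convention <- function(v) {
  s <- sign(v[which.max(abs(v))])
  if (s == 0) 1 else s
}
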