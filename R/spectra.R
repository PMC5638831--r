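# Spectral preprocessing: import, water-region exclusion, adaptive binning,
# probability quotient normalization, mean-centering.

#' Read a set of 1D spectra listed in a manifest
#'
#' The manifest CSV must carry columns `sample_id`, `group`, `file` (paths
#' relative to the manifest unless absolute); optional columns (dose, soil,
#' ...) are kept. Each spectrum file is two-column ASCII (ppm, intensity).
#' Spectra whose axes differ from the first spectrum's are resampled onto it
#' by linear interpolation. The axis is stored ascending internally
#' (descending is only a rendering convention).
#'
#' @param manifest_path path to the manifest CSV.
#' @return a `spectra_set`.
#' @export
read_spectra <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path)
  }
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "file")
  if (!all(need %in% names(manifest))) {
    stop("manifest ", manifest_path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  dup <- manifest$sample_id[duplicated(manifest$sample_id)]
  if (length(dup)) {
    stop("duplicate sample_id in ", manifest_path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  root <- dirname(manifest_path)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", manifest$file), manifest$file,
                  file.path(root, manifest$file))
  axis <- NULL
  X <- NULL
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i])) {
      stop("spectrum file missing for sample ", manifest$sample_id[i], ": ",
           paths[i])
    }
    lines <- readLines(paths[i])
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[,;[:space:]]+")
    bad <- which(vapply(parts, function(p) {
      length(p) != 2L || anyNA(suppressWarnings(as.numeric(p)))
    }, logical(1)))
    if (length(bad)) {
      stop("non-numeric or malformed row in ", paths[i], " at line ", bad[1])
    }
    ppm <- vapply(parts, function(p) as.numeric(p[1]), 0)
    y <- vapply(parts, function(p) as.numeric(p[2]), 0)
    o <- order(ppm)
    ppm <- ppm[o]; y <- y[o]
    if (is.null(axis)) {
      axis <- ppm
      X <- matrix(NA_real_, nrow(manifest), length(axis),
                  dimnames = list(manifest$sample_id, NULL))
      X[1, ] <- y
    } else if (length(ppm) == length(axis) && all(ppm == axis)) {
      X[i, ] <- y
    } else {
      X[i, ] <- stats::approx(ppm, y, xout = axis, rule = 2)$y
    }
  }
  structure(list(ppm = axis, X = X,
                 manifest = manifest[setdiff(names(manifest), "file")],
                 excluded_regions = list()),
            class = "spectra_set")
}

#' Automatic baseline-offset correction
#'
#' Subtracts a per-spectrum constant offset estimated from the baseline.
#' In a 1D NMR spectrum most grid points carry no peak, so a low robust
#' location statistic of the intensities estimates the baseline level; the
#' median is the default (peaks bias it upward only slightly at typical
#' peak densities), with a lower quantile available for crowded spectra.
#' This replaces interactive phase/baseline polishing, which is out of
#' scope here.
#'
#' @param set a `spectra_set`.
#' @param quantile_level quantile of the intensities used as the offset
#'   estimate (0.5 = median).
#' @return the corrected `spectra_set`; estimated offsets are attached as
#'   the `baseline_offsets` element.
#' @export
correct_baseline <- function(set, quantile_level = 0.5) {
  stopifnot(inherits(set, "spectra_set"),
            quantile_level > 0, quantile_level <= 0.5)
  off <- apply(set$X, 1L, stats::quantile, probs = quantile_level,
               names = FALSE)
  set$X <- sweep(set$X, 1L, off, "-")
  set$baseline_offsets <- off
  set
}

#' Remove a ppm region (e.g. the residual water signal) from all spectra
#'
#' Points with `lo <= ppm <= hi` are dropped from the common axis and from
#' every spectrum, and the exclusion is recorded so that downstream binning
#' never places a bin across the gap. A region entirely outside the axis is
#' a no-op.
#'
#' @param set a `spectra_set`.
#' @param lo,hi region bounds in ppm (`lo < hi`).
#' @return the modified `spectra_set`.
#' @export
#' @examples
#' lib <- default_library(3)
#' sim <- simulate_study(lib, study_design(c(A = 2, B = 2), seed = 1))
#' s <- exclude_region(sim$spectra, 4.70, 5.25)
#' any(s$ppm >= 4.70 & s$ppm <= 5.25)
exclude_region <- function(set, lo, hi) {
  stopifnot(inherits(set, "spectra_set"))
  if (!(is.numeric(lo) && is.numeric(hi) && lo < hi)) {
    stop("invalid exclusion region: need lo < hi, got [", lo, ", ", hi, "]")
  }
  drop <- set$ppm >= lo & set$ppm <= hi
  if (all(drop)) stop("exclusion [", lo, ", ", hi, "] covers the whole axis")
  if (!any(drop)) return(set)
  set$ppm <- set$ppm[!drop]
  set$X <- set$X[, !drop, drop = FALSE]
  set$excluded_regions <- c(set$excluded_regions, list(c(lo, hi)))
  set
}

# Indices where the axis is contiguous; splits at excluded gaps (grid steps
# much larger than the median step).
.axis_segments <- function(ppm) {
  if (length(ppm) < 2L) return(list(seq_along(ppm)))
  dx <- diff(ppm)
  gap <- which(dx > 3 * stats::median(dx))
  starts <- c(1L, gap + 1L)
  ends <- c(gap, length(ppm))
  Map(seq, starts, ends)
}

#' Adaptively bin a spectra set
#'
#' Bin boundaries are placed at local minima of the Savitzky-Golay-smoothed
#' mean spectrum, so that bins respect peak valleys; boundaries closer than
#' half the target width are merged, and stretches longer than twice the
#' target width without a minimum are split uniformly. The per-sample bin
#' value is the trapezoidal integral of the spectrum over the half-open bin
#' interval `[lo, hi)`. Excluded regions produce no bins.
#'
#' @param set a `spectra_set`.
#' @param lo,hi binned range (ppm).
#' @param target_width intended average bin width (ppm).
#' @return a `bin_table`: `bins` (data frame lo/hi/mid), `X` (sample x bin
#'   integral matrix), `manifest`, `excluded_regions`.
#' @export
adaptive_bin <- function(set, lo = 0.2, hi = 8.8, target_width = 0.015) {
  stopifnot(inherits(set, "spectra_set"), lo < hi, target_width > 0)
  keep <- set$ppm >= lo & set$ppm <= hi
  if (sum(keep) < 8L) {
    stop("fewer than 8 axis points in [", lo, ", ", hi, "]; cannot bin")
  }
  ppm <- set$ppm[keep]
  X <- set$X[, keep, drop = FALSE]
  mean_spec <- colMeans(X)
  step <- stats::median(diff(ppm))

  edges <- c()
  for (seg in .axis_segments(ppm)) {
    if (length(seg) < 4L) next
    x <- ppm[seg]
    y <- mean_spec[seg]
    win <- max(5L, round(target_width / step))
    if (win %% 2L == 0L) win <- win + 1L
    ys <- if (length(y) > win + 2L) {
      signal::sgolayfilt(y, p = 3, n = win)
    } else y
    n <- length(ys)
    is_min <- c(FALSE, ys[2:(n - 1)] < ys[1:(n - 2)] &
                       ys[2:(n - 1)] <= ys[3:n], FALSE)
    cand <- x[is_min]
    # greedy merge: keep minima at least half a target width apart and away
    # from the segment ends
    b <- x[1]
    acc <- b
    for (cm in cand) {
      if (cm - b >= 0.5 * target_width && x[n] - cm >= 0.5 * target_width) {
        acc <- c(acc, cm)
        b <- cm
      }
    }
    acc <- c(acc, x[n])
    # uniform split of long minima-free stretches
    out <- acc[1]
    for (k in 2:length(acc)) {
      w <- acc[k] - acc[k - 1]
      if (w > 2 * target_width) {
        nsub <- max(1L, round(w / target_width))
        out <- c(out, acc[k - 1] + w * seq_len(nsub) / nsub)
      } else {
        out <- c(out, acc[k])
      }
    }
    edges <- c(edges, list(list(seg = seg, edges = out)))
  }
  if (!length(edges)) stop("no contiguous segment long enough to bin")

  bins <- do.call(rbind, lapply(edges, function(e) {
    data.frame(lo = e$edges[-length(e$edges)], hi = e$edges[-1])
  }))
  bins$mid <- (bins$lo + bins$hi) / 2

  B <- matrix(0, nrow(X), nrow(bins),
              dimnames = list(rownames(X), NULL))
  col0 <- 0L
  for (e in edges) {
    x <- ppm[e$seg]
    nb <- length(e$edges) - 1L
    for (i in seq_len(nrow(X))) {
      ci <- cum_integral_at(x, X[i, e$seg], e$edges)
      B[i, col0 + seq_len(nb)] <- diff(ci)
    }
    col0 <- col0 + nb
  }

  structure(list(bins = bins, X = B, manifest = set$manifest,
                 excluded_regions = set$excluded_regions,
                 range = c(lo, hi), target_width = target_width),
            class = "bin_table")
}

#' Probability quotient normalization of a bin table
#'
#' Corrects per-sample global dilution: each sample is first scaled so its
#' total integral matches the reference spectrum's total, then divided by
#' the median ratio of its bins to the reference's bins (the probability
#' quotient). The stored `quotients` are the combined per-sample factors
#' divided out, which estimate relative dilution. The reference is the
#' per-bin median spectrum of all samples (default), of one group, or a
#' fixed numeric vector (frozen reference; under a frozen reference the
#' operation is exactly idempotent).
#'
#' @param bt a `bin_table` (or `feature_matrix`).
#' @param reference `"median"` (all samples), `"group"`, or a numeric
#'   vector of length `ncol(X)`.
#' @param group group label when `reference = "group"`.
#' @return a `feature_matrix`: normalized `X`, `ppm` (bin midpoints),
#'   `bins`, `quotients`, `reference` (the reference spectrum used),
#'   `manifest`, `centered = FALSE`.
#' @export
pqn_normalize <- function(bt, reference = "median", group = NULL) {
  X <- as_feature_X(bt)
  if (is.numeric(reference)) {
    if (length(reference) != ncol(X)) {
      stop("numeric reference must have one value per bin")
    }
    ref <- reference
  } else if (identical(reference, "median")) {
    ref <- apply(X, 2L, stats::median)
  } else if (identical(reference, "group")) {
    if (is.null(group)) stop("reference = 'group' needs a group label")
    sel <- bt$manifest$group == group
    if (!any(sel)) stop("no samples in group '", group, "'")
    ref <- apply(X[sel, , drop = FALSE], 2L, stats::median)
  } else {
    stop("reference must be 'median', 'group', or a numeric vector")
  }
  if (!any(ref > 0)) {
    stop("reference spectrum has no positive bins; cannot normalize")
  }
  # degenerate-quotient guard: the quotient median is taken over bins where
  # the reference clearly carries signal, so near-zero noise bins (whose
  # ratios are arbitrary in sign and size) cannot swamp it. The reference
  # must be usable there: at least 4 signal bins, all strictly positive by
  # construction of the floor.
  pos <- ref[ref > 0]
  valid <- ref > max(1e-12 * max(ref), 0.05 * mean(pos))
  if (sum(valid) < 4L) {
    stop("reference spectrum carries too few signal bins (",
         sum(valid), ") for a stable quotient")
  }
  tot_ref <- sum(ref)
  n <- nrow(X)
  quot <- numeric(n)
  out <- X
  ids <- rownames(X) %||% as.character(seq_len(n))
  for (i in seq_len(n)) {
    tot_i <- sum(X[i, ])
    if (tot_i == 0) stop("sample ", ids[i], " is all zero; cannot normalize")
    a <- tot_i / tot_ref
    s <- X[i, ] / a
    q <- stats::median(s[valid] / ref[valid])
    if (!is.finite(q) || q <= 0) {
      stop("degenerate probability quotient for sample ", ids[i])
    }
    out[i, ] <- s / q
    quot[i] <- a * q
  }
  names(quot) <- ids
  structure(list(X = out, ppm = bt$bins$mid, bins = bt$bins,
                 quotients = quot, reference = ref,
                 manifest = bt$manifest, centered = FALSE,
                 col_means = NULL),
            class = "feature_matrix")
}

#' Mean-center a feature matrix
#'
#' Subtracts the column means, retaining them for back-transformation of
#' loadings to the intensity scale.
#'
#' @param fm a `feature_matrix`.
#' @return the centered `feature_matrix` with `col_means` filled in.
#' @export
mean_center <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (isTRUE(fm$centered)) stop("feature matrix is already centered")
  if (nrow(fm$X) < 2L) stop("cannot center a single-sample matrix")
  cc <- center_cols(fm$X)
  fm$X <- cc$X
  fm$col_means <- cc$means
  fm$centered <- TRUE
  fm
}

#' Undo mean-centering
#' @param fm a centered `feature_matrix`.
#' @return the uncentered `feature_matrix`.
#' @export
uncenter <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"), isTRUE(fm$centered))
  fm$X <- sweep(fm$X, 2L, fm$col_means, "+")
  fm$centered <- FALSE
  fm
}

#' @export
print.bin_table <- function(x, ...) {
  cat("<bin_table> ", nrow(x$X), " samples x ", nrow(x$bins), " bins, range ",
      x$range[1], "-", x$range[2], " ppm, mean width ",
      signif(mean(x$bins$hi - x$bins$lo), 3), " ppm\n", sep = "")
  invisible(x)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$X), " samples x ", ncol(x$X), " features",
      if (isTRUE(x$centered)) ", mean-centered" else "",
      "\n  PQN quotients: ",
      paste(signif(range(x$quotients), 3), collapse = " - "), "\n", sep = "")
  invisible(x)
}

#' Export a feature matrix (or bin table) to CSV
#'
#' Writes the sample x feature matrix with bin lo/hi/midpoint header rows.
#'
#' @param x a `feature_matrix` or `bin_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(x, path) {
  X <- as_feature_X(x)
  hdr <- rbind(lo = x$bins$lo, hi = x$bins$hi, mid = x$bins$mid)
  df <- rbind(
    data.frame(sample_id = rownames(hdr), hdr, check.names = FALSE),
    data.frame(sample_id = rownames(X) %||% seq_len(nrow(X)), X,
               check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
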