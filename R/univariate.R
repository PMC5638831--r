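# Univariate layer: metabolite-level integrals, fold changes, Student's t
# tests, Benjamini-Hochberg adjustment, and the colored fold-change table.

#' Sum bin integrals into metabolite-level values
#'
#' A metabolite assignment maps a metabolite name to one or more ppm
#' windows; the metabolite value of a sample is the sum of the bin
#' integrals whose midpoints fall inside any of its windows.
#'
#' @param fm a `feature_matrix` or `bin_table` (uncentered values).
#' @param assignments data frame with columns `metabolite`, `lo_ppm`,
#'   `hi_ppm` (several rows per metabolite allowed).
#' @return sample x metabolite numeric matrix.
#' @export
metabolite_integrals <- function(fm, assignments) {
  need <- c("metabolite", "lo_ppm", "hi_ppm")
  if (!all(need %in% names(assignments))) {
    stop("assignments must have columns: ", paste(need, collapse = ", "))
  }
  X <- as_feature_X(fm)
  mids <- if (inherits(fm, "bin_table")) fm$bins$mid else fm$ppm
  mets <- unique(assignments$metabolite)
  out <- matrix(0, nrow(X), length(mets),
                dimnames = list(rownames(X), mets))
  for (m in mets) {
    win <- assignments[assignments$metabolite == m, , drop = FALSE]
    sel <- Reduce(`|`, lapply(seq_len(nrow(win)), function(i) {
      mids >= win$lo_ppm[i] & mids <= win$hi_ppm[i]
    }))
    if (!any(sel)) {
      stop("assignment windows for '", m, "' intersect no bin")
    }
    out[, m] <- rowSums(X[, sel, drop = FALSE])
  }
  out
}

#' Fold change of a treated group relative to control
#'
#' @param treated,control numeric vectors of per-sample values.
#' @return list with `fold` = mean(treated)/mean(control) and `log2_fold`.
#' @export
#' @examples
#' fold_change(c(4, 4), c(1, 1))
fold_change <- function(treated, control) {
  mc <- mean(control)
  if (!is.finite(mc) || mc <= 0) {
    stop("control mean must be positive, got ", format(mc))
  }
  fold <- mean(treated) / mc
  list(fold = fold, log2_fold = log2(fold))
}

#' Two-sided Student's t test (pooled variance)
#'
#' Thin wrapper around `stats::t.test(var.equal = TRUE)` with guards for
#' degenerate inputs: zero pooled variance with equal means gives p = 1
#' (with a warning); with unequal means, p is floored at 1e-300.
#'
#' @param treated,control numeric vectors (each n >= 2).
#' @return the raw two-sided p-value.
#' @export
t_test <- function(treated, control) {
  if (length(treated) < 2L || length(control) < 2L) {
    stop("each group needs at least 2 observations")
  }
  if (stats::var(treated) == 0 && stats::var(control) == 0) {
    if (mean(treated) == mean(control)) {
      warning("zero variance and equal means; p set to 1")
      return(1)
    }
    warning("zero variance with unequal means; p floored at 1e-300")
    return(1e-300)
  }
  p <- stats::t.test(treated, control, var.equal = TRUE)$p.value
  max(p, 1e-300)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via `stats::p.adjust`), with
#' input validation.
#'
#' @param pvals vector of raw p-values in (0, 1].
#' @return the adjusted q-values.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) stop("empty p-value vector")
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("all p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

.stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", ""), right = TRUE) |> as.character()
}

#' Build the per-comparison fold-change table
#'
#' One row per metabolite per treated-vs-control comparison: fold change
#' (treated mean / control mean), log2 fold, raw Student-t p, BH q
#' (adjusted within the comparison across metabolites), and significance
#' stars keyed to the raw p (0.05/0.01/0.001). The `color` column encodes
#' the sign of the log2 fold (red = increase, blue = decrease, white =
#' unchanged) for rendering the colored table.
#'
#' @param integrals sample x metabolite matrix from
#'   [metabolite_integrals()].
#' @param manifest data frame with `sample_id` and `group` matching the
#'   rows of `integrals`.
#' @param comparisons list of `c(treated, control)` group-label pairs.
#' @param stars_on `"raw"` (default; the table legend convention) or
#'   `"adjusted"`.
#' @return a `fold_change_table` (data frame subclass) with columns
#'   `comparison`, `metabolite`, `fold`, `log2_fold`, `p_raw`, `q_bh`,
#'   `stars`, `color`.
#' @export
build_fold_change_table <- function(integrals, manifest, comparisons,
                                    stars_on = c("raw", "adjusted")) {
  stars_on <- match.arg(stars_on)
  groups <- manifest$group
  rows <- list()
  for (cmp in comparisons) {
    if (length(cmp) != 2L) stop("each comparison must be c(treated, control)")
    missing <- setdiff(cmp, groups)
    if (length(missing)) {
      stop("unknown group(s) in comparison: ", paste(missing, collapse = ", "))
    }
    ti <- integrals[groups == cmp[1], , drop = FALSE]
    ci <- integrals[groups == cmp[2], , drop = FALSE]
    res <- lapply(colnames(integrals), function(m) {
      fc <- fold_change(ti[, m], ci[, m])
      data.frame(comparison = paste(cmp[1], "vs", cmp[2]),
                 metabolite = m, fold = fc$fold, log2_fold = fc$log2_fold,
                 p_raw = t_test(ti[, m], ci[, m]))
    })
    tab <- do.call(rbind, res)
    tab$q_bh <- bh_adjust(tab$p_raw)  # BH family: metabolites within one comparison
    rows[[length(rows) + 1L]] <- tab
  }
  out <- do.call(rbind, rows)
  out$stars <- .stars(if (stars_on == "raw") out$p_raw else out$q_bh)
  out$color <- ifelse(out$log2_fold > 0, "red",
                      ifelse(out$log2_fold < 0, "blue", "white"))
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Export a fold-change table as CSV and color-coded HTML
#'
#' @param tab a `fold_change_table`.
#' @param path_csv CSV output path.
#' @param path_html optional HTML output path (cell background scales with
#'   |log2 fold|, red increase / blue decrease, stars appended).
#' @return `path_csv`, invisibly.
#' @export
write_fold_change_table <- function(tab, path_csv, path_html = NULL) {
  utils::write.csv(as.data.frame(tab), path_csv, row.names = FALSE)
  if (!is.null(path_html)) {
    shade <- function(lf) {
      a <- pmin(1, abs(lf) / 2)
      ifelse(lf > 0, sprintf("rgba(220,50,47,%.2f)", a),
             ifelse(lf < 0, sprintf("rgba(38,139,210,%.2f)", a), "white"))
    }
    cells <- sprintf(
      "<tr><td>%s</td><td>%s</td><td style='background:%s'>%.2f%s</td><td>%.3g</td><td>%.3g</td></tr>",
      tab$comparison, tab$metabolite, shade(tab$log2_fold), tab$fold,
      tab$stars, tab$p_raw, tab$q_bh)
    html <- c("<table border='1' cellpadding='3'>",
              "<tr><th>comparison</th><th>metabolite</th><th>fold</th><th>p</th><th>q (BH)</th></tr>",
              cells, "</table>")
    writeLines(html, path_html)
  }
  invisible(path_csv)
}
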