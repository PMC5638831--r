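# ggplot2 figure helpers. Each plotting function consumes the plain data
# the corresponding computation returns, so figures never recompute.

#' Score plot with 95% Hotelling T2 ellipse
#'
#' @param scores n x >=2 score matrix (PCA or PLS-DA).
#' @param groups group labels per sample.
#' @param level ellipse confidence level.
#' @return a ggplot object.
#' @export
plot_scores <- function(scores, groups, level = 0.95) {
  df <- data.frame(t1 = scores[, 1], t2 = scores[, 2],
                   group = as.character(groups))
  n <- nrow(df)
  # Hotelling T2 ellipse on the first two scores (rendering convention)
  S <- stats::cov(df[, 1:2])
  r2 <- 2 * (n - 1) / (n - 2) * stats::qf(level, 2, n - 2)
  theta <- seq(0, 2 * pi, length.out = 200)
  ell <- t(chol(S * r2)) %*% rbind(cos(theta), sin(theta))
  edf <- data.frame(t1 = colMeans(df[, 1, drop = FALSE]) + ell[1, ],
                    t2 = colMeans(df[, 2, drop = FALSE]) + ell[2, ])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t1, y = .data$t2,
                                   color = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_path(data = edf, ggplot2::aes(x = .data$t1, y = .data$t2),
                       inherit.aes = FALSE, linetype = 2) +
    ggplot2::labs(x = "t[1]", y = "t[2]") +
    ggplot2::theme_bw()
}

#' S-plot figure
#' @param sp output of [splot()].
#' @return a ggplot object.
#' @export
plot_splot <- function(sp) {
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$covariance,
                                   y = .data$correlation)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "cov(t1, X)", y = "corr(t1, X)") +
    ggplot2::theme_bw()
}

#' Correlation-coded loading pseudo-spectrum figure
#'
#' Covariance "peaks" against ppm (axis reversed, the NMR convention),
#' colored by |correlation|; warm colors mark variables that separate the
#' classes reliably.
#'
#' @param cl output of [correlation_loadings()].
#' @return a ggplot object.
#' @export
plot_correlation_loadings <- function(cl) {
  ggplot2::ggplot(cl, ggplot2::aes(x = .data$ppm, y = .data$covariance,
                                   color = .data$abs_correlation)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$ppm, yend = 0)) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_color_gradient(low = "blue", high = "red",
                                  limits = c(0, 1), name = "|r|") +
    ggplot2::labs(x = "ppm", y = "cov(t1, X)") +
    ggplot2::theme_bw()
}

#' Permutation null histogram
#' @param mv a `model_validation`.
#' @return a ggplot object with the observed statistic marked.
#' @export
plot_permutation_hist <- function(mv) {
  df <- data.frame(stat = mv$null_stats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(xintercept = mv$observed_stat, color = "red",
                        linewidth = 1) +
    ggplot2::labs(x = "permutation Q2Y", y = "count") +
    ggplot2::theme_bw()
}

#' Pathway impact bubble plot
#'
#' x = topology impact, y = -log10 raw p, bubble area proportional to
#' impact, color by significance.
#'
#' @param pr a `pathway_results` table from [metpa()].
#' @return a ggplot object.
#' @export
plot_metpa_bubble <- function(pr) {
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$impact, y = .data$neg_log10_p,
                                   size = .data$impact,
                                   color = .data$raw_p)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::scale_color_gradient(low = "red", high = "yellow") +
    ggplot2::labs(x = "pathway impact", y = "-log10(raw p)") +
    ggplot2::theme_bw()
}
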