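#' OPLS-DA score plot
#'
#' Predictive score on the horizontal axis, first orthogonal score on the
#' vertical axis, colored by group. Pass projected scores of passive groups
#' to reproduce multi-group score planes from a two-group fit.
#'
#' @param scores data.frame `sample_id`, `t`, `t_ortho`.
#' @param metadata data.frame `sample_id`, `group`.
#' @return a ggplot object.
#' @export
plot_scores <- function(scores, metadata) {
  d <- merge(scores, metadata, by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$t_ortho,
                                  color = .data$group)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "t (predictive)", y = "t_ortho (orthogonal)") +
    ggplot2::theme_bw()
}

#' Mean score trajectory plot
#'
#' @param traj a [trajectory()] table.
#' @return a ggplot object.
#' @export
plot_trajectory <- function(traj) {
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$t, y = .data$t_ortho,
                                     color = .data$group,
                                     group = .data$group)) +
    ggplot2::geom_path(arrow = grid::arrow(length = grid::unit(2, "mm"))) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$period), vjust = -0.8,
                       size = 2.8, show.legend = FALSE) +
    ggplot2::labs(x = "t (predictive)", y = "t_ortho (orthogonal)") +
    ggplot2::theme_bw()
}

#' S-plot
#'
#' @param sp a [splot()] table.
#' @return a ggplot object.
#' @export
plot_splot <- function(sp) {
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$covariance,
                                   y = .data$correlation)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "cov(t, X)", y = "corr(t, X)") +
    ggplot2::theme_bw()
}

#' Correlation-colored loading plot
#'
#' Back-scaled covariance trace over ppm, colored by the absolute
#' correlation of each bin with the predictive score; ppm axis reversed as
#' is conventional for NMR.
#'
#' @param sp a [splot()] table.
#' @return a ggplot object.
#' @export
plot_loadings <- function(sp) {
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$ppm, y = .data$covariance,
                                   color = abs(.data$correlation))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_color_gradient(low = "blue", high = "red",
                                  limits = c(0, 1), name = "|corr|") +
    ggplot2::labs(x = "ppm", y = "cov(t, X)") +
    ggplot2::theme_bw()
}

#' Permutation scatter plot
#'
#' R2 and Q2 of permuted models against the |correlation| of permuted with
#' original labels, with the OLS regression lines whose intercepts at 0
#' diagnose overfitting.
#'
#' @param perm a [permutation_test()] result.
#' @return a ggplot object.
#' @export
plot_permutation <- function(perm) {
  rec <- perm$records
  d <- rbind(data.frame(correlation = rec$correlation, value = rec$r2,
                        statistic = "R2"),
             data.frame(correlation = rec$correlation, value = rec$q2,
                        statistic = "Q2"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$correlation, y = .data$value,
                                  color = .data$statistic)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         fullrange = TRUE, linewidth = 0.5) +
    ggplot2::labs(x = "|correlation with original labels|", y = NULL) +
    ggplot2::theme_bw()
}

#' ROC curve plot
#'
#' @param roc data.frame `fpr`, `tpr` from [roc_auroc()].
#' @param auroc optional AUROC annotated in the subtitle.
#' @return a ggplot object.
#' @export
plot_roc <- function(roc, auroc = NULL) {
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = if (!is.null(auroc))
                    sprintf("AUROC = %.3f", auroc)) +
    ggplot2::theme_bw()
}

#' STOCSY trace plot
#'
#' Covariance trace over ppm colored by squared correlation with the
#' driver.
#'
#' @param res a [run_stocsy()] result.
#' @return a ggplot object.
#' @export
plot_stocsy <- function(res) {
  d <- as.data.frame(res)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ppm, y = .data$covariance,
                                  color = .data$r^2)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = attr(res, "driver_ppm"),
                        linetype = 3) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_color_gradient(low = "blue", high = "red",
                                  limits = c(0, 1), name = expression(r^2)) +
    ggplot2::labs(x = "ppm", y = "covariance with driver") +
    ggplot2::theme_bw()
}

#' Z-score heatmap
#'
#' Metabolite x period tile map of clipped z-scores with significance
#' stars.
#'
#' @param zt a [zscore_table()] result.
#' @return a ggplot object.
#' @export
plot_zscores <- function(zt) {
  z <- zt$z_clipped
  d <- expand.grid(metabolite = rownames(z), period = colnames(z),
                   stringsAsFactors = FALSE)
  d$z <- as.vector(z)
  d$stars <- as.vector(zt$stars)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$period, y = .data$metabolite,
                                  fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 2.5) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0,
                                  limits = c(-zt$clip, zt$clip),
                                  name = "z") +
    ggplot2::theme_bw()
}
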