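#' Plot per-mouse density statistics as points with group mean and SEM
#'
#' One panel per density statistic, genotype on the x axis split by age
#' group; individual points are per-mouse means over crops, the crossbar
#' is the group mean with an SEM error bar — the convention used for
#' density data.
#'
#' @param mice Per-mouse summary tibble from [aggregate_mice()].
#' @return A ggplot object.
#' @export
plot_density_summary <- function(mice) {
  long <- tidyr::pivot_longer(
    mice, c("density_pre_um3", "density_gfp_pre_um3", "pct_gfp_pre"),
    names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age_group, y = .data$value,
                                     colour = .data$genotype)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5),
                        alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, geom = "errorbar",
                          width = 0.2,
                          position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "age group (months)", y = NULL,
                  title = "Synapse density by genotype and age") +
    ggplot2::theme_minimal()
}

#' Plot tau colocalization percentages as median and IQR
#'
#' Per-mouse points with the group median and interquartile range — the
#' convention used for colocalization data, which is typically skewed.
#'
#' @param mice Per-mouse summary tibble from [aggregate_mice()].
#' @return A ggplot object.
#' @export
plot_coloc_summary <- function(mice) {
  long <- tidyr::pivot_longer(mice, c("pct_post_tau", "pct_pairs_tau"),
                              names_to = "statistic", values_to = "value")
  long <- long[!is.na(long$value), ]
  med_iqr <- function(v) {
    data.frame(y = stats::median(v),
               ymin = stats::quantile(v, 0.25),
               ymax = stats::quantile(v, 0.75))
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age_group, y = .data$value,
                                     colour = .data$genotype)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5),
                        alpha = 0.7) +
    ggplot2::stat_summary(fun.data = med_iqr, geom = "pointrange",
                          position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "age group (months)", y = "percent",
                  title = "Tau colocalization by genotype and age") +
    ggplot2::theme_minimal()
}

#' Autoplot a pipeline run
#'
#' @param object A `synaptomo_run` from [run_pipeline()].
#' @param type `"density"` or `"coloc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.synaptomo_run <- function(object, type = c("density", "coloc"), ...) {
  type <- match.arg(type)
  switch(type,
         density = plot_density_summary(object$mice),
         coloc = plot_coloc_summary(object$mice))
}
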