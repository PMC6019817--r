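# ggplot2 views of the three result types. Each returns the ggplot object;
# styling is deliberately minimal so callers can theme.

#' Plot back-transformed class means with standard errors
#'
#' @param x A [genotype_anova()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.qtlfine_anova <- function(x, ...) {
  ggplot2::ggplot(x$class_means,
                  ggplot2::aes(x = class, y = mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = mean - se, ymax = mean + se)) +
    ggplot2::labs(x = "genotype class", y = "corrected tooth number",
                  subtitle = sprintf("ANOVA F(%d, %d) = %.3g, p = %.3g",
                                     x$df_between, x$df_within, x$F, x$p_value))
}

#' Plot the QTL concordance score track
#'
#' Scores along the interval; perfectly concordant variants highlighted.
#'
#' @param x A [perfect_cluster_report()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_report <- function(x, ...) {
  track <- dplyr::filter(x$score_track, !is.na(score))
  ggplot2::ggplot(track, ggplot2::aes(x = pos, y = score)) +
    ggplot2::geom_point(ggplot2::aes(colour = score >= x$score_threshold),
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position (bp)", y = "QTL concordance score")
}

#' Plot gene-set enrichment results
#'
#' Observed one-sample t statistics per set against their permutation null
#' bands; significant sets highlighted.
#'
#' @param x An [evaluate_gene_sets()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_result <- function(x, ...) {
  d <- dplyr::filter(tibble::as_tibble(x), !is.na(t_statistic))
  ggplot2::ggplot(d, ggplot2::aes(x = set, y = t_statistic)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = cutoff_low, ymax = cutoff_high),
                            colour = "grey60", linewidth = 3, alpha = 0.5) +
    ggplot2::geom_point(ggplot2::aes(colour = significant), size = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "set t statistic (band: permutation null)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
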