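#' Between-condition log-NSAF scatter plot
#'
#' Plots each reproducibly identified protein at its mean log NSAF in the
#' two conditions; points off the diagonal are differentially abundant, and
#' significant proteins are highlighted.
#'
#' @param scatter output of [scatter_table()].
#' @param condition_a,condition_b axis labels.
#' @return a ggplot object.
#' @export
plot_nsaf_scatter <- function(scatter, condition_a = "condition a",
                              condition_b = "condition b") {
  ggplot2::ggplot(scatter,
                  ggplot2::aes(x = .data$mean_log_nsaf_a,
                               y = .data$mean_log_nsaf_b,
                               colour = .data$significant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "lightblue3",
                                            `TRUE` = "navy"),
                                 name = "significant") +
    ggplot2::labs(x = paste("mean log NSAF,", condition_a),
                  y = paste("mean log NSAF,", condition_b)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nsaf_diff <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$p_value), ]
  d$log2fc <- signed_log2fc(d)
  d$significant <- d$direction != "unchanged"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(.data$p_value),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "lightblue3",
                                            `TRUE` = "navy")) +
    ggplot2::labs(
      x = sprintf("log2 fold change (%s / %s)", attr(object, "condition_a"),
                  attr(object, "condition_b")),
      y = "-log10 p"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nsaf_samplecor <- function(object, ...) {
  ord <- object$hclust$labels[object$hclust$order]
  d <- tidy(object)
  d_full <- tibble::tibble(
    sample_a = factor(rep(object$samples, length(object$samples)),
                      levels = ord),
    sample_b = factor(rep(object$samples, each = length(object$samples)),
                      levels = ord),
    rho = as.vector(object$rho)
  )
  ggplot2::ggplot(d_full, ggplot2::aes(x = .data$sample_a,
                                       y = .data$sample_b,
                                       fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "navy",
                                 limits = c(min(object$rho), 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Concordance quadrant plot
#'
#' Protein vs mRNA log2 fold change with the four sign-pattern groups
#' coloured and the fold-change thresholds drawn.
#'
#' @param records output of [classify_concordance()].
#' @param threshold_fold threshold drawn as dashed lines (default 2).
#' @return a ggplot object.
#' @export
plot_concordance <- function(records, threshold_fold = 2) {
  thr <- log2(threshold_fold)
  d <- records[records$joined, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$protein_log2fc,
                                  y = .data$mrna_log2fc,
                                  colour = .data$group)) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = 2,
                        colour = "grey70") +
    ggplot2::geom_vline(xintercept = c(-thr, thr), linetype = 2,
                        colour = "grey70") +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::labs(x = "protein log2 fold change",
                  y = "mRNA log2 fold change") +
    ggplot2::theme_minimal()
}
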