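#' Plot the log R ratio profile of an asCN call
#'
#' Per-marker LRR values faceted by chromosome with segment means overlaid;
#' segment colour encodes the called `(major, minor)` state.
#'
#' @param object An `ascn_call`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ascn_call <- function(object, ...) {
  snvs <- object$snvs
  segs <- mutate(object$segments,
                 state = paste0("(", .data$major, ",", .data$minor, ")"))
  ggplot2::ggplot(snvs, ggplot2::aes(x = .data$pos / 1e6, y = .data$lrr)) +
    ggplot2::geom_point(size = 0.2, alpha = 0.3, colour = "grey40") +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$mean_lrr, yend = .data$mean_lrr,
                   colour = .data$state),
      linewidth = 1.2, inherit.aes = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "log R ratio",
                  colour = "asCN state") +
    ggplot2::theme_minimal()
}

#' Plot the allelic-imbalance profile of an asCN call
#'
#' Heterozygous-SNV AI values (`|RAF - 0.5|`) with the per-segment cluster
#' means `AF_h` / `AF_L`.
#'
#' @param x An `ascn_call`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_allelic_imbalance <- function(x, ...) {
  hets <- filter(x$snvs, .data$is_het)
  segs <- x$segments |>
    tidyr::pivot_longer(c("af_h", "af_l"), names_to = "cluster",
                        values_to = "af")
  ggplot2::ggplot(hets, ggplot2::aes(x = .data$pos / 1e6, y = .data$ai)) +
    ggplot2::geom_point(size = 0.2, alpha = 0.3, colour = "grey40") +
    ggplot2::geom_segment(
      data = filter(segs, !is.na(.data$af)),
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$af, yend = .data$af, colour = .data$cluster),
      linewidth = 1, inherit.aes = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(AI[snp]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of an ASE call
#'
#' WGS/RNA odds ratio (log2) against the model-1 binomial evidence, coloured
#' by ASE class.
#'
#' @param object An `ase_call`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ase_call <- function(object, ...) {
  g <- filter(object$genes, .data$ase_class != "NOT_TESTABLE")
  ggplot2::ggplot(g, ggplot2::aes(x = log2(.data$odds_ratio),
                                  y = -log10(pmax(.data$p_model1, 1e-300)),
                                  colour = .data$ase_class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = log2(c(0.5, 2)), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "log2 odds ratio (RNA vs WGS)",
                  y = "-log10 p (equal-expression null)",
                  colour = "class") +
    ggplot2::theme_minimal()
}
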