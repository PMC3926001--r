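#' Manhattan-style plot of per-bin association results
#'
#' @param object A `medip_ewas` tibble.
#' @param threshold Optional p-value threshold drawn as a horizontal line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot medip_ewas
autoplot.medip_ewas <- function(object, threshold = NULL, ...) {
  df <- as_tibble(object) |> filter(.data$status == "ok")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$start / 1e6,
                                        y = -log10(.data$p))) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' @rdname autoplot.medip_ewas
#' @export
#' @method autoplot medip_meta
autoplot.medip_meta <- function(object, threshold = NULL, ...) {
  df <- as_tibble(object) |> filter(.data$het_pass)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$start / 1e6,
                                        y = -log10(.data$p_ma))) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p[MA]))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' FDR step-function plot
#'
#' Estimated FDR against the nominal p-value threshold, with the requested
#' level and the attained threshold marked.
#'
#' @param object A `medip_fdr` object.
#' @param ... Unused.
#' @export
#' @method autoplot medip_fdr
autoplot.medip_fdr <- function(object, ...) {
  g <- object$grid
  p <- ggplot2::ggplot(g, ggplot2::aes(x = log10(.data$p), y = .data$fdr)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = "dotted") +
    ggplot2::labs(x = expression(log[10](p~threshold)),
                  y = "estimated FDR") +
    ggplot2::theme_minimal()
  if (!is.na(object$threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = log10(object$threshold),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Boxplot of the MZ versus unrelated correlation contrast
#'
#' @param object A `medip_pair_contrast` object.
#' @param ... Unused.
#' @export
#' @method autoplot medip_pair_contrast
autoplot.medip_pair_contrast <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$pair_type, y = .data$r)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "genome-wide pair correlation") +
    ggplot2::theme_minimal()
}

#' Histogram of per-bin intraclass correlations
#'
#' @param object A `medip_icc` tibble.
#' @param ... Unused.
#' @export
#' @method autoplot medip_icc
autoplot.medip_icc <- function(object, ...) {
  ggplot2::ggplot(filter(as_tibble(object), .data$status == "ok"),
                  ggplot2::aes(x = .data$icc)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::labs(x = "within-pair ICC per bin", y = "bins") +
    ggplot2::theme_minimal()
}
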