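#' Plot an M-prime track with called peaks
#'
#' Probe-level M-prime values along one chromosome (promoter block),
#' with accepted DEP intervals shaded and the rejected ones outlined.
#'
#' @param mtrack A [compute_mprime()] track.
#' @param deps Optional [call_deps()] result.
#' @param chrom Chromosome to display (default: the first).
#' @return A ggplot object.
#' @export
plot_mprime_track <- function(mtrack, deps = NULL, chrom = NULL) {
  chrom <- chrom %||% mtrack$chrom[1]
  m <- mtrack[mtrack$chrom == chrom, , drop = FALSE]
  p <- ggplot2::ggplot(m, ggplot2::aes(
    x = probe_mid(.data$start, .data$end), y = .data$mprime
  )) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = paste0(chrom, " position (bp)"),
                  y = expression(M * minute),
                  title = paste("Differential enrichment,", chrom))
  if (!is.null(deps)) {
    d <- deps[deps$chrom == chrom, , drop = FALSE]
    if (nrow(d) > 0L) {
      p <- p + ggplot2::geom_rect(
        data = d, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$start, xmax = .data$end,
                     ymin = -Inf, ymax = Inf, fill = .data$accepted),
        alpha = 0.2
      ) +
        ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                              `FALSE` = "grey50"),
                                   name = "accepted")
    }
  }
  p + ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression result
#'
#' @param object A [differential_expression()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(
    x = .data$log2_fc, y = -log10(.data$p_value),
    colour = .data$passes_filter
  )) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60"),
                                 name = "passes filter") +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = expression(-log[10] ~ italic(p))) +
    ggplot2::theme_minimal()
}

#' Heat-map style tile plot of a PeakScore (or expression) matrix
#'
#' Rows and columns are ordered by UPGMA clustering before plotting.
#'
#' @param mat A tibble with one label column plus numeric columns
#'   (e.g. [peak_score_matrix()] output).
#' @return A ggplot object.
#' @export
plot_score_heatmap <- function(mat) {
  om <- ordered_matrix(mat)
  lab <- names(om)[!vapply(om, is.numeric, logical(1))][1]
  long <- tidyr::pivot_longer(om, -dplyr::all_of(lab),
                              names_to = "sample", values_to = "score")
  long$sample <- factor(long$sample, levels = setdiff(names(om), lab))
  long[[lab]] <- factor(long[[lab]], levels = rev(om[[lab]]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data[[lab]],
                                     fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "PeakScore") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
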