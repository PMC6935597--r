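#' Heatmap of a joint allele-frequency spectrum
#'
#' Log-scaled tile plot of the AFS grid with the masked low-frequency
#' corner left blank, the standard way joint spectra are displayed when
#' comparing divergence models.
#'
#' @param object An `afs_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.afs_grid <- function(object, ...) {
  d <- tidyr::expand_grid(a = 0:(2 * object$n), b = 0:(2 * object$m))
  d$count <- as.vector(object$counts)
  d$masked <- as.vector(object$mask)
  d <- d[!d$masked, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$a, .data$b,
                                  fill = log10(.data$count + 1))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10(SNPs + 1)") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = sprintf("allele count in %s (0-%d)", object$pools[1],
                  2 * object$n),
      y = sprintf("allele count in %s (0-%d)", object$pools[2],
                  2 * object$m)
    ) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of a per-SNP Fst track
#'
#' @param object An `fst_track` tibble (`chrom`, `pos`, `fst`).
#' @param ... Unused.
#' @return A ggplot object with one panel row, chromosomes along x and
#'   per-SNP Fst on y.
#' @export
autoplot.fst_track <- function(object, ...) {
  d <- dplyr::arrange(tibble::as_tibble(object), .data$chrom, .data$pos)
  ggplot2::ggplot(d, ggplot2::aes(.data$pos / 1e6, .data$fst,
                                  colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = expression(F[st]),
                  title = attr(object, "contrast") %||% NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing = ggplot2::unit(0.1, "lines"))
}

#' Windowed Fst scan with peak regions highlighted
#'
#' @param scan An `fst_scan` result.
#' @return A ggplot object of window means with flagged peak windows
#'   emphasized.
#' @export
plot_fst_scan <- function(scan) {
  w <- scan$windows
  ggplot2::ggplot(w, ggplot2::aes((.data$start + .data$end) / 2e6,
                                  .data$mean_fst)) +
    ggplot2::geom_step(colour = "grey40") +
    ggplot2::geom_point(data = w[w$peak, ], colour = "firebrick",
                        size = 1.2) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "window midpoint (Mb)",
                  y = expression(mean ~ F[st])) +
    ggplot2::theme_minimal()
}
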