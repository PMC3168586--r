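#' Plot a sample's profile along the genome
#'
#' One panel per chromosome, probes at their genomic positions, values on
#' the y axis (log2 ratios or z-scores, per the profile's `value_kind`);
#' CNV calls, if supplied, are drawn as shaded spans colored by state.
#'
#' @param profiles Long profile tibble.
#' @param design The probe design (positions).
#' @param sample_id Which sample to draw (default: the first).
#' @param calls Optional CNV call tibble to overlay.
#' @return A ggplot object.
#' @export
plot_profile <- function(profiles, design, sample_id = NULL, calls = NULL) {
  design <- as_probe_design(design)
  if (is.null(sample_id)) sample_id <- profiles$sample_id[1]
  p <- profiles[profiles$sample_id == sample_id, ]
  df <- dplyr::inner_join(p, design, by = "probe_id")
  ylab <- if (value_kind(profiles) == "z_score") "z-score" else "log2 ratio"
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data$value)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = ylab, title = sample_id) +
    ggplot2::theme_minimal()
  if (!is.null(calls)) {
    cs <- calls[calls$sample_id == sample_id, ]
    if (nrow(cs)) {
      gg <- gg + ggplot2::geom_rect(
        data = cs,
        ggplot2::aes(xmin = .data$start, xmax = .data$end,
                     fill = .data$state),
        ymin = -Inf, ymax = Inf, alpha = 0.25, inherit.aes = FALSE) +
        ggplot2::scale_fill_manual(
          values = c(decreased = "#D55E00", increased = "#0072B2"))
    }
  }
  gg
}

#' Size distribution of CNV calls
#'
#' Histogram of call sizes on a log10 axis, colored by state, with the
#' conventional 50-kbp and 500-kbp reporting thresholds marked.
#'
#' @param calls A CNV call tibble.
#' @return A ggplot object.
#' @export
plot_call_sizes <- function(calls) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$size_bp,
                                      fill = .data$state)) +
    ggplot2::geom_histogram(bins = 40, position = "stack") +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = c(5e4, 5e5), linetype = "dashed") +
    ggplot2::scale_fill_manual(
      values = c(decreased = "#D55E00", increased = "#0072B2")) +
    ggplot2::labs(x = "call size (bp)", y = "calls") +
    ggplot2::theme_minimal()
}
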