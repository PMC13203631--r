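#' Manhattan-style plot of window statistics
#'
#' Plots a per-window statistic against cumulative genomic position,
#' alternating colors by chromosome, with optional horizontal threshold
#' lines — the standard view of a genome scan. Requires ggplot2.
#'
#' @param stats a `window_stats` table from [scan_windows()]
#' @param statistic column to plot (`"fst"` or `"log2_ratio"`)
#' @param thresholds numeric vector of horizontal cutoff lines
#' @return a ggplot object
#' @export
plot_manhattan <- function(stats, statistic = c("fst", "log2_ratio"),
                           thresholds = NULL) {
  statistic <- match.arg(statistic)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_manhattan needs the ggplot2 package")
  chroms <- unique(stats$chrom)
  offsets <- c(0, cumsum(vapply(chroms, function(ch)
    max(stats$end[stats$chrom == ch]), 0)))[seq_along(chroms)]
  names(offsets) <- chroms
  df <- data.frame(
    pos = (stats$start + stats$end) / 2 + offsets[stats$chrom],
    value = stats[[statistic]],
    chrom = factor(stats$chrom, levels = chroms))
  df <- df[!is.na(df$value), , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$value,
                                        color = .data$chrom)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::scale_color_manual(
      values = rep(c("#1f77b4", "#ff7f0e"), length.out = length(chroms))) +
    ggplot2::labs(x = "genomic position", y = statistic) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds))
    p <- p + ggplot2::geom_hline(yintercept = thresholds,
                                 linetype = "dashed", color = "red")
  p
}
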