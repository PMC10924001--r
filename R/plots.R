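#' Plot methylation and recombination tracks of a consensus table
#'
#' Draws the smoothed CG/CHG/CHH counts and recombination rate along each
#' chromosome, counts and rate on free y scales, one facet per chromosome
#' and track.
#'
#' @param consensus Consensus table from [build_consensus()].
#' @param smoothed Plot smoothed (default) or raw tracks.
#' @return A ggplot object.
#' @export
plot_consensus_tracks <- function(consensus, smoothed = TRUE) {
  cols <- if (smoothed) c("cg_s", "chg_s", "chh_s", "rate_s")
          else c("cg", "chg", "chh", "rate")
  long <- tidyr::pivot_longer(
    consensus[c("chrom", "start", cols)],
    cols = all_of(cols), names_to = "track", values_to = "value"
  )
  long$track <- factor(long$track, levels = cols)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$start / 1e6,
                                     y = .data$value,
                                     colour = .data$track)) +
    ggplot2::geom_line(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::facet_grid(track ~ chrom, scales = "free_y") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of context-recombination correlations
#'
#' One tile per chromosome and methylation context, coloured by the Pearson
#' correlation with the recombination rate (purple negative, green
#' positive); non-significant values are starred.
#'
#' @param report Correlation report from [correlate_contexts()].
#' @return A ggplot object.
#' @export
plot_correlation_report <- function(report) {
  report$label <- ifelse(is.na(report$significant) | report$significant,
                         "", "*")
  ggplot2::ggplot(report, ggplot2::aes(x = .data$context, y = .data$chrom,
                                       fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label)) +
    ggplot2::scale_fill_gradient2(low = "purple4", mid = "white",
                                  high = "green4", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' @rdname plot_predictions
#' @export
autoplot.recomb_eval <- function(object, ...) {
  plot_predictions(object, ...)
}

#' Plot predicted against observed recombination landscapes
#'
#' Observed and predicted smoothed recombination rates along each held-out
#' chromosome, with the physical quartile boundaries marked.
#'
#' @param object A `recomb_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_predictions <- function(object, ...) {
  pr <- object$predictions
  long <- tidyr::pivot_longer(pr, cols = c("rate_s_true", "rate_s_pred"),
                              names_to = "series", values_to = "rate")
  long$series <- ifelse(long$series == "rate_s_true", "observed",
                        "predicted")
  qlines <- pr |>
    group_by(.data$chrom) |>
    summarise(q = list(stats::quantile(.data$start, c(.25, .5, .75))),
              .groups = "drop") |>
    tidyr::unnest_longer("q")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$start / 1e6, y = .data$rate,
                                     colour = .data$series)) +
    ggplot2::geom_vline(data = qlines,
                        ggplot2::aes(xintercept = .data$q / 1e6),
                        colour = "grey70", linetype = "dashed") +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~chrom, scales = "free") +
    ggplot2::labs(x = "position (Mb)", y = "smoothed rate (cM/window)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
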