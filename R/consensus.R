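#' Simple exponential smoothing of an ordered track
#'
#' One forward pass of simple exponential smoothing,
#' `s[1] = x[1]`, `s[t] = alpha * x[t] + (1 - alpha) * s[t - 1]`,
#' used to damp the abrupt window-to-window changes in methylation counts
#' and recombination rates before correlation and modeling. Apply per
#' chromosome and per feature.
#'
#' @param x Numeric track ordered by window index.
#' @param alpha Smoothing factor in `(0, 1]`; `1` returns `x` unchanged.
#'   Default 0.1.
#' @return Smoothed numeric vector of the same length.
#' @examples
#' smooth_track(c(0, 1), alpha = 0.1)   # 0.0 0.1
#' @export
smooth_track <- function(x, alpha = 0.1) {
  assert_scalar_number(alpha, "alpha", min = 1e-12, max = 1)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (anyNA(x)) stop_invalid("smooth_track requires a complete track")
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                           init = x[1]))
}

#' Assemble the consensus table of methylation counts and recombination
#'
#' Inner-joins the per-window context counts with the windowed
#' recombination rates on `(chrom, window_index)`, drops windows whose rate
#' is undefined, and appends exponentially smoothed versions of every
#' feature (`cg_s`, `chg_s`, `chh_s`, `rate_s`), smoothing each chromosome
#' independently *after* the join.
#'
#' @param windows Window counts ([filter_and_count()] output or compatible:
#'   `chrom`, `window_index`, `start`, `end`, `cg`, `chg`, `chh`).
#' @param rates Rate track ([rates_from_map()] output: `chrom`,
#'   `window_index`, `rate`).
#' @param alpha Smoothing factor (default 0.1).
#' @return Tibble `chrom`, `window_index`, `start`, `end`, `cg`, `chg`,
#'   `chh`, `rate`, `cg_s`, `chg_s`, `chh_s`, `rate_s`, ordered by
#'   chromosome and window; attributes `n_dropped` (windows without a
#'   defined rate or counts) and `alpha`.
#' @export
build_consensus <- function(windows, rates, alpha = 0.1) {
  assert_columns(windows, c("chrom", "window_index", "start", "end",
                            "cg", "chg", "chh"), "window table")
  assert_columns(rates, c("chrom", "window_index", "rate"), "rate track")

  shared_chroms <- intersect(unique(windows$chrom), unique(rates$chrom))
  if (length(shared_chroms) == 0L) {
    stop_invalid("window table and rate track share no chromosomes")
  }
  joined <- inner_join(
    windows[c("chrom", "window_index", "start", "end", "cg", "chg", "chh")],
    rates[c("chrom", "window_index", "rate")],
    by = c("chrom", "window_index")
  )
  if (nrow(joined) == 0L) {
    stop_invalid(
      "window grids do not overlap; do the two inputs use the same window size?")
  }
  # windows on shared chromosomes that failed to pair off (grid mismatch)
  w_shared <- sum(windows$chrom %in% shared_chroms)
  r_shared <- sum(rates$chrom %in% shared_chroms)
  if (nrow(joined) < 0.5 * min(w_shared, r_shared)) {
    stop_invalid(
      "fewer than half the windows joined; window sizes likely differ")
  }
  n_before <- nrow(joined)
  joined <- joined[!is.na(joined$rate), , drop = FALSE]
  n_dropped <- n_before - nrow(joined)

  joined <- joined |>
    arrange(.data$chrom, .data$window_index) |>
    group_by(.data$chrom) |>
    mutate(
      cg_s = smooth_track(.data$cg, alpha),
      chg_s = smooth_track(.data$chg, alpha),
      chh_s = smooth_track(.data$chh, alpha),
      rate_s = smooth_track(.data$rate, alpha)
    ) |>
    ungroup()
  attr(joined, "n_dropped") <- n_dropped
  attr(joined, "alpha") <- alpha
  joined
}

#' Correlate methylation contexts with recombination per chromosome
#'
#' Pearson correlation of each smoothed context track (`cg_s`, `chg_s`,
#' `chh_s`) against the smoothed recombination rate (`rate_s`), per
#' chromosome, with a two-sided p-value and a significance flag. Set
#' `smoothed = FALSE` to correlate the raw tracks instead.
#'
#' @param consensus Consensus table from [build_consensus()].
#' @param significance_level Flag threshold for the two-sided p-value
#'   (default 0.05).
#' @param smoothed Correlate smoothed (default) or raw tracks.
#' @return Tibble `chrom`, `context`, `r`, `p_value`, `n`, `significant`,
#'   `note`; `r` is `NA` with an explanatory `note` when either track has
#'   zero variance or fewer than 3 windows.
#' @export
correlate_contexts <- function(consensus, significance_level = 0.05,
                               smoothed = TRUE) {
  cols <- if (smoothed) c(cg = "cg_s", chg = "chg_s", chh = "chh_s")
          else c(cg = "cg", chg = "chg", chh = "chh")
  rate_col <- if (smoothed) "rate_s" else "rate"
  assert_columns(consensus, c("chrom", "window_index", cols, rate_col),
                 "consensus table")
  assert_scalar_number(significance_level, "significance_level",
                       min = 0, max = 1)

  rows <- list()
  for (ch in unique(consensus$chrom)) {
    sub <- consensus[consensus$chrom == ch, , drop = FALSE]
    for (ctx in names(cols)) {
      x <- sub[[cols[[ctx]]]]
      y <- sub[[rate_col]]
      n <- length(x)
      if (n < 3) {
        rows[[length(rows) + 1L]] <- tibble(
          chrom = ch, context = toupper(ctx), r = NA_real_,
          p_value = NA_real_, n = n, significant = NA,
          note = "fewer than 3 windows")
        next
      }
      if (sd(x) == 0 || sd(y) == 0) {
        rows[[length(rows) + 1L]] <- tibble(
          chrom = ch, context = toupper(ctx), r = NA_real_,
          p_value = NA_real_, n = n, significant = NA,
          note = "zero variance")
        next
      }
      ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
      rows[[length(rows) + 1L]] <- tibble(
        chrom = ch, context = toupper(ctx),
        r = unname(ct$estimate), p_value = ct$p.value, n = n,
        significant = ct$p.value < significance_level, note = NA_character_)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "significance_level") <- significance_level
  out
}
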