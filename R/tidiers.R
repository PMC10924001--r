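#' Tidy a recombination-model evaluation
#'
#' @param x A `recomb_eval` from [loco_evaluate()] or
#'   [transfer_evaluate()].
#' @param ... Unused.
#' @return Per-chromosome metrics as a tibble: `chrom`, `n_windows`, `r2`,
#'   `r`, `mse`, `note`.
#' @export
tidy.recomb_eval <- function(x, ...) {
  x$metrics
}

#' Summarise a recombination-model evaluation
#'
#' @param x A `recomb_eval`.
#' @param ... Unused.
#' @return One-row tibble with the evaluation kind, chromosome count, and
#'   mean and standard deviation of R^2, Pearson r and MSE across
#'   chromosomes (missing chromosomes excluded).
#' @export
glance.recomb_eval <- function(x, ...) {
  m <- x$metrics
  tibble(
    kind = x$kind,
    n_chrom = nrow(m),
    mean_r2 = mean(m$r2, na.rm = TRUE),
    sd_r2 = sd(m$r2, na.rm = TRUE),
    mean_r = mean(m$r, na.rm = TRUE),
    sd_r = sd(m$r, na.rm = TRUE),
    mean_mse = mean(m$mse, na.rm = TRUE),
    sd_mse = sd(m$mse, na.rm = TRUE)
  )
}

#' Augmented predictions of an evaluation
#'
#' @param x A `recomb_eval`.
#' @param ... Unused.
#' @return The per-window prediction tibble (`chrom`, `window_index`,
#'   `start`, `end`, `rate_s_true`, `rate_s_pred`, `residual`).
#' @export
augment.recomb_eval <- function(x, ...) {
  out <- x$predictions
  out$residual <- out$rate_s_true - out$rate_s_pred
  out
}

#' @export
tidy.recomb_contributions <- function(x, ...) {
  x$ranking
}

#' @export
print.recomb_eval <- function(x, ...) {
  cat(sprintf("<recomb_eval: %s over %d chromosome(s)>\n",
              x$kind, nrow(x$metrics)))
  print(x$metrics)
  g <- glance(x)
  cat(sprintf("  mean R2 %.3f +/- %.3f, mean r %.3f +/- %.3f, mean MSE %.4g\n",
              g$mean_r2, g$sd_r2, g$mean_r, g$sd_r, g$mean_mse))
  invisible(x)
}
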