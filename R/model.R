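#' Fit an Extra Trees regressor of recombination on methylation features
#'
#' Fits an extremely randomized trees (Extra Trees) ensemble predicting the
#' smoothed recombination rate `rate_s` from smoothed methylation-count
#' features, via [ranger::ranger()] with `splitrule = "extratrees"` and the
#' classic Extra Trees setup: one random split per candidate feature, all
#' features considered at every split, no bootstrap (each tree sees the full
#' training set).
#'
#' @param consensus Consensus table ([build_consensus()]).
#' @param features Character subset of `c("cg_s", "chg_s", "chh_s")`
#'   (default all three).
#' @param seed Integer seed making the fit reproducible.
#' @param num_trees Number of trees (default 100).
#' @param min_node_size Minimal node size to split (default 2).
#' @param ... Further arguments passed to [ranger::ranger()].
#' @return Object of class `recomb_model`: the ranger fit plus the feature
#'   set, training data, and per-tree structure used for attributions.
#' @export
fit_recomb_model <- function(consensus, features = c("cg_s", "chg_s", "chh_s"),
                             seed = 42L, num_trees = 100,
                             min_node_size = 2, ...) {
  if (length(features) == 0) stop_invalid("`features` must be non-empty")
  assert_columns(consensus, c(features, "rate_s"), "consensus table")
  assert_scalar_number(seed, "seed", integerish = TRUE)
  train <- consensus[c(features, "rate_s")]
  if (anyNA(train)) stop_invalid("consensus table has missing values")

  fit <- ranger::ranger(
    dependent.variable.name = "rate_s",
    data = as.data.frame(train),
    num.trees = num_trees,
    splitrule = "extratrees",
    num.random.splits = 1,
    mtry = length(features),
    replace = FALSE,
    sample.fraction = 1,
    min.node.size = min_node_size,
    seed = as.integer(seed),
    num.threads = 1,
    ...
  )
  structure(
    list(fit = fit, features = features, seed = as.integer(seed),
         train = train),
    class = "recomb_model"
  )
}

#' @export
predict.recomb_model <- function(object, newdata, ...) {
  assert_columns(newdata, object$features, "prediction data")
  predict(object$fit, data = as.data.frame(newdata[object$features]),
          num.threads = 1)$predictions
}

#' @export
print.recomb_model <- function(x, ...) {
  cat("<recomb_model>\n")
  cat(sprintf("  Extra Trees (%d trees) on %d rows; features: %s\n",
              x$fit$num.trees, nrow(x$train),
              paste(x$features, collapse = ", ")))
  invisible(x)
}

# Closed-form evaluation metrics on one held-out chromosome.
# R^2 uses SS_tot about the held-out data's own mean, so it can be negative
# out of sample; r is Pearson correlation; MSE is on the modeled scale.
eval_metrics <- function(truth, pred) {
  mse <- mean((truth - pred)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) {
    return(list(r2 = NA_real_, r = NA_real_, mse = mse,
                note = "zero rate variance on held-out data"))
  }
  r2 <- 1 - sum((truth - pred)^2) / ss_tot
  r <- if (sd(pred) == 0) NA_real_ else cor(truth, pred)
  list(r2 = r2, r = r, mse = mse, note = NA_character_)
}

#' Leave-one-chromosome-out evaluation
#'
#' For each chromosome `c` in the consensus table, fits an Extra Trees model
#' on all remaining chromosomes, predicts the smoothed recombination rate of
#' `c`, and scores the prediction with the coefficient of determination
#' R\eqn{^2} (about the held-out chromosome's own mean, so negative values
#' indicate a fit worse than that mean), Pearson `r`, and MSE. Also computes
#' quartile-stratified correlations of each held-out chromosome and, from a
#' model fitted on *all* chromosomes, per-feature additive attributions.
#'
#' @inheritParams fit_recomb_model
#' @param significance_level Threshold for quartile-correlation flags.
#' @param contributions Compute feature attributions (default `TRUE`).
#' @return Object of class `recomb_eval` with elements `metrics`
#'   (per-chromosome tibble), `predictions` (per-window tibble),
#'   `quartiles` ([quartile_eval()] output), `contributions`
#'   ([feature_contributions()] output or `NULL`), `features`, `seed`,
#'   `kind = "loco"`.
#' @examples
#' \donttest{
#' specs <- lapply(1:3, function(i)
#'   landscape_spec(chrom_length = 1e6, window_size = 1e5, total_cM = 10,
#'                  cg_base = 60, chg_base = 40, chh_base = 20, seed = i))
#' ct <- do.call(rbind, lapply(seq_along(specs), function(i) {
#'   sim <- simulate_methylome(specs[[i]], chrom = paste0("chr", i))
#'   rt <- sim$truth
#'   rt$rate[nrow(rt)] <- NA
#'   build_consensus(sim$expected_windows, rt)
#' }))
#' ev <- loco_evaluate(ct, seed = 1)
#' tidy(ev)
#' }
#' @export
loco_evaluate <- function(consensus, features = c("cg_s", "chg_s", "chh_s"),
                          seed = 42L, num_trees = 100, min_node_size = 2,
                          significance_level = 0.05, contributions = TRUE) {
  assert_columns(consensus,
                 c("chrom", "window_index", features, "rate_s"),
                 "consensus table")
  chroms <- unique(consensus$chrom)
  if (length(chroms) < 2L) {
    stop_invalid("leave-one-chromosome-out needs at least 2 chromosomes")
  }

  metrics <- vector("list", length(chroms))
  preds <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    train <- consensus[consensus$chrom != ch, , drop = FALSE]
    test <- consensus[consensus$chrom == ch, , drop = FALSE]
    model <- fit_recomb_model(train, features = features,
                              seed = seed + i, num_trees = num_trees,
                              min_node_size = min_node_size)
    p <- predict(model, test)
    m <- eval_metrics(test$rate_s, p)
    metrics[[i]] <- tibble(
      chrom = ch, n_windows = nrow(test), r2 = m$r2, r = m$r, mse = m$mse,
      note = m$note
    )
    preds[[i]] <- tibble(
      chrom = ch, window_index = test$window_index,
      start = test$start, end = test$end,
      rate_s_true = test$rate_s, rate_s_pred = p
    )
  }
  metrics <- dplyr::bind_rows(metrics)
  predictions <- dplyr::bind_rows(preds)
  quartiles <- quartile_eval(predictions,
                             significance_level = significance_level)

  contrib <- NULL
  if (contributions) {
    full <- fit_recomb_model(consensus, features = features, seed = seed,
                             num_trees = num_trees,
                             min_node_size = min_node_size)
    contrib <- feature_contributions(full)
  }

  structure(
    list(metrics = metrics, predictions = predictions,
         quartiles = quartiles, contributions = contrib,
         features = features, seed = as.integer(seed), kind = "loco"),
    class = "recomb_eval"
  )
}

#' Cross-dataset transfer evaluation
#'
#' Fits one Extra Trees model on *all* chromosomes of a training consensus
#' table and evaluates it per chromosome of a second (e.g. another species'
#' dataset), with the same metrics as [loco_evaluate()]. Feature tracks are
#' used as-is; set `normalize = "per-dataset-zscore"` to z-score each
#' feature within each dataset first (sensitivity analysis; off by
#' default).
#'
#' @param ct_train,ct_test Consensus tables exposing the configured
#'   features.
#' @inheritParams loco_evaluate
#' @param normalize `"none"` (default) or `"per-dataset-zscore"`.
#' @return A `recomb_eval` object with `kind = "transfer"`.
#' @export
transfer_evaluate <- function(ct_train, ct_test,
                              features = c("cg_s", "chg_s", "chh_s"),
                              seed = 42L, num_trees = 100,
                              min_node_size = 2,
                              significance_level = 0.05,
                              normalize = c("none", "per-dataset-zscore"),
                              contributions = TRUE) {
  normalize <- match.arg(normalize)
  assert_columns(ct_train, c("chrom", features, "rate_s"),
                 "training consensus table")
  assert_columns(ct_test, c("chrom", "window_index", features, "rate_s"),
                 "test consensus table")
  if (normalize == "per-dataset-zscore") {
    zscore <- function(ct) {
      for (f in features) {
        s <- sd(ct[[f]])
        ct[[f]] <- (ct[[f]] - mean(ct[[f]])) / if (s > 0) s else 1
      }
      ct
    }
    ct_train <- zscore(ct_train)
    ct_test <- zscore(ct_test)
  }

  model <- fit_recomb_model(ct_train, features = features, seed = seed,
                            num_trees = num_trees,
                            min_node_size = min_node_size)
  chroms <- unique(ct_test$chrom)
  metrics <- vector("list", length(chroms))
  preds <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    test <- ct_test[ct_test$chrom == chroms[i], , drop = FALSE]
    p <- predict(model, test)
    m <- eval_metrics(test$rate_s, p)
    metrics[[i]] <- tibble(
      chrom = chroms[i], n_windows = nrow(test), r2 = m$r2, r = m$r,
      mse = m$mse, note = m$note
    )
    preds[[i]] <- tibble(
      chrom = chroms[i], window_index = test$window_index,
      start = test$start, end = test$end,
      rate_s_true = test$rate_s, rate_s_pred = p
    )
  }
  predictions <- dplyr::bind_rows(preds)
  structure(
    list(metrics = dplyr::bind_rows(metrics), predictions = predictions,
         quartiles = quartile_eval(predictions,
                                   significance_level = significance_level),
         contributions = if (contributions) feature_contributions(model)
                         else NULL,
         features = features, seed = as.integer(seed), kind = "transfer"),
    class = "recomb_eval"
  )
}

#' Quartile-stratified correlation of predictions
#'
#' Splits each chromosome's windows (ordered by position) into four
#' contiguous blocks — the physical quartiles of the chromosome — and
#' computes the Pearson correlation of predicted versus observed smoothed
#' rates within each block. When the window count is not divisible by 4 the
#' remainder goes to the earlier quartiles (10 windows -> 3, 3, 2, 2). A
#' quartile where either side has zero variance (e.g. a recombination-free
#' chromosome arm) or fewer than 3 windows yields `NA` with a reason.
#'
#' @param predictions Tibble with `chrom`, `window_index`, `rate_s_true`,
#'   `rate_s_pred` (as in a `recomb_eval`).
#' @param significance_level Two-sided p-value threshold for the
#'   significance flag (default 0.05).
#' @return Tibble `chrom`, `quartile`, `n_windows`, `r`, `p_value`,
#'   `significant`, `note`.
#' @export
quartile_eval <- function(predictions, significance_level = 0.05) {
  assert_columns(predictions,
                 c("chrom", "window_index", "rate_s_true", "rate_s_pred"),
                 "prediction table")
  rows <- list()
  for (ch in unique(predictions$chrom)) {
    sub <- predictions[predictions$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$window_index), , drop = FALSE]
    sizes <- quartile_sizes(nrow(sub))
    block <- rep(1:4, times = sizes)
    for (q in 1:4) {
      tr <- sub$rate_s_true[block == q]
      pr <- sub$rate_s_pred[block == q]
      if (length(tr) < 3) {
        rows[[length(rows) + 1L]] <- tibble(
          chrom = ch, quartile = paste0("Q", q), n_windows = length(tr),
          r = NA_real_, p_value = NA_real_, significant = NA,
          note = "fewer than 3 windows")
      } else if (sd(tr) == 0 || sd(pr) == 0) {
        rows[[length(rows) + 1L]] <- tibble(
          chrom = ch, quartile = paste0("Q", q), n_windows = length(tr),
          r = NA_real_, p_value = NA_real_, significant = NA,
          note = "zero variance")
      } else {
        ct <- cor.test(tr, pr)
        rows[[length(rows) + 1L]] <- tibble(
          chrom = ch, quartile = paste0("Q", q), n_windows = length(tr),
          r = unname(ct$estimate), p_value = ct$p.value,
          significant = ct$p.value < significance_level,
          note = NA_character_)
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Block sizes for 4 contiguous quartiles; remainder to the earlier blocks.
quartile_sizes <- function(n) {
  sizes <- rep(n %/% 4L, 4L)
  extra <- n %% 4L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}
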