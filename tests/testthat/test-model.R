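test_that("evaluation metrics match independent closed forms", {
  set.seed(2)
  for (i in 1:5) {
    truth <- rnorm(40)
    pred <- truth + rnorm(40, sd = 0.5)
    m <- methrecomb:::eval_metrics(truth, pred)
    # independent two-line re-derivations
    expect_equal(m$mse, sum((truth - pred)^2) / 40, tolerance = 1e-12)
    expect_equal(m$r2, 1 - sum((truth - pred)^2) /
                   sum((truth - mean(truth))^2), tolerance = 1e-12)
    expect_equal(m$r, sum(scale(truth) * scale(pred)) / 39,
                 tolerance = 1e-12)
  }
  # predicting the held-out mean gives R^2 = 0 by definition
  truth <- c(1, 2, 3, 4)
  m0 <- methrecomb:::eval_metrics(truth, rep(mean(truth), 4))
  expect_equal(m0$r2, 0)
  # R^2 is not r^2: anti-scaled predictions keep r = 1 with negative R^2
  m1 <- methrecomb:::eval_metrics(truth, 10 * truth)
  expect_equal(m1$r, 1)
  expect_lt(m1$r2, 0)
})

test_that("LOCO evaluation is reproducible and holds chromosomes out", {
  ct <- make_species_ct(900, coupling = 0.9, n_chrom = 3, n_windows = 60)
  ev1 <- loco_evaluate(ct, seed = 5, contributions = FALSE)
  ev2 <- loco_evaluate(ct, seed = 5, contributions = FALSE)
  expect_identical(ev1$metrics, ev2$metrics)
  expect_identical(ev1$predictions, ev2$predictions)
  expect_equal(sort(unique(ev1$predictions$chrom)),
               sort(unique(ct$chrom)))
  expect_equal(nrow(ev1$predictions), nrow(ct))
  expect_error(loco_evaluate(ct[ct$chrom == "chr1", ]),
               class = "methrecomb_validation_error")
})

test_that("a noiseless single-feature target is interpolated near-perfectly", {
  ct <- make_species_ct(77, coupling = 0.9, n_chrom = 3)
  ct$rate_s <- 0.01 * ct$chh_s
  ev <- loco_evaluate(ct, seed = 1, contributions = FALSE)
  expect_true(all(ev$metrics$r2 >= 0.99))
})

test_that("tidy, glance and augment expose the evaluation", {
  ct <- make_species_ct(901, coupling = 0.9, n_chrom = 3, n_windows = 60)
  ev <- loco_evaluate(ct, seed = 2, contributions = FALSE)
  td <- tidy(ev)
  expect_equal(names(td), c("chrom", "n_windows", "r2", "r", "mse", "note"))
  g <- glance(ev)
  expect_equal(g$n_chrom, 3L)
  expect_equal(g$mean_r, mean(td$r))
  au <- augment(ev)
  expect_equal(au$residual, au$rate_s_true - au$rate_s_pred)
})

test_that("quartile blocks are contiguous with remainder to early quartiles", {
  expect_equal(methrecomb:::quartile_sizes(8), c(2, 2, 2, 2))
  expect_equal(methrecomb:::quartile_sizes(10), c(3, 3, 2, 2))
  expect_equal(methrecomb:::quartile_sizes(13), c(4, 3, 3, 3))

  set.seed(3)
  pred <- tibble::tibble(
    chrom = "chr1", window_index = 0:19,
    rate_s_true = c(rep(0, 5), runif(15)),
    rate_s_pred = runif(20)
  )
  q <- quartile_eval(pred)
  expect_equal(q$quartile, paste0("Q", 1:4))
  expect_equal(q$n_windows, rep(5L, 4))
  # Q1 truth is constant zero -> correlation undefined
  expect_true(is.na(q$r[1]))
  expect_equal(q$note[1], "zero variance")
  expect_false(anyNA(q$r[2:4]))
})

test_that("transfer evaluation trains on everything and errors on missing features", {
  ct <- make_species_ct(902, coupling = 0.9, n_chrom = 3, n_windows = 60)
  self <- transfer_evaluate(ct, ct, seed = 4, contributions = FALSE)
  loco <- loco_evaluate(ct, seed = 4, contributions = FALSE)
  # in-sample optimism: training data includes every test chromosome
  expect_true(all(self$metrics$r2 >= loco$metrics$r2))

  renamed <- dplyr::rename(ct, chh_smooth = "chh_s")
  expect_error(transfer_evaluate(ct, renamed, seed = 1),
               class = "methrecomb_validation_error")
})

test_that("removing the informative feature degrades prediction", {
  deltas <- vapply(1:5, function(s) {
    ct <- make_species_ct(s * 7 + 600, coupling = 0.9, n_chrom = 3,
                          n_windows = 100)
    full <- glance(loco_evaluate(ct, seed = s, contributions = FALSE))
    ablated <- glance(loco_evaluate(ct, features = c("cg_s", "chg_s"),
                                    seed = s, contributions = FALSE))
    full$mean_r - ablated$mean_r
  }, numeric(1))
  expect_gt(mean(deltas), 0)
  expect_gt(min(deltas), -0.02)   # no seed should show a real gain
})
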