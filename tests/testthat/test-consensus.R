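test_that("exponential smoothing follows the one-step recursion", {
  expect_equal(smooth_track(c(5, 5, 5, 5), alpha = 0.1), rep(5, 4))
  expect_equal(smooth_track(c(0, 1), alpha = 0.1), c(0, 0.1))
  x <- c(2, 7, 1, 4, 9)
  expect_lt(max(abs(smooth_track(x, alpha = 1) - x)), 1e-12)
  expect_equal(smooth_track(numeric(0)), numeric(0))
  # manual recursion oracle
  s <- x[1]
  for (t in 2:5) s[t] <- 0.3 * x[t] + 0.7 * s[t - 1]
  expect_equal(smooth_track(x, alpha = 0.3), s)
})

test_that("smoothing is linear in its input", {
  set.seed(7)
  x <- rnorm(50)
  y <- rnorm(50)
  lhs <- smooth_track(2 * x + 3 * y, alpha = 0.2)
  rhs <- 2 * smooth_track(x, alpha = 0.2) + 3 * smooth_track(y, alpha = 0.2)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

make_windows <- function(n, chrom = "chr1", w = 1e5) {
  tibble::tibble(
    chrom = chrom, window_index = seq_len(n) - 1L,
    start = (seq_len(n) - 1L) * w + 1, end = seq_len(n) * w,
    cg = rpois(n, 50), chg = rpois(n, 30), chh = rpois(n, 20)
  )
}

test_that("consensus joins windows with rates and drops undefined rates", {
  set.seed(5)
  w <- make_windows(10)
  rates <- tibble::tibble(chrom = "chr1", window_index = 0:9,
                          rate = c(runif(9), NA))
  ct <- build_consensus(w, rates)
  expect_equal(nrow(ct), 9L)
  expect_equal(attr(ct, "n_dropped"), 1L)
  expect_true(all(c("cg_s", "chg_s", "chh_s", "rate_s") %in% names(ct)))

  # mismatched window grids (50 kb rates vs 100 kb windows) error out
  rates50 <- tibble::tibble(chrom = "chr1", window_index = 0:19,
                            rate = runif(20))
  w50 <- w
  w50$window_index <- w$window_index * 2L   # only even indices join
  expect_error(build_consensus(w50, tibble::tibble(
    chrom = "chr1", window_index = c(1L, 3L, 5L), rate = runif(3))),
    class = "methrecomb_validation_error")
})

test_that("consensus smoothing is applied per chromosome after the join", {
  set.seed(6)
  w <- dplyr::bind_rows(make_windows(10, "chr1"), make_windows(10, "chr2"))
  rates <- tibble::tibble(chrom = rep(c("chr1", "chr2"), each = 10),
                          window_index = rep(0:9, 2), rate = runif(20))
  ct <- build_consensus(w, rates, alpha = 0.2)
  for (ch in c("chr1", "chr2")) {
    sub <- ct[ct$chrom == ch, ]
    expect_equal(sub$rate_s, smooth_track(sub$rate, 0.2))
    expect_equal(sub$chh_s, smooth_track(sub$chh, 0.2))
  }
})

test_that("generator round-trip reproduces expected counts in the consensus", {
  sim <- simulate_methylome(
    landscape_spec(chrom_length = 4e5, window_size = 2e4, total_cM = 10,
                   cg_base = 30, chg_base = 20, chh_base = 15, seed = 77))
  rt <- sim$truth
  rt$rate[nrow(rt)] <- NA
  ct <- build_consensus(sim$expected_windows, rt)
  expect_equal(ct$cg, sim$expected_windows$cg[-nrow(sim$expected_windows)])
  expect_equal(ct$rate, sim$truth$rate[-nrow(sim$truth)])
})

test_that("correlation report flags perfect, undefined and null cases", {
  n <- 30
  set.seed(8)
  ct <- tibble::tibble(
    chrom = "chr1", window_index = 0:(n - 1),
    cg = 0, chg = 0, chh = 0,
    cg_s = runif(n), chg_s = runif(n), chh_s = NA_real_,
    rate = 0, rate_s = runif(n)
  )
  ct$chh_s <- ct$rate_s          # exact equality -> r = 1
  rep <- correlate_contexts(ct)
  expect_equal(rep$r[rep$context == "CHH"], 1)
  expect_true(rep$significant[rep$context == "CHH"])

  ct0 <- ct
  ct0$rate_s <- 3                # constant rate -> zero variance
  rep0 <- correlate_contexts(ct0)
  expect_true(all(is.na(rep0$r)))
  expect_equal(unique(rep0$note), "zero variance")
})

test_that("correlations are invariant to affine rescaling of a feature", {
  ct <- make_species_ct(500, coupling = 0.8, n_chrom = 1, n_windows = 80)
  r1 <- correlate_contexts(ct)
  ct2 <- ct
  ct2$chh_s <- 10 * ct2$chh_s + 3
  r2 <- correlate_contexts(ct2)
  expect_equal(r2$r, r1$r, tolerance = 1e-12)
})
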