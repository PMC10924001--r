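test_that("Kosambi function matches its closed form and inverse", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.25), 25 * log(3))
  # small-r regime: relative deviation from 100 r is (4/3) r^2 + O(r^4)
  expect_equal(kosambi_cm(0.01), 100 * 0.01 * (1 + (4 / 3) * 0.01^2),
               tolerance = 1e-7)
  # strictly increasing
  grid <- seq(0, 0.499, by = 0.001)
  expect_true(all(diff(kosambi_cm(grid)) > 0))
  # analytic inverse round-trips to 1e-12
  expect_true(all(abs(kosambi_inv(kosambi_cm(grid)) - grid) < 1e-12))
  expect_error(kosambi_cm(0.5), class = "methrecomb_validation_error")
  expect_error(kosambi_inv(-1), class = "methrecomb_validation_error")
})

test_that("recombination fractions count informative individuals", {
  a <- rep("A", 10)
  expect_equal(recombination_fraction(a, a), list(r = 0, n = 10L, d = 0L))
  b <- a; b[1:2] <- "B"
  expect_equal(recombination_fraction(a, b)$r, 0.2)
  b2 <- b; b2[8:10] <- NA
  fr <- recombination_fraction(a, b2)
  expect_equal(fr$n, 7L)
  expect_equal(fr$r, 2 / 7)
  expect_true(is.na(recombination_fraction(a, rep(NA_character_, 10))$r))
})

test_that("grid imputation copies the nearest marker row with lower-position ties", {
  gm <- tibble::tibble(
    marker_id = c("m1", "m2"), chrom = "chr1", pos_bp = c(40000, 260000),
    i1 = c("A", "B"), i2 = c("B", "B")
  )
  grid <- impute_genotype_grid(gm, step = 1e5,
                               chrom_lengths = c(chr1 = 3e5))
  # grid 100 kb: |100-40| = 60 < |260-100| = 160 -> m1
  # grid 200 kb: |200-40| = 160 > |260-200| = 60 -> m2
  expect_equal(grid$source_marker, c("m1", "m2", "m2"))
  expect_equal(grid$i1, c("A", "B", "B"))

  # exact midpoint: markers at 50k and 150k, grid at 100k -> lower marker
  gm2 <- tibble::tibble(
    marker_id = c("a", "b"), chrom = "chr1", pos_bp = c(50000, 150000),
    i1 = c("A", "B")
  )
  grid2 <- impute_genotype_grid(gm2, step = 1e5,
                                chrom_lengths = c(chr1 = 2e5))
  expect_equal(grid2$source_marker[1], "a")
})

test_that("single-marker chromosomes give flat maps and zero rates", {
  gm <- tibble::tibble(marker_id = "m1", chrom = "chr1", pos_bp = 150000,
                       i1 = c("A"), i2 = c("B"))
  gmap <- map_from_genotypes(gm, step = 1e5)
  expect_true(all(gmap$cM == 0))
  rt <- rates_from_map(gmap, window_size = 1e5)
  expect_true(all(rt$rate[!is.na(rt$rate)] == 0))
})

test_that("two grid intervals with r = 0.1 each accumulate the closed form", {
  # 10 individuals, 1 flip between consecutive rows -> r = 0.1 per interval
  calls <- rbind(rep("A", 10),
                 c("B", rep("A", 9)),
                 c("B", "B", rep("A", 8)))
  gm <- tibble::tibble(marker_id = c("m1", "m2", "m3"), chrom = "chr1",
                       pos_bp = c(1e5, 2e5, 3e5))
  for (j in 1:10) gm[[sprintf("i%02d", j)]] <- calls[, j]
  gmap <- map_from_genotypes(gm, step = 1e5)
  expect_equal(max(gmap$cM), 2 * 25 * log(1.2 / 0.8), tolerance = 1e-12)
})

test_that("rates difference the map and flag the last window as undefined", {
  gmap <- tibble::tibble(chrom = "chr1", grid_bp = (1:6) * 1e5,
                         cM = c(0, 1, 2, 3, 4, 5))
  rt <- rates_from_map(gmap, window_size = 1e5)
  expect_equal(rt$rate, c(1, 1, 1, 1, 1, NA))
  expect_equal(rt$window_index, 0:5)

  # plateau across a centromere: zero rates there
  gmap2 <- tibble::tibble(chrom = "chr1", grid_bp = (1:6) * 1e5,
                          cM = c(0, 2, 2, 2, 3, 4))
  rt2 <- rates_from_map(gmap2, window_size = 1e5)
  expect_equal(rt2$rate, c(2, 0, 0, 1, 1, NA))

  # telescoping: defined rates sum exactly to the map span
  expect_equal(sum(rt2$rate, na.rm = TRUE), max(gmap2$cM) - min(gmap2$cM))
})

test_that("marker-level maps are imputed to the window grid by nearest anchor", {
  # anchors (0 bp, 0 cM), (250 kb, 5 cM), W = 100 kb, chromosome 300 kb:
  # grid 100k -> anchor@0 (100 < 150), 200k -> anchor@250k, 300k -> 250k
  # grid cM = (0, 5, 5); rates = (5, 0, NA)
  gmap <- tibble::tibble(marker_id = c("a1", "a2"), chrom = "chr1",
                         pos_bp = c(0, 250000), pos_cM = c(0, 5))
  rt <- rates_from_map(gmap, window_size = 1e5,
                       chrom_lengths = c(chr1 = 3e5))
  expect_equal(rt$rate, c(5, 0, NA))
})

test_that("decreasing maps beyond tolerance are rejected, tiny dips clipped", {
  bad <- tibble::tibble(chrom = "chr1", grid_bp = (1:3) * 1e5,
                        cM = c(0, 2, 1))
  expect_error(rates_from_map(bad, window_size = 1e5),
               class = "methrecomb_validation_error")
  tiny <- tibble::tibble(chrom = "chr1", grid_bp = (1:3) * 1e5,
                         cM = c(0, 1, 1 - 1e-9))
  rt <- rates_from_map(tiny, window_size = 1e5)
  expect_equal(rt$rate, c(1, 0, NA))
  expect_equal(attr(rt, "n_clipped"), 1L)
})

test_that("genotype path matches the brute-force oracle on small instances", {
  set.seed(99)
  for (trial in 1:12) {
    n_markers <- sample(2:6, 1)
    n_ind <- sample(2:8, 1)
    miss <- sample(c(0, 0.15, 0.3), 1)
    fx <- random_small_genotypes(n_markers, n_ind, miss)
    expected <- oracle_rate_path(fx$markers, fx$calls, step = 1e5)

    gmap <- map_from_genotypes(fx$gm, step = 1e5)
    expect_equal(gmap$grid_bp, expected$grid)
    expect_equal(gmap$cM, expected$cm, tolerance = 1e-12)
    rt <- rates_from_map(gmap, window_size = 1e5)
    expect_equal(rt$rate[!is.na(rt$rate)], expected$rates,
                 tolerance = 1e-12)
  }
})

test_that("genotype files round-trip and unknown calls are masked", {
  fx <- random_small_genotypes(4, 3, 0.2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(fx$gm, path)
  back <- read_genotypes(path)
  expect_equal(as.data.frame(back), as.data.frame(fx$gm))

  gm_het <- fx$gm
  gm_het$i01[1] <- "H"
  write_genotypes(gm_het, path)
  expect_warning(masked <- read_genotypes(path), "masking")
  expect_true(is.na(masked$i01[1]))
  expect_error(read_genotypes(path, strict = TRUE),
               class = "methrecomb_validation_error")
})

test_that("estimated map length recovers simulated truth within 3 SE", {
  spec <- landscape_spec(chrom_length = 5e6, window_size = 1e5,
                         total_cM = 100, seed = 123)
  truth <- make_landscape(spec)
  g <- simulate_genotypes(truth, n_individuals = 1000, seed = 123)
  gmap <- map_from_genotypes(g$genotypes, step = 1e5)
  # total crossovers ~ Poisson(n * L/100); SE of length estimate ~ 100 *
  # sqrt(L/100/n) ~ 3.2 cM at L = 100, n = 1000
  expect_lt(abs(max(gmap$cM) - 100), 3 * 100 * sqrt(1 / 1000))
})
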