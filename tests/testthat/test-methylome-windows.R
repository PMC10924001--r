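rec <- function(pos, n_meth, n_unmeth, context, tri, strand = "+",
                chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = pos, strand = strand,
                 n_meth = as.integer(n_meth),
                 n_unmeth = as.integer(n_unmeth),
                 context = context, trinucleotide = tri)
}

test_that("methylation level is the methylated read fraction", {
  expect_equal(methylation_level(3, 1), 0.75)
  expect_equal(methylation_level(0, 7), 0)
  expect_equal(methylation_level(10, 0), 1)
  expect_error(methylation_level(0, 0),
               class = "methrecomb_validation_error")
})

test_that("hand-built report produces exact window counts", {
  report <- dplyr::bind_rows(
    rec(100000, 10, 2, "CHH", "CAT"),          # boundary: window 0
    rec(100001, 10, 2, "CHH", "CAT"),          # first bp of window 1
    rec(10, 9, 3, "CHH", "CTT"),               # level 0.75 exactly
    rec(20, 8, 4, "CHH", "CTT"),               # level 2/3 -> dropped
    rec(30, 5, 1, "CHH", "CAA"),               # coverage 6 -> dropped
    rec(40, 9, 1, "CG", "CGA"),
    rec(250010, 12, 0, "CHG", "CAG", strand = "-"),
    rec(250020, 12, 0, "CHG", "CTG")
  )
  w <- filter_and_count(report, window_size = 1e5,
                        chrom_lengths = c(chr1 = 3e5))
  expect_equal(w$window_index, 0:2)
  expect_equal(w$chh, c(2L, 1L, 0L))
  expect_equal(w$cg, c(1L, 0L, 0L))
  expect_equal(w$chg, c(0L, 0L, 2L))
  expect_equal(w$start, c(1, 100001, 200001))

  # exclusive threshold drops the level == 0.75 record
  w2 <- filter_and_count(report, window_size = 1e5,
                         level_inclusive = FALSE,
                         chrom_lengths = c(chr1 = 3e5))
  expect_equal(w2$chh, c(1L, 1L, 0L))
})

test_that("three CHH records across a window boundary bin as expected", {
  report <- dplyr::bind_rows(
    rec(10, 10, 0, "CHH", "CTA"),
    rec(150010, 10, 0, "CHH", "CTA"),
    rec(150020, 10, 0, "CHH", "CTA")
  )
  w <- filter_and_count(report, window_size = 1e5,
                        chrom_lengths = c(chr1 = 2e5))
  expect_equal(w$chh, c(1L, 2L))
})

test_that("window counts conserve retained records and ignore input order", {
  sim <- simulate_methylome(
    landscape_spec(chrom_length = 4e5, window_size = 2e4, total_cM = 10,
                   cg_base = 30, chg_base = 20, chh_base = 15, seed = 12))
  w <- filter_and_count(sim$report, window_size = 2e4,
                        chrom_lengths = c(chr1 = 4e5))
  lev <- sim$report$n_meth / (sim$report$n_meth + sim$report$n_unmeth)
  cov <- sim$report$n_meth + sim$report$n_unmeth
  retained <- sim$report[lev >= 0.75 & cov >= 10, ]
  expect_equal(sum(w$cg), sum(retained$context == "CG"))
  expect_equal(sum(w$chg), sum(retained$context == "CHG"))
  expect_equal(sum(w$chh), sum(retained$context == "CHH"))

  shuffled <- sim$report[sample.int(nrow(sim$report)), ]
  w_shuf <- filter_and_count(shuffled, window_size = 2e4,
                             chrom_lengths = c(chr1 = 4e5))
  expect_equal(w_shuf, w)
})

test_that("raising thresholds never increases any window count", {
  sim <- simulate_methylome(
    landscape_spec(chrom_length = 4e5, window_size = 2e4, total_cM = 10,
                   cg_base = 30, chg_base = 20, chh_base = 15, seed = 13))
  base <- filter_and_count(sim$report, window_size = 2e4,
                           level_threshold = 0.5, min_coverage = 5,
                           chrom_lengths = c(chr1 = 4e5))
  for (thr in c(0.75, 0.9)) {
    for (mc in c(10, 20)) {
      w <- filter_and_count(sim$report, window_size = 2e4,
                            level_threshold = thr, min_coverage = mc,
                            chrom_lengths = c(chr1 = 4e5))
      expect_true(all(w$cg <= base$cg))
      expect_true(all(w$chg <= base$chg))
      expect_true(all(w$chh <= base$chh))
    }
  }
})

test_that("records with inconsistent context annotation are dropped with a count", {
  report <- dplyr::bind_rows(
    rec(10, 10, 0, "CG", "CAT"),     # CAT implies CHH, not CG
    rec(20, 10, 0, "CHH", "CTT")
  )
  expect_warning(
    w <- filter_and_count(report, window_size = 1e5,
                          chrom_lengths = c(chr1 = 1e5)),
    "contradicts"
  )
  expect_equal(attr(w, "rejected_records"), 1L)
  expect_equal(w$chh, 1L)
  expect_equal(w$cg, 0L)
})

test_that("CHH motif tally covers the nine motifs and handles strands", {
  single <- rec(10, 10, 0, "CHH", "CTT")
  tal <- tally_chh_motifs(single)
  expect_equal(tal$motif, c("CAA", "CAC", "CAT", "CCA", "CCC", "CCT",
                            "CTA", "CTC", "CTT"))
  expect_equal(tal$proportion[tal$motif == "CTT"], 1)
  expect_equal(sum(tal$proportion), 1)

  # minus-strand cytosine over plus-strand AAG at positions 1-3:
  # reverse complement of AAG is CTT
  genome <- c(chr1 = "AAGTTTT")
  minus <- rec(3, 10, 0, "CHH", "CTT", strand = "-")
  tal2 <- tally_chh_motifs(minus, genome = genome)
  expect_equal(tal2$count[tal2$motif == "CTT"], 1L)
  expect_equal(sum(tal2$count), 1L)
})

test_that("motif proportions recover generator frequencies within 3 SE", {
  set.seed(41)
  motifs <- c("CAA", "CAC", "CAT", "CCA", "CCC", "CCT", "CTA", "CTC", "CTT")
  f <- c(0.20, 0.04, 0.18, 0.05, 0.03, 0.06, 0.14, 0.06, 0.24)
  n <- 10000
  draws <- sample(motifs, n, replace = TRUE, prob = f)
  report <- tibble::tibble(
    chrom = "chr1", pos = seq_len(n) * 10, strand = "+",
    n_meth = 10L, n_unmeth = 0L, context = "CHH", trinucleotide = draws
  )
  tal <- tally_chh_motifs(report)
  se <- sqrt(f * (1 - f) / n)
  expect_true(all(abs(tal$proportion - f) <= 3 * se))
  expect_equal(sum(tal$proportion), 1, tolerance = 1e-9)
})

test_that("trinucleotides containing N are excluded and counted", {
  report <- dplyr::bind_rows(
    rec(10, 10, 0, "CHH", "CNT"),
    rec(20, 10, 0, "CHH", "CAT")
  )
  tal <- tally_chh_motifs(report)
  expect_equal(sum(tal$count), 1L)
  expect_equal(attr(tal, "rejected_records"), 1L)
})

test_that("report round-trips through write and read", {
  sim <- simulate_methylome(
    landscape_spec(chrom_length = 2e5, window_size = 2e4, total_cM = 5,
                   cg_base = 10, chg_base = 8, chh_base = 6, seed = 19),
    decoys_per_window = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cytosine_report(sim$report, path)
  back <- read_cytosine_report(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$report))
})
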