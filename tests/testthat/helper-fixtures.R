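# Shared fixtures: small synthetic species and an independent brute-force
# oracle for the genotype -> rate path.

# Consensus table for a synthetic species of `n_chrom` chromosomes of 200
# 10-kb windows each (base counts sized so windows never run out of
# cytosine sites). `enrich = 1` plus `coupling = 0` gives a methylome fully
# decoupled from recombination.
make_species_ct <- function(seed0, coupling, n_chrom = 3, enrich = 3,
                            count_scale = 1, n_windows = 200,
                            window_size = 1e4) {
  cts <- lapply(seq_len(n_chrom), function(i) {
    spec <- landscape_spec(
      chrom_length = n_windows * window_size, window_size = window_size,
      total_cM = 100,
      cg_base = 60 * count_scale, chg_base = 45 * count_scale,
      chh_base = 40 * count_scale,
      cg_peri_enrich = enrich, chg_peri_enrich = enrich,
      chh_coupling = coupling, seed = seed0 + i
    )
    ch <- paste0("chr", i)
    sim <- simulate_methylome(spec, chrom = ch, decoys_per_window = 0)
    rt <- sim$truth
    rt$rate[nrow(rt)] <- NA    # last window has no defined rate downstream
    build_consensus(sim$expected_windows, rt)
  })
  dplyr::bind_rows(cts)
}

# Independent brute-force implementation of the genotype -> windowed-rate
# path (nearest-marker imputation, pairwise recombination fractions,
# Kosambi, differencing), written with plain loops and no shared code.
oracle_rate_path <- function(markers, calls, step) {
  chrom_end <- ceiling(max(markers) / step) * step
  grid <- seq(step, chrom_end, by = step)
  rows <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    d <- abs(markers - grid[gi])
    rows[[gi]] <- calls[which(d == min(d))[1], ]   # tie -> lower position
  }
  cm <- numeric(length(grid))
  for (i in seq_len(length(grid) - 1)) {
    a <- rows[[i]]
    b <- rows[[i + 1]]
    inf <- !is.na(a) & !is.na(b)
    seg <- 0
    if (sum(inf) > 0) {
      r <- sum(a[inf] != b[inf]) / sum(inf)
      r <- min(r, 0.5 - 1e-6)
      seg <- 25 * log((1 + 2 * r) / (1 - 2 * r))
    }
    cm[i + 1] <- cm[i] + seg
  }
  list(grid = grid, cm = cm, rates = diff(cm))
}

# Random small genotype matrix where every individual keeps at least one
# non-missing call.
random_small_genotypes <- function(n_markers, n_ind, missing_rate,
                                   chrom = "chr1") {
  positions <- sort(sample.int(6e5, n_markers))
  calls <- matrix(sample(c("A", "B"), n_markers * n_ind, replace = TRUE),
                  nrow = n_markers)
  if (missing_rate > 0) {
    mask <- matrix(runif(length(calls)) < missing_rate, nrow = n_markers)
    for (j in seq_len(n_ind)) {
      if (all(mask[, j])) mask[sample.int(n_markers, 1), j] <- FALSE
    }
    calls[mask] <- NA_character_
  }
  gm <- tibble::tibble(
    marker_id = sprintf("m%02d", seq_len(n_markers)),
    chrom = chrom, pos_bp = positions
  )
  for (j in seq_len(n_ind)) gm[[sprintf("i%02d", j)]] <- calls[, j]
  list(gm = gm, markers = positions, calls = calls)
}
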