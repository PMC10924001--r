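#' Simulate a genome and its per-cytosine methylation report
#'
#' Generates (i) a random nucleotide sequence for the chromosome described
#' by `spec`, (ii) a Bismark-style per-cytosine methylation report drawn on
#' real cytosine positions of that sequence (both strands), and (iii) the
#' ground-truth table of retained-cytosine counts per window and context.
#'
#' Counts of *retained* cytosines (methylation level above the filter
#' threshold) per window are drawn first: CG and CHG means are enriched
#' pericentromerically by `cg_peri_enrich`/`chg_peri_enrich`, the CHH mean
#' mixes a flat base with the true recombination rate in proportion
#' `chh_coupling`, and all three are perturbed with negative-binomial noise
#' of dispersion `noise_dispersion`. That many cytosines of the matching
#' context are then sampled inside each window and emitted as
#' high-methylation records (underlying level in \[0.8, 1\]); the remainder
#' of the emitted records are low-methylation decoys (level in \[0, 0.6\])
#' that a 75% filter must discard. Methylated read counts are rounded so a
#' high record never drops below 0.75 and a decoy never reaches it, making
#' the expected retained counts exact rather than approximate.
#'
#' @param spec A [landscape_spec()].
#' @param truth Truth track from [make_landscape()] for the same spec. If
#'   `NULL`, it is built internally.
#' @param chrom Chromosome name.
#' @param decoys_per_window Number of low-methylation records emitted per
#'   window and context (default 50), exercising the level filter.
#' @return A list of class `sim_methylome` with elements
#'   \describe{
#'     \item{report}{tibble of per-cytosine records: `chrom`, `pos`,
#'       `strand`, `n_meth`, `n_unmeth`, `context`, `trinucleotide`.}
#'     \item{expected_windows}{tibble `chrom`, `window_index`, `start`,
#'       `end`, `cg`, `chg`, `chh` of ground-truth retained counts.}
#'     \item{genome}{named character vector of chromosome sequences.}
#'     \item{truth}{the landscape track used.}
#'   }
#' @examples
#' spec <- landscape_spec(chrom_length = 2e5, window_size = 2e4,
#'                        cg_base = 30, chg_base = 20, chh_base = 10,
#'                        seed = 4)
#' sim <- simulate_methylome(spec)
#' head(sim$report)
#' @export
simulate_methylome <- function(spec, truth = NULL, chrom = "chr1",
                               decoys_per_window = 50) {
  stopifnot(inherits(spec, "landscape_spec"))
  truth <- truth %||% make_landscape(spec, chrom = chrom)
  set.seed(spec$seed)

  genome_int <- simulate_sequence_int(spec$chrom_length, spec$gc_content)
  sites <- cytosine_sites(genome_int)
  sites$window_index <- (sites$pos - 1L) %/% as.integer(spec$window_size)

  mu <- window_count_means(spec, truth)
  expected <- truth[c("chrom", "window_index", "start", "end")]
  expected$cg <- draw_counts(mu$cg, spec$noise_dispersion)
  expected$chg <- draw_counts(mu$chg, spec$noise_dispersion)
  expected$chh <- draw_counts(mu$chh, spec$noise_dispersion)

  pieces <- vector("list", 3L)
  names(pieces) <- c("cg", "chg", "chh")
  for (ctx in names(pieces)) {
    ctx_label <- c(cg = "CG", chg = "CHG", chh = "CHH")[[ctx]]
    ctx_sites <- sites[sites$context == ctx_label, , drop = FALSE]
    avail <- tabulate(ctx_sites$window_index + 1L, nbins = nrow(expected))
    want <- expected[[ctx]]
    capped <- pmin(want, avail)
    if (any(capped < want)) {
      warn(sprintf(
        "%s: %d window(s) had fewer %s sites than the drawn count; capped",
        chrom, sum(capped < want), ctx_label
      ))
      expected[[ctx]] <- capped
    }
    n_decoy <- pmin(decoys_per_window, pmax(avail - capped, 0L))
    pieces[[ctx]] <- sample_context_records(ctx_sites, capped, n_decoy, spec)
  }

  report <- dplyr::bind_rows(pieces)
  report$chrom <- chrom
  report <- report[order(report$pos), c("chrom", "pos", "strand", "n_meth",
                                        "n_unmeth", "context",
                                        "trinucleotide")]
  genome <- int_to_dna(genome_int)
  names(genome) <- chrom

  structure(
    list(report = as_tibble(report), expected_windows = expected,
         genome = genome, truth = truth, spec = spec),
    class = "sim_methylome"
  )
}

# Random i.i.d. sequence as integers 1..4 = A, C, G, T.
simulate_sequence_int <- function(len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample.int(4L, size = len, replace = TRUE, prob = p)
}

int_to_dna <- function(x) {
  paste(c("A", "C", "G", "T")[x], collapse = "")
}

# Enumerate every cytosine on both strands with its 5'->3' trinucleotide
# (read on the cytosine's own strand) and context. Sites whose trinucleotide
# would run off the chromosome end are skipped.
cytosine_sites <- function(genome_int) {
  bases <- c("A", "C", "G", "T")
  len <- length(genome_int)

  plus_pos <- which(genome_int == 2L)
  plus_pos <- plus_pos[plus_pos <= len - 2L]
  plus_tri <- paste0(bases[genome_int[plus_pos]],
                     bases[genome_int[plus_pos + 1L]],
                     bases[genome_int[plus_pos + 2L]])

  # A minus-strand cytosine sits opposite a plus-strand G; its trinucleotide
  # is the reverse complement of the plus-strand 3-mer ending at that G.
  minus_pos <- which(genome_int == 3L)
  minus_pos <- minus_pos[minus_pos >= 3L]
  comp <- c(4L, 3L, 2L, 1L)
  minus_tri <- paste0(bases[comp[genome_int[minus_pos]]],
                      bases[comp[genome_int[minus_pos - 1L]]],
                      bases[comp[genome_int[minus_pos - 2L]]])

  out <- data.frame(
    pos = c(plus_pos, minus_pos),
    strand = rep(c("+", "-"), c(length(plus_pos), length(minus_pos))),
    trinucleotide = c(plus_tri, minus_tri),
    stringsAsFactors = FALSE
  )
  out$context <- context_of_trinuc(out$trinucleotide)
  out[!is.na(out$context), , drop = FALSE]
}

# Emit n_high retained (level >= 0.8 by construction) and n_decoy discarded
# (level <= 0.6) records per window from the available sites of one context.
sample_context_records <- function(ctx_sites, n_high, n_decoy, spec) {
  split_idx <- split(seq_len(nrow(ctx_sites)), ctx_sites$window_index)
  picks_high <- integer(0)
  picks_low <- integer(0)
  for (w in names(split_idx)) {
    wi <- as.integer(w) + 1L
    idx <- split_idx[[w]]
    nh <- n_high[wi]
    nl <- n_decoy[wi]
    chosen <- idx[sample.int(length(idx), min(nh + nl, length(idx)))]
    picks_high <- c(picks_high, chosen[seq_len(nh)])
    if (nl > 0) picks_low <- c(picks_low, chosen[nh + seq_len(nl)])
  }
  rec <- ctx_sites[c(picks_high, picks_low), , drop = FALSE]
  n_h <- length(picks_high)
  n_tot <- nrow(rec)
  coverage <- spec$min_coverage +
    rpois(n_tot, max(spec$coverage_mean - spec$min_coverage, 0))
  level <- c(runif(n_h, 0.80, 1), runif(n_tot - n_h, 0, 0.60))
  # ceiling for retained records keeps observed level >= true level >= 0.8;
  # floor for decoys keeps it <= 0.6. The 75% filter is therefore exact.
  n_meth <- c(ceiling(level[seq_len(n_h)] * coverage[seq_len(n_h)]),
              floor(level[n_h + seq_len(n_tot - n_h)] *
                      coverage[n_h + seq_len(n_tot - n_h)]))
  rec$n_meth <- as.integer(n_meth)
  rec$n_unmeth <- as.integer(coverage - n_meth)
  rec
}

#' @export
print.sim_methylome <- function(x, ...) {
  cat("<sim_methylome>\n")
  cat(sprintf("  %d cytosine records on %s (%s bp), %d windows\n",
              nrow(x$report), names(x$genome)[1],
              format(nchar(x$genome)[1], big.mark = ","),
              nrow(x$expected_windows)))
  invisible(x)
}
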