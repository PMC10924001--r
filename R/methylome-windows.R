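#' Per-cytosine methylation level
#'
#' The fraction of bisulfite reads calling a cytosine methylated,
#' `n_meth / (n_meth + n_unmeth)`. Records with zero total coverage must be
#' excluded before calling this.
#'
#' @param n_meth,n_unmeth Non-negative read counts (vectorised).
#' @return Numeric vector of levels in \[0, 1\].
#' @examples
#' methylation_level(3, 1)   # 0.75
#' @export
methylation_level <- function(n_meth, n_unmeth) {
  total <- n_meth + n_unmeth
  if (any(total < 1)) {
    stop_invalid("methylation level undefined at zero coverage")
  }
  n_meth / total
}

#' Read a Bismark-style cytosine report
#'
#' Parses the seven-column per-cytosine TSV written by Bismark's cytosine /
#' CX report step (and by [write_cytosine_report()]): chromosome, 1-based
#' position, strand, methylated count, unmethylated count, context,
#' trinucleotide. Context labels `CpG` and `CG` are both accepted and
#' normalised to `CG`.
#'
#' @param path Path to the TSV (no header).
#' @return A tibble with columns `chrom`, `pos`, `strand`, `n_meth`,
#'   `n_unmeth`, `context`, `trinucleotide`.
#' @export
read_cytosine_report <- function(path) {
  if (!file.exists(path)) {
    stop_parse(sprintf("cytosine report not found: %s", path))
  }
  out <- tryCatch(
    readr::read_tsv(
      path,
      col_names = c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                    "context", "trinucleotide"),
      col_types = readr::cols(
        chrom = readr::col_character(), pos = readr::col_double(),
        strand = readr::col_character(), n_meth = readr::col_integer(),
        n_unmeth = readr::col_integer(), context = readr::col_character(),
        trinucleotide = readr::col_character()
      ),
      progress = FALSE
    ),
    error = function(e) stop_parse(sprintf(
      "failed to parse cytosine report %s: %s", path, conditionMessage(e)
    ))
  )
  out$context[out$context == "CpG"] <- "CG"
  out
}

#' Write a cytosine report TSV
#'
#' @param report Tibble as returned by [read_cytosine_report()] or found in
#'   a [simulate_methylome()] result.
#' @param path Output path.
#' @param cpg_label Write the CG context as `CpG` (Bismark's label) instead
#'   of `CG`.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(report, path, cpg_label = TRUE) {
  assert_columns(report, c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                           "context", "trinucleotide"), "cytosine report")
  out <- report
  if (cpg_label) out$context[out$context == "CG"] <- "CpG"
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Filter cytosines and count them per context per window
#'
#' Applies the retention rule — coverage at least `min_coverage` reads and
#' methylation level at least (or strictly above) `level_threshold` — and
#' counts the retained cytosines of each context in consecutive windows of
#' `window_size` bp along each chromosome. Both strands are pooled. Windows
#' are 1-based closed intervals `[k*W + 1, (k+1)*W]`, so a cytosine at
#' position `pos` falls in `window_index = floor((pos - 1) / W)`; empty
#' windows are present with zero counts.
#'
#' Records whose context label contradicts their trinucleotide are dropped
#' with a warning, and the number dropped is attached as the
#' `rejected_records` attribute. When `chrom_lengths` is not supplied the
#' chromosome end is inferred from the last record and the output gains an
#' `inferred_length` flag column.
#'
#' @param report Cytosine report tibble ([read_cytosine_report()]).
#' @param window_size Window width in bp (default 100,000).
#' @param level_threshold Methylation-level cutoff (default 0.75).
#' @param min_coverage Minimum total reads per cytosine (default 10).
#' @param level_inclusive Retain records at exactly the threshold
#'   (default `TRUE`, i.e. `level >= threshold`).
#' @param chrom_lengths Optional named vector of chromosome lengths (bp);
#'   windows then tile each chromosome to its stated end, and a trailing
#'   partial window is kept and flagged in `partial`.
#' @return A tibble `chrom`, `window_index`, `start`, `end`, `cg`, `chg`,
#'   `chh`, `partial`, `inferred_length`; attribute `rejected_records`
#'   carries the count of malformed records dropped.
#' @examples
#' rep <- tibble::tibble(
#'   chrom = "chr1", pos = c(10, 150010, 150020), strand = "+",
#'   n_meth = 9L, n_unmeth = 1L, context = "CHH",
#'   trinucleotide = "CAT"
#' )
#' filter_and_count(rep, window_size = 1e5)
#' @export
filter_and_count <- function(report, window_size = 1e5,
                             level_threshold = 0.75, min_coverage = 10,
                             level_inclusive = TRUE, chrom_lengths = NULL) {
  assert_columns(report, c("chrom", "pos", "n_meth", "n_unmeth", "context",
                           "trinucleotide"), "cytosine report")
  assert_scalar_number(window_size, "window_size", min = 1)
  assert_scalar_number(level_threshold, "level_threshold", min = 0, max = 1)
  assert_scalar_number(min_coverage, "min_coverage", min = 1)

  implied <- context_of_trinuc(report$trinucleotide)
  bad <- is.na(implied) | implied != report$context
  n_bad <- sum(bad)
  if (n_bad > 0) {
    warn(sprintf(
      "dropped %d record(s) whose context contradicts the trinucleotide",
      n_bad
    ))
    report <- report[!bad, , drop = FALSE]
  }

  coverage <- report$n_meth + report$n_unmeth
  covered <- coverage >= min_coverage & coverage >= 1
  level <- ifelse(coverage >= 1, report$n_meth / pmax(coverage, 1), NA_real_)
  passes_level <- if (level_inclusive) level >= level_threshold
                  else level > level_threshold
  retained <- report[covered & passes_level, , drop = FALSE]

  chroms <- unique(report$chrom)
  inferred <- is.null(chrom_lengths)
  if (inferred) {
    chrom_lengths <- vapply(
      chroms,
      function(ch) max(report$pos[report$chrom == ch]),
      numeric(1)
    )
  } else {
    missing_len <- setdiff(chroms, names(chrom_lengths))
    if (length(missing_len) > 0) {
      stop_invalid(sprintf("chrom_lengths missing: %s",
                           paste(missing_len, collapse = ", ")))
    }
  }

  per_chrom <- lapply(chroms, function(ch) {
    len <- chrom_lengths[[ch]]
    nw <- as.integer(ceiling(len / window_size))
    grid <- tibble(
      chrom = ch,
      window_index = seq_len(nw) - 1L,
      start = (seq_len(nw) - 1L) * window_size + 1,
      end = pmin(seq_len(nw) * window_size, len)
    )
    sub <- retained[retained$chrom == ch, , drop = FALSE]
    widx <- as.integer((sub$pos - 1) %/% window_size)
    grid$cg <- tabulate(widx[sub$context == "CG"] + 1L, nbins = nw)
    grid$chg <- tabulate(widx[sub$context == "CHG"] + 1L, nbins = nw)
    grid$chh <- tabulate(widx[sub$context == "CHH"] + 1L, nbins = nw)
    grid$partial <- grid$end - grid$start + 1 < window_size
    grid
  })
  out <- dplyr::bind_rows(per_chrom)
  out$inferred_length <- inferred
  attr(out, "rejected_records") <- n_bad
  out
}

#' Tally CHH sub-context motifs among retained cytosines
#'
#' Counts retained CHH cytosines over the nine CHH trinucleotide motifs
#' (`CAA`, `CAC`, `CAT`, `CCA`, `CCC`, `CCT`, `CTA`, `CTC`, `CTT`). The
#' report's trinucleotide column is already 5'->3' on the cytosine's own
#' strand, so minus-strand records need no further handling; if a `genome`
#' is supplied instead, trinucleotides are looked up from the sequence and
#' minus-strand 3-mers are reverse-complemented before binning.
#'
#' @param report Retained CHH records (tibble with `pos`, `strand`,
#'   `trinucleotide`, and `chrom` when `genome` is used). Apply the level /
#'   coverage filter first (e.g. via [filter_and_count()]'s retention rule).
#' @param genome Optional named character vector of chromosome sequences
#'   (or a `Biostrings::DNAStringSet`); when given, trinucleotides are taken
#'   from the genome rather than the report.
#' @return A tibble `motif`, `count`, `proportion` over the nine motifs
#'   (proportions sum to 1 when any site was counted); attribute
#'   `rejected_records` counts sites excluded for `N` or off-pattern
#'   trinucleotides.
#' @export
tally_chh_motifs <- function(report, genome = NULL) {
  report <- report[report$context == "CHH", , drop = FALSE]
  if (!is.null(genome)) {
    assert_columns(report, c("chrom", "pos", "strand"), "CHH record table")
    if (inherits(genome, "DNAStringSet")) {
      genome <- as.character(genome)
    }
    tri <- vapply(seq_len(nrow(report)), function(i) {
      seqi <- genome[[report$chrom[i]]]
      p <- report$pos[i]
      if (report$strand[i] == "+") {
        if (p + 2 > nchar(seqi)) return(NA_character_)
        substr(seqi, p, p + 2)
      } else {
        if (p - 2 < 1) return(NA_character_)
        revcomp3(substr(seqi, p - 2, p))
      }
    }, character(1))
  } else {
    assert_columns(report, "trinucleotide", "CHH record table")
    tri <- report$trinucleotide
  }

  motifs <- chh_motifs()
  ok <- !is.na(tri) & tri %in% motifs
  counts <- table(factor(tri[ok], levels = motifs))
  total <- sum(counts)
  out <- tibble(
    motif = motifs,
    count = as.integer(counts),
    proportion = if (total > 0) as.numeric(counts) / total else rep(0, 9)
  )
  attr(out, "rejected_records") <- sum(!ok)
  out
}

#' Write a window-count table
#'
#' @param windows Tibble from [filter_and_count()].
#' @param path Output TSV path.
#' @param bed Write 0-based half-open coordinates (BED convention) instead
#'   of the default 1-based closed intervals.
#' @return `path`, invisibly.
#' @export
write_window_counts <- function(windows, path, bed = FALSE) {
  out <- windows[c("chrom", "window_index", "start", "end",
                   "cg", "chg", "chh")]
  if (bed) {
    out$start <- out$start - 1
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
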