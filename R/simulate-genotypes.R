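#' Simulate a parental-origin genotype matrix from a recombination landscape
#'
#' Draws gametes of a haploid-phase (doubled-haploid-like) mapping
#' population. Each individual receives a Poisson number of crossovers with
#' mean equal to the landscape's total genetic length in Morgans
#' (`sum(rate) / 100`); breakpoint positions are placed with density
#' proportional to the window rates (uniform within a window). The parental
#' phase starts at `A` on the left telomere and flips at every breakpoint,
#' so only phase *changes* carry recombination signal. Marker calls are then
#' read off each individual's phase and masked to missing at `missing_rate`.
#'
#' Crossover interference is deliberately not modeled: placement is pure
#' Poisson, which the estimation side (recombination fractions at 100-kb
#' spacing, where interference is negligible) tolerates.
#'
#' @param truth Landscape track from [make_landscape()] (columns `chrom`,
#'   `window_index`, `start`, `end`, `rate`).
#' @param n_individuals Number of individuals (>= 2).
#' @param markers Marker positions in bp, sorted, within the chromosome. If
#'   `NULL`, one marker per window midpoint.
#' @param missing_rate Fraction of calls masked to `NA`.
#' @param seed Integer seed.
#' @return A list of class `sim_genotypes`:
#'   \describe{
#'     \item{genotypes}{tibble `marker_id`, `chrom`, `pos_bp`, then one
#'       `A`/`B`/`NA` character column per individual.}
#'     \item{breakpoints}{tibble `individual`, `pos_bp` of true crossover
#'       positions (strictly increasing within an individual).}
#'   }
#' @examples
#' spec <- landscape_spec(chrom_length = 1e6, window_size = 1e5,
#'                        total_cM = 50, seed = 2)
#' truth <- make_landscape(spec)
#' g <- simulate_genotypes(truth, n_individuals = 20, seed = 2)
#' g$genotypes[1:3, 1:6]
#' @export
simulate_genotypes <- function(truth, n_individuals, markers = NULL,
                               missing_rate = 0, seed = 1L) {
  assert_columns(truth, c("chrom", "window_index", "start", "end", "rate"),
                 "truth track")
  assert_scalar_number(n_individuals, "n_individuals", min = 2,
                       integerish = TRUE)
  assert_scalar_number(missing_rate, "missing_rate", min = 0, max = 1)
  assert_scalar_number(seed, "seed", integerish = TRUE)
  if (length(unique(truth$chrom)) != 1L) {
    stop_invalid("simulate_genotypes works on a single chromosome track")
  }
  chrom <- truth$chrom[1]
  chrom_end <- max(truth$end)
  markers <- markers %||% ((truth$start + truth$end) / 2)
  if (is.unsorted(markers, strictly = TRUE)) {
    stop_invalid("`markers` must be strictly increasing")
  }
  if (min(markers) < 1 || max(markers) > chrom_end) {
    stop_invalid("`markers` must lie within the chromosome")
  }

  set.seed(as.integer(seed))
  total_cM <- sum(truth$rate)
  n_xo <- rpois(n_individuals, total_cM / 100)

  bp_list <- vector("list", n_individuals)
  pos_rate <- truth$rate
  for (i in seq_len(n_individuals)) {
    k <- n_xo[i]
    if (k == 0L || total_cM <= 0) {
      bp_list[[i]] <- numeric(0)
      next
    }
    win <- sample.int(nrow(truth), k, replace = TRUE, prob = pos_rate)
    pos <- truth$start[win] +
      runif(k) * (truth$end[win] - truth$start[win] + 1) - 1
    bp_list[[i]] <- sort(unique(pos))
  }

  # phase at marker m: A if an even number of breakpoints precede it
  calls <- matrix(NA_character_, nrow = length(markers),
                  ncol = n_individuals)
  for (i in seq_len(n_individuals)) {
    n_before <- findInterval(markers, bp_list[[i]])
    calls[, i] <- ifelse(n_before %% 2L == 0L, "A", "B")
  }
  if (missing_rate > 0) {
    mask <- matrix(runif(length(calls)) < missing_rate, nrow = nrow(calls))
    calls[mask] <- NA_character_
  }

  geno <- tibble(
    marker_id = sprintf("m%04d", seq_along(markers)),
    chrom = chrom, pos_bp = markers
  )
  ind_names <- sprintf("ind%03d", seq_len(n_individuals))
  for (j in seq_len(n_individuals)) geno[[ind_names[j]]] <- calls[, j]

  breakpoints <- tibble(
    individual = rep(ind_names, lengths(bp_list)),
    pos_bp = unlist(bp_list)
  )

  structure(list(genotypes = geno, breakpoints = breakpoints),
            class = "sim_genotypes")
}

#' @export
print.sim_genotypes <- function(x, ...) {
  cat("<sim_genotypes>\n")
  cat(sprintf("  %d markers x %d individuals, %d crossovers total\n",
              nrow(x$genotypes), ncol(x$genotypes) - 3L,
              nrow(x$breakpoints)))
  invisible(x)
}
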