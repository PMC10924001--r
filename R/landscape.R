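#' Specify a synthetic chromosome landscape
#'
#' A `landscape_spec` bundles every parameter of the synthetic-data
#' generator: chromosome geometry, the shape of the recombination landscape,
#' mean methylated-cytosine counts per window in each context, the coupling
#' between CHH methylation and recombination, and count noise. The defaults
#' describe an Arabidopsis-like chromosome: 20 Mb, 100-kb windows, a
#' recombination landscape that rises from the telomeres and collapses at
#' the centromere, CG/CHG methylation densest pericentromerically, and CHH
#' counts positively coupled to the recombination rate.
#'
#' @param chrom_length Chromosome length in bp. Must be at least
#'   `10 * window_size`.
#' @param window_size Window width in bp (default 100,000, the scale at
#'   which methylation counts and recombination rates are tabulated).
#' @param centromere_center Centromere midpoint in bp (default: chromosome
#'   midpoint). Must lie inside the chromosome.
#' @param centromere_halfwidth Width scale (bp) of the Gaussian centromeric
#'   suppression of recombination (default: a quarter of the chromosome,
#'   giving the broad crossover-poor interior seen in plant chromosomes);
#'   `0` disables suppression entirely.
#' @param base_rate Baseline recombination rate, cM per window, added
#'   uniformly along the chromosome.
#' @param arm_amplitude Amplitude (cM per window) of the chromosome-arm
#'   component of the recombination landscape.
#' @param total_cM If non-`NULL`, the finished landscape is rescaled so the
#'   rates sum to this genetic length (cM). Handy for simulating a
#'   chromosome of known map length.
#' @param cg_base,chg_base,chh_base Mean retained-cytosine counts per window
#'   in the CG, CHG and CHH contexts on a neutral (telomeric) window.
#' @param cg_peri_enrich,chg_peri_enrich Multiplicative pericentromeric
#'   enrichment factors (>= 1) for CG and CHG counts. The enrichment
#'   follows a heterochromatin profile: a Gaussian `meth_peri_scale` times
#'   wider than the recombination suppression, multiplied by the complement
#'   of the normalised recombination rate, so CG/CHG methylation is dense
#'   across the crossover-poor interior and sparse where crossovers
#'   concentrate (the negative coupling seen in plant genomes).
#' @param meth_peri_scale Ratio of the methylation-enrichment width to
#'   `centromere_halfwidth` (default 2).
#' @param chh_coupling Fraction in \[0, 1\] of the CHH window mean driven by
#'   the recombination landscape; `0` decouples CHH counts from
#'   recombination, `1` makes the CHH mean proportional to the true rate.
#' @param noise_dispersion Negative-binomial dispersion of window counts
#'   (`size = 1/noise_dispersion`); `0` gives Poisson counts.
#' @param coverage_mean Mean sequencing coverage per cytosine (reads).
#' @param min_coverage Guaranteed minimum coverage per emitted cytosine.
#' @param gc_content Genome GC fraction used when simulating sequence.
#' @param seed Integer seed; every stochastic draw in the generator is
#'   reproducible given the spec.
#'
#' @return An object of class `landscape_spec` (a validated named list).
#' @examples
#' spec <- landscape_spec(chrom_length = 2e6, window_size = 1e5, seed = 1)
#' spec$centromere_center
#' @export
landscape_spec <- function(chrom_length = 2e7,
                           window_size = 1e5,
                           centromere_center = NULL,
                           centromere_halfwidth = NULL,
                           base_rate = 0.05,
                           arm_amplitude = 1,
                           total_cM = NULL,
                           cg_base = 2000,
                           chg_base = 1200,
                           chh_base = 400,
                           cg_peri_enrich = 3,
                           chg_peri_enrich = 3,
                           meth_peri_scale = 2,
                           chh_coupling = 0.8,
                           noise_dispersion = 0.05,
                           coverage_mean = 20,
                           min_coverage = 10,
                           gc_content = 0.36,
                           seed = 1L) {
  assert_scalar_number(window_size, "window_size", min = 1)
  assert_scalar_number(chrom_length, "chrom_length", min = 10 * window_size)
  centromere_center <- centromere_center %||% (chrom_length / 2)
  centromere_halfwidth <- centromere_halfwidth %||% (chrom_length / 4)
  assert_scalar_number(centromere_center, "centromere_center",
                       min = 1, max = chrom_length)
  assert_scalar_number(centromere_halfwidth, "centromere_halfwidth", min = 0)
  assert_scalar_number(base_rate, "base_rate", min = 0)
  assert_scalar_number(arm_amplitude, "arm_amplitude", min = 0)
  if (!is.null(total_cM)) assert_scalar_number(total_cM, "total_cM", min = 0)
  assert_scalar_number(cg_base, "cg_base", min = 0)
  assert_scalar_number(chg_base, "chg_base", min = 0)
  assert_scalar_number(chh_base, "chh_base", min = 0)
  assert_scalar_number(cg_peri_enrich, "cg_peri_enrich", min = 1)
  assert_scalar_number(chg_peri_enrich, "chg_peri_enrich", min = 1)
  assert_scalar_number(meth_peri_scale, "meth_peri_scale", min = 0.1)
  assert_scalar_number(chh_coupling, "chh_coupling", min = 0, max = 1)
  assert_scalar_number(noise_dispersion, "noise_dispersion", min = 0)
  assert_scalar_number(coverage_mean, "coverage_mean", min = 1)
  assert_scalar_number(min_coverage, "min_coverage", min = 1)
  assert_scalar_number(gc_content, "gc_content", min = 0.05, max = 0.95)
  assert_scalar_number(seed, "seed", integerish = TRUE)

  structure(
    list(
      chrom_length = chrom_length, window_size = window_size,
      centromere_center = centromere_center,
      centromere_halfwidth = centromere_halfwidth,
      base_rate = base_rate, arm_amplitude = arm_amplitude,
      total_cM = total_cM,
      cg_base = cg_base, chg_base = chg_base, chh_base = chh_base,
      cg_peri_enrich = cg_peri_enrich, chg_peri_enrich = chg_peri_enrich,
      meth_peri_scale = meth_peri_scale,
      chh_coupling = chh_coupling, noise_dispersion = noise_dispersion,
      coverage_mean = coverage_mean, min_coverage = min_coverage,
      gc_content = gc_content, seed = as.integer(seed)
    ),
    class = "landscape_spec"
  )
}

#' @export
print.landscape_spec <- function(x, ...) {
  cat("<landscape_spec>\n")
  cat(sprintf("  chromosome: %s bp in %s-bp windows (%d windows)\n",
              format(x$chrom_length, big.mark = ","),
              format(x$window_size, big.mark = ","),
              n_windows(x)))
  cat(sprintf("  centromere: %s bp +/- %s bp\n",
              format(x$centromere_center, big.mark = ","),
              format(x$centromere_halfwidth, big.mark = ",")))
  cat(sprintf("  rate: base %.3g + arm %.3g cM/window%s\n", x$base_rate,
              x$arm_amplitude,
              if (is.null(x$total_cM)) "" else
                sprintf(" (rescaled to %.4g cM)", x$total_cM)))
  cat(sprintf("  counts/window: CG %.4g (x%.3g peri), CHG %.4g (x%.3g peri), CHH %.4g\n",
              x$cg_base, x$cg_peri_enrich, x$chg_base, x$chg_peri_enrich,
              x$chh_base))
  cat(sprintf("  chh_coupling %.3g, dispersion %.3g, seed %d\n",
              x$chh_coupling, x$noise_dispersion, x$seed))
  invisible(x)
}

n_windows <- function(spec) as.integer(ceiling(spec$chrom_length / spec$window_size))

# Pericentromeric proximity weight in [0, 1]: 1 at the centromere center,
# decaying with a Gaussian profile of scale `centromere_halfwidth * scale`.
peri_weight <- function(spec, pos, scale = 1) {
  if (spec$centromere_halfwidth <= 0) return(rep(0, length(pos)))
  exp(-((pos - spec$centromere_center) /
          (scale * spec$centromere_halfwidth))^2)
}

#' Build the true recombination landscape of a synthetic chromosome
#'
#' Evaluates the ground-truth recombination rate, in cM per window, on the
#' window grid of a [landscape_spec()]. The rate at a window midpoint `x` is
#'
#' \deqn{\rho(x) = \big(b + a \sin(\pi x / L)\big)\,s(x), \qquad
#'       s(x) = 1 - e^{-((x - c)/h)^2}}
#'
#' with baseline `b`, arm amplitude `a`, chromosome length `L`, centromere
#' center `c` and suppression scale `h`. The sine arm term peaks
#' mid-chromosome and the suppression factor `s` annihilates it at the
#' centromere, producing the pericentromeric shoulders and centromeric
#' collapse characteristic of plant crossover landscapes. `h = 0` disables
#' suppression (`s = 1`). If `spec$total_cM` is set the track is rescaled to
#' that total genetic length.
#'
#' @param spec A [landscape_spec()].
#' @param chrom Chromosome name for the output track.
#' @return A tibble with columns `chrom`, `window_index` (0-based), `start`,
#'   `end` (1-based closed bp intervals) and `rate` (cM per window, >= 0).
#' @examples
#' spec <- landscape_spec(chrom_length = 2e6, window_size = 1e5,
#'                        total_cM = 10, seed = 1)
#' truth <- make_landscape(spec)
#' sum(truth$rate)
#' @export
make_landscape <- function(spec, chrom = "chr1") {
  stopifnot(inherits(spec, "landscape_spec"))
  nw <- n_windows(spec)
  start <- (seq_len(nw) - 1L) * spec$window_size + 1
  end <- pmin(seq_len(nw) * spec$window_size, spec$chrom_length)
  mid <- (start + end) / 2
  arm <- spec$arm_amplitude * sin(pi * mid / spec$chrom_length)
  suppression <- 1 - peri_weight(spec, mid)
  rate <- pmax(0, (spec$base_rate + arm) * suppression)
  if (!is.null(spec$total_cM)) {
    total <- sum(rate)
    if (total <= 0 && spec$total_cM > 0) {
      stop_compute("landscape is identically zero; cannot rescale to total_cM")
    }
    if (total > 0) rate <- rate * spec$total_cM / total
  }
  tibble(
    chrom = chrom, window_index = seq_len(nw) - 1L,
    start = start, end = end, rate = rate
  )
}

# Expected retained-count means per window for each context, given the truth
# track. CG/CHG enrichment follows the heterochromatin profile: a broad
# pericentromeric Gaussian times the complement of the (normalised)
# recombination rate, so methylation is dense across the crossover-poor
# interior and falls off exactly where recombination rises. CHH mixes its
# base mean with the truth rate scaled to the same mean, so the overall CHH
# abundance is invariant to the coupling strength.
window_count_means <- function(spec, truth) {
  mid <- (truth$start + truth$end) / 2
  peri <- peri_weight(spec, mid, scale = spec$meth_peri_scale)
  anti <- if (max(truth$rate) > 0) 1 - truth$rate / max(truth$rate)
          else rep(1, nrow(truth))
  hetero <- peri * anti
  cg <- spec$cg_base * (1 + (spec$cg_peri_enrich - 1) * hetero)
  chg <- spec$chg_base * (1 + (spec$chg_peri_enrich - 1) * hetero)
  mean_rate <- mean(truth$rate)
  scaled_rate <- if (mean_rate > 0) truth$rate * spec$chh_base / mean_rate
                 else rep(spec$chh_base, nrow(truth))
  chh <- (1 - spec$chh_coupling) * spec$chh_base +
    spec$chh_coupling * scaled_rate
  tibble(cg = cg, chg = chg, chh = chh)
}

# Draw counts around means with negative-binomial noise (Poisson in the
# dispersion -> 0 limit).
draw_counts <- function(mu, dispersion) {
  mu <- pmax(mu, 0)
  if (dispersion <= 0) return(rpois(length(mu), mu))
  rnbinom(length(mu), size = 1 / dispersion, mu = mu)
}
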