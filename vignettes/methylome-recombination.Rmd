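---
title: "Predicting recombination landscapes from methylomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting recombination landscapes from methylomes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methrecomb)
```

This vignette is the package's own account of its science: the models each
stage implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the design choices made where the
design was genuinely open.

## 1. From cytosine reports to windowed methylation counts

The methylome enters as a Bismark-style per-cytosine report: chromosome,
1-based position, strand, methylated and unmethylated read counts, context
(CG/CHG/CHH, with H one of A, C, T), and the trinucleotide read 5'→3' on
the cytosine's own strand. A cytosine's methylation level is the fraction
of reads calling it methylated, $m = n_\text{meth} / (n_\text{meth} +
n_\text{unmeth})$.

`filter_and_count()` retains a cytosine when its coverage is at least
`min_coverage` (default 10 reads) and its level is at least
`level_threshold` (default 0.75), then counts retained cytosines per
context in consecutive windows of `window_size` bp (default 100 kb).
Design choices:

* **Threshold inclusivity.** The retention rule is inclusive
  (level ≥ 0.75) by default, with `level_inclusive = FALSE` available. At
  realistic coverages many cytosines sit exactly on a rational boundary
  (e.g. 9 of 12 reads), so the choice is observable; inclusivity matches
  the convention of reporting "≥ 75 %" tracks.
* **Minimum coverage.** Bisulfite callers do not impose a universal
  coverage floor; 10 reads is a common operating point that keeps
  level estimates within ±0.15 of truth at the 0.75 boundary. It is
  configurable and recorded in the output.
* **Coordinates.** Windows are 1-based closed intervals
  $[kW+1, (k+1)W]$; a position maps to `floor((pos - 1)/W)`. A position
  exactly at $kW$ therefore belongs to window $k-1$ — the convention of
  the underlying report format. A trailing short window is kept and
  flagged (`partial`).
* **Strands.** Both strands are pooled per window; the unit counted is
  the cytosine, not the symmetric CpG pair.
* **Malformed records** (context label contradicting the trinucleotide)
  are dropped with a warning and surfaced via the `rejected_records`
  attribute rather than silently kept or fatally rejected.

`tally_chh_motifs()` bins retained CHH cytosines over the nine CHH
trinucleotides (CAA … CTT). With H ∈ {A, C, T} there are exactly
3 × 3 = 9 such motifs; the tally is over these nine, with N-containing
trinucleotides excluded and counted separately. When the trinucleotide is
looked up from a genome rather than taken from the report, minus-strand
sites use the reverse complement of the plus-strand 3-mer ending at the
site, so the motif is always read on the cytosine's own strand.

## 2. From genotypes to windowed recombination rates

The input is a parental-origin genotype matrix: markers ordered by
physical position × individuals, each call A or B by descent. The model
population is haploid-phase (doubled-haploid-like): each individual's
chromosome is a mosaic of the two founder haplotypes and only phase
*changes* along the chromosome carry recombination information. Calls
other than A/B are treated as missing by default (`strict = TRUE` errors
instead), since the encoding is strictly biallelic by construction.

The estimation path mirrors classical map building:

1. **Grid imputation** (`impute_genotype_grid()`): for grid positions
   $W, 2W, \dots$ each row is a full copy — including its missing entries
   — of the nearest marker's row. A grid position exactly midway between
   two markers takes the lower-position marker (deterministic and
   order-independent); positions outside the marker span copy the
   terminal rows.
2. **Recombination fractions**: between consecutive grid rows,
   $r = d/n$ with $n$ the individuals non-missing in both rows and $d$
   those whose calls differ. $r$ is clamped to $0.5 - 10^{-6}$ before
   mapping; an interval with $n = 0$ contributes 0 cM and is counted in
   an `n_gaps` attribute — keeping the cumulative map defined rather than
   propagating holes.
3. **Kosambi mapping function**: $\text{cM} = 25\,\ln\frac{1+2r}{1-2r}$,
   the interference-allowing standard for plant maps; its analytic
   inverse is $r = \tfrac{1}{2}\tanh(2d)$ with $d$ in Morgans, and the
   package round-trips the pair to $10^{-12}$.
4. **Differencing** (`rates_from_map()`): window $k$'s genetic position
   is the cM of the grid row it contains, and its rate is
   $\text{cM}(k+1) - \text{cM}(k)$; the last window of each chromosome is
   undefined (`NA`). Externally supplied marker-level maps are first
   imputed to the window grid by nearest-anchor copy. Negative
   differences up to $10^{-6}$ cM (imputation artifacts) are clipped to
   zero and counted; anything larger is an error naming the offending
   anchors, because a genuinely decreasing map means corrupted input.

Two numerical consequences are worth knowing. The defined rates
telescope exactly to the map span, so the windowed track conserves total
genetic length. And the difference assigned to window $k$ physically
measures the interval between the rows in windows $k$ and $k+1$ — a
half-window offset inherent to the differencing convention; at 100-kb
resolution on smooth landscapes the effect on recovery correlations is
below $10^{-3}$ and is ignored.

## 3. Consensus table, smoothing, correlations

`build_consensus()` inner-joins window counts and rates on (chromosome,
window), drops windows with undefined rate (reported via `n_dropped`),
and appends exponentially smoothed tracks: $s_1 = x_1$, $s_t = \alpha x_t
+ (1-\alpha)s_{t-1}$, per chromosome and per feature, $\alpha = 0.1$ by
default. Choices made where the procedure is underdetermined:

* **Initialisation** $s_1 = x_1$ and a single forward pass — the
  simplest scheme consistent with "damp abrupt window-to-window change";
  both are visible in the first windows of any track, and the recursion
  is exposed directly as `smooth_track()` so alternatives can be built.
* **Smoothing after the join**, so a dropped window does not leak into
  its neighbours' smoothed values through the recursion. For complete
  grids the order is irrelevant.
* **Correlations on smoothed tracks** (`correlate_contexts()`), matching
  the modeling scale; `smoothed = FALSE` gives the raw-track sensitivity
  analysis. Significance is a two-sided Pearson test at 0.05 by default,
  with no multiple-testing correction across chromosomes — the report
  flags per-chromosome evidence, it does not gate downstream steps.
  Zero-variance tracks yield `NA` with an explicit reason rather than a
  spurious coefficient.

Smoothing is linear, so the smoothed tracks inherit affine-invariance:
correlation reports are unchanged by rescaling any single feature.

## 4. Extra Trees prediction and evaluation

`fit_recomb_model()` fits extremely randomized trees via `ranger` in the
classic Extra Trees configuration: every feature considered at every
split (`mtry = p`), one random cut per feature, no bootstrap (each tree
sees all training rows), 100 trees, minimal split size 2, fixed seed.
Hyperparameters are deliberately left at these defaults — with three
smooth, strongly structured features there is little to tune, and the
package treats the model family as fixed rather than searched.

Evaluation is leave-one-chromosome-out: fit on all other chromosomes,
predict the held-out one, score with MSE, Pearson $r$, and
$R^2 = 1 - SS_\text{res}/SS_\text{tot}$ with $SS_\text{tot}$ about the
held-out chromosome's own mean. This is the standard out-of-sample
definition: $R^2$ is *not* $r^2$ and goes negative whenever the model
predicts worse than the held-out mean — which is exactly what happens,
and should be visible, when the methylome carries no recombination
signal. A held-out chromosome with zero rate variance yields `NA` with a
reason. All metrics are on the smoothed-rate scale, the only scale the
model ever sees.

`quartile_eval()` splits each chromosome's windows into four contiguous
physical blocks (remainder windows to the earlier blocks: 10 → 3,3,2,2)
and correlates predictions with observations within each block,
reporting `NA` with a reason for blocks with zero variance — e.g. a
recombination-free chromosome arm — or fewer than 3 windows.

`feature_contributions()` decomposes each prediction additively:
within each tree a row walks root → leaf, and at every split the change
in the node's training mean is credited to the split feature; averaging
over trees gives per-row, per-feature attributions with
$\text{base} + \sum_j \phi_j = \hat{y}$ holding exactly (asserted at
$10^{-6}$; in practice at machine precision, because internal node values
are reconstructed from leaf occupancies of the actual training set).
These are tree-path-dependent attributions: fast, exact in additivity,
and adequate for ranking three features — but unlike Shapley-style
attributions they are not symmetric under feature reorderings within
correlated groups, which is the known cost of the path-dependent scheme.
By default attributions are computed on the training rows of the
all-chromosome model; any row set can be supplied.

`transfer_evaluate()` trains on every chromosome of one dataset and
scores each chromosome of another, with no rescaling of features by
default — transferability of the *raw* smoothed counts is itself the
question of interest; `normalize = "per-dataset-zscore"` exists for
sensitivity analysis.

## 5. The synthetic-data generator

The generator exists so every stage above can be validated against known
truth without any external download. It emulates, per chromosome:

* a **recombination landscape** on the window grid,
  $\rho(x) = (b + a\sin(\pi x/L)) \cdot s(x)$ with Gaussian centromeric
  suppression $s(x) = 1 - e^{-((x-c)/h)^2}$; default $h = L/4$ gives the
  broad crossover-poor interior with flanking shoulders characteristic of
  plant chromosomes, and `total_cM` rescales the track to a stated
  genetic length. With $h = 0$ suppression is absent and the track is
  flat at $b$ when $a = 0$.
* **CG/CHG counts** per window with mean
  $\mu = \text{base} \cdot (1 + (\text{enrich}-1) w(x))$, where the
  heterochromatin profile $w(x)$ is a Gaussian twice the suppression
  width multiplied by the complement of the normalised rate — methylation
  dense across the crossover-poor interior, sparse where crossovers
  concentrate. The profile was chosen because plant CG/CHG methylation is
  negatively coupled to recombination at chromosome scale; a narrow
  centromeric bump alone cannot reproduce that coupling (its profile
  correlation with the rate is only about −0.4 even without noise,
  and the realised correlations then straddle zero).
* **CHH counts** with mean
  $(1-\kappa)\,\mu_\text{CHH} + \kappa\,\tilde\rho(x)$, where
  $\tilde\rho$ is the rate scaled to mean $\mu_\text{CHH}$ and
  $\kappa \in [0,1]$ (`chh_coupling`) sets how much of the CHH landscape
  is driven by recombination. $\kappa = 0$ decouples CHH from the rate
  entirely; $\kappa$ near 1 emulates the strong positive coupling seen
  in some species. The mixture preserves overall CHH abundance across
  couplings.
* **count noise**: negative binomial with dispersion `noise_dispersion`
  (`size = 1/dispersion`; Poisson in the limit 0). Over-dispersion is the
  realistic stress case for correlation recovery.
* **a genome** of i.i.d. nucleotides at configurable GC content —
  sufficient to realise all cytosine contexts and all nine CHH motifs at
  predictable frequencies. Emitted records sit on real cytosine positions
  of this genome with genome-consistent trinucleotides on both strands.
* **per-cytosine records**: for each window and context, the drawn count
  of retained cytosines is emitted with underlying methylation level in
  [0.8, 1] and methylated reads rounded *up*, plus `decoys_per_window`
  low-methylation records (level in [0, 0.6], rounded *down*) that a 75 %
  filter must discard. Rounding directions make the filter's outcome
  deterministic, so the generator's drawn counts are recovered *exactly*
  by `filter_and_count()` — a clean round-trip contract rather than a
  statistical one.
* **gametes** (`simulate_genotypes()`): each individual receives
  $\text{Poisson}(\text{map length}/100)$ crossovers placed with density
  proportional to the window rates, uniform within a window; founder
  phase is A at the left telomere and flips at each breakpoint; calls are
  masked to missing at `missing_rate`. Crossover interference is *not*
  modeled: the estimation side works at 100-kb marker spacing where
  adjacent-interval fractions are ~0.005 and the Kosambi/Haldane
  distinction is far below sampling noise.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: read-level bisulfite noise and
conversion failure (no FASTQ simulation), genome sequence structure
(repeats, genes, real motif composition), fine-scale crossover hotspots
within windows, interference, heterozygous (F2-style) populations, and
any species-specific quantitative coupling. Tests against the generator
validate the *machinery* (estimators, joins, metrics, attributions) and
the qualitative regimes, not species-level numbers.

## 6. Study conditions used by the tests and acceptance script

Problem sizes were fixed once, as desk-scale stand-ins for the real
analyses: map recovery uses one 20-Mb chromosome of 200 × 100-kb windows,
a 100-cM landscape, 500 individuals and one marker per window; the
regime-separation experiments use 10 chromosomes × 200 windows (10-kb
windows, so the same window counts at a fraction of the sequence);
correlation sign checks run 20 independent seeds. Thresholds asserted in
tests were frozen from 20-seed pilots at exactly these conditions:
estimated map length within 10 % of truth (observed ≤ 7.5 %), raw
per-window recovery correlation ≥ 0.55 (observed minimum 0.607 — the
binomial sampling floor at $n = 500$, where the per-interval standard
error of ~0.32 cM is comparable to the landscape's own 0.30 cM spread),
smoothed-track recovery ≥ 0.8 (observed minimum 0.92), strong-coupling
LOCO mean $r \ge 0.8$ and mean $R^2 \ge 0.6$ (observed ≈ 0.99), and a
decoupled-null mean $R^2 \le 0.1$ with negative per-chromosome values
(observed mean ≈ −0.1, negatives in every pilot seed).

## 7. Known limitations

* The rate estimator ignores double crossovers between grid rows within
  an interval (they cancel in $d/n$); at 100-kb spacing this bias is
  negligible, at cM-scale spacing it would not be.
* Attributions are path-dependent (see §4); do not over-interpret small
  differences between correlated features' shares.
* The smoothing recursion is causal and introduces a phase lag of about
  $1/\alpha$ windows in every smoothed track; correlations and models
  compare smoothed tracks to smoothed tracks, so the lag cancels, but
  smoothed tracks should not be compared directly to raw ones.
* `R²` comparisons across datasets inherit the scale of the smoothed
  rate; MSE values are only comparable within a dataset.
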