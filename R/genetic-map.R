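#' Kosambi mapping function
#'
#' Converts a recombination fraction `r` into additive genetic distance in
#' centimorgans, `25 * log((1 + 2r) / (1 - 2r))`. Strictly increasing on
#' `[0, 0.5)` and approximately `100 * r` for small `r`.
#'
#' @param r Recombination fraction(s), `0 <= r < 0.5`.
#' @return Distance(s) in cM.
#' @examples
#' kosambi_cm(0.25)   # 25 * log(3)
#' @export
kosambi_cm <- function(r) {
  if (any(is.na(r)) || any(r < 0) || any(r >= 0.5)) {
    stop_invalid("kosambi_cm requires 0 <= r < 0.5 (clamp upstream)")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi mapping function
#'
#' Recovers the recombination fraction from a Kosambi distance,
#' `r = tanh(2d) / 2` with `d` the distance in Morgans, i.e.
#' `r = tanh(cM / 50) / 2`.
#'
#' @param cm Distance(s) in cM, `>= 0`.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
kosambi_inv <- function(cm) {
  if (any(is.na(cm)) || any(cm < 0)) {
    stop_invalid("kosambi_inv requires cm >= 0")
  }
  tanh(cm / 50) / 2
}

#' Read a parental-origin genotype matrix
#'
#' Expects a TSV with header columns `marker_id`, `chrom`, `pos_bp`
#' followed by one column per individual, entries `A`/`B` with missing
#' encoded as any of `missing_codes`. Heterozygous or otherwise
#' unrecognised calls are treated as missing (with a warning) unless
#' `strict = TRUE`, in which case they are an error.
#'
#' @param path Path to the genotype TSV.
#' @param missing_codes Strings interpreted as missing in addition to empty
#'   fields (default `NA`, `-`, `.`).
#' @param strict Error on unrecognised calls instead of masking them.
#' @return Tibble `marker_id`, `chrom`, `pos_bp`, individuals...
#' @export
read_genotypes <- function(path, missing_codes = c("NA", "-", "."),
                           strict = FALSE) {
  if (!file.exists(path)) {
    stop_parse(sprintf("genotype file not found: %s", path))
  }
  gm <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                    na = c("", missing_codes), progress = FALSE),
    error = function(e) stop_parse(sprintf(
      "failed to parse genotype file %s: %s", path, conditionMessage(e)))
  )
  assert_columns(gm, c("marker_id", "chrom", "pos_bp"), "genotype matrix")
  gm$pos_bp <- as.numeric(gm$pos_bp)
  ind_cols <- setdiff(names(gm), c("marker_id", "chrom", "pos_bp"))
  if (length(ind_cols) == 0) stop_invalid("genotype matrix has no individuals")
  calls <- as.matrix(gm[ind_cols])
  unknown <- !is.na(calls) & !(calls %in% c("A", "B"))
  if (any(unknown)) {
    if (strict) {
      stop_invalid(sprintf("%d unrecognised genotype call(s); expected A/B",
                           sum(unknown)))
    }
    warn(sprintf("masking %d unrecognised genotype call(s) to missing",
                 sum(unknown)))
    calls[unknown] <- NA_character_
    gm[ind_cols] <- as.data.frame(calls, stringsAsFactors = FALSE)
  }
  validate_genotype_matrix(gm)
  gm
}

validate_genotype_matrix <- function(gm) {
  assert_columns(gm, c("marker_id", "chrom", "pos_bp"), "genotype matrix")
  by_chrom <- split(gm$pos_bp, gm$chrom)
  for (ch in names(by_chrom)) {
    if (is.unsorted(by_chrom[[ch]], strictly = TRUE)) {
      stop_invalid(sprintf(
        "marker positions must be strictly increasing on %s", ch))
    }
  }
  ind_cols <- setdiff(names(gm), c("marker_id", "chrom", "pos_bp"))
  calls <- as.matrix(gm[ind_cols])
  empty <- colSums(!is.na(calls)) == 0
  if (any(empty)) {
    stop_invalid(sprintf("individual(s) with no calls: %s",
                         paste(ind_cols[empty], collapse = ", ")))
  }
  invisible(gm)
}

#' Impute genotype rows onto a regular physical grid
#'
#' For grid positions `step, 2*step, ...` up to the chromosome end, each
#' grid row is a full copy (including missing entries) of the row of the
#' marker nearest in physical distance. A grid position exactly midway
#' between two markers takes the lower-position marker's row; positions
#' before the first or after the last marker copy the first or last row.
#'
#' @param gm Genotype tibble ([read_genotypes()]), single or multiple
#'   chromosomes.
#' @param step Grid spacing in bp (default 100,000).
#' @param chrom_lengths Optional named vector of chromosome lengths; the
#'   grid otherwise extends to the last marker position rounded up to a
#'   multiple of `step`.
#' @return Tibble `chrom`, `grid_bp`, `source_marker`, individuals...
#' @export
impute_genotype_grid <- function(gm, step = 1e5, chrom_lengths = NULL) {
  validate_genotype_matrix(gm)
  assert_scalar_number(step, "step", min = 1)
  ind_cols <- setdiff(names(gm), c("marker_id", "chrom", "pos_bp"))
  per_chrom <- lapply(split(gm, gm$chrom), function(sub) {
    len <- if (!is.null(chrom_lengths) && sub$chrom[1] %in% names(chrom_lengths))
      chrom_lengths[[sub$chrom[1]]]
    else ceiling(max(sub$pos_bp) / step) * step
    grid <- seq(step, len, by = step)
    idx <- nearest_index(sub$pos_bp, grid)
    out <- tibble(chrom = sub$chrom[1], grid_bp = grid,
                  source_marker = sub$marker_id[idx])
    out[ind_cols] <- sub[idx, ind_cols]
    out
  })
  dplyr::bind_rows(per_chrom)
}

# Index of the nearest value in sorted `anchors` for each `x`; ties at the
# exact midpoint resolve to the lower-position anchor.
nearest_index <- function(anchors, x) {
  lo <- findInterval(x, anchors)
  lo_c <- pmax(lo, 1L)
  hi_c <- pmin(lo + 1L, length(anchors))
  d_lo <- abs(x - anchors[lo_c])
  d_hi <- abs(anchors[hi_c] - x)
  ifelse(lo == 0L, 1L, ifelse(d_lo <= d_hi, lo_c, hi_c))
}

#' Recombination fraction between two genotype rows
#'
#' Counts individuals non-missing in both rows (`n`) and, among those, the
#' fraction whose parental-origin calls differ (`r = d / n`). The fraction
#' is clamped to `0.5 - 1e-6` before Kosambi conversion.
#'
#' @param row_i,row_j Character vectors of `A`/`B`/`NA` calls over the same
#'   individuals.
#' @return A list with `r` (clamped fraction; `NA` if no informative
#'   individuals), `n` (informative count) and `d` (differing count).
#' @export
recombination_fraction <- function(row_i, row_j) {
  if (length(row_i) != length(row_j)) {
    stop_invalid("genotype rows must cover the same individuals")
  }
  informative <- !is.na(row_i) & !is.na(row_j)
  n <- sum(informative)
  if (n == 0L) return(list(r = NA_real_, n = 0L, d = 0L))
  d <- sum(row_i[informative] != row_j[informative])
  r <- min(d / n, 0.5 - 1e-6)
  list(r = r, n = n, d = as.integer(d))
}

#' Estimate a genetic map from a genotype matrix
#'
#' Imputes rows onto the physical grid ([impute_genotype_grid()]), computes
#' the recombination fraction of each pair of consecutive grid rows,
#' converts each to centimorgans with the Kosambi function, and accumulates
#' the distances into a monotone genetic map anchored at 0 cM on the first
#' grid position. Intervals with no informative individuals contribute 0 cM
#' and are counted in the `n_gaps` attribute.
#'
#' @inheritParams impute_genotype_grid
#' @return Tibble `chrom`, `grid_bp`, `cM` (monotone non-decreasing within
#'   each chromosome); attribute `n_gaps` counts uninformative intervals.
#' @examples
#' spec <- landscape_spec(chrom_length = 1e6, window_size = 1e5,
#'                        total_cM = 20, seed = 3)
#' sim <- simulate_genotypes(make_landscape(spec), n_individuals = 50,
#'                           seed = 3)
#' map_from_genotypes(sim$genotypes, step = 1e5)
#' @export
map_from_genotypes <- function(gm, step = 1e5, chrom_lengths = NULL) {
  grid <- impute_genotype_grid(gm, step = step, chrom_lengths = chrom_lengths)
  ind_cols <- setdiff(names(grid), c("chrom", "grid_bp", "source_marker"))
  n_gaps <- 0L
  per_chrom <- lapply(split(grid, grid$chrom), function(sub) {
    calls <- as.matrix(sub[ind_cols])
    k <- nrow(sub)
    seg <- numeric(max(k - 1L, 0L))
    for (i in seq_len(k - 1L)) {
      fr <- recombination_fraction(calls[i, ], calls[i + 1L, ])
      if (is.na(fr$r)) {
        n_gaps <<- n_gaps + 1L
        seg[i] <- 0
      } else {
        seg[i] <- kosambi_cm(fr$r)
      }
    }
    tibble(chrom = sub$chrom[1], grid_bp = sub$grid_bp,
           cM = cumsum(c(0, seg)))
  })
  out <- dplyr::bind_rows(per_chrom)
  if (n_gaps > 0) {
    warn(sprintf("%d grid interval(s) had no informative individuals; 0 cM",
                 n_gaps))
  }
  attr(out, "n_gaps") <- n_gaps
  out
}

#' Read a marker-level genetic map
#'
#' @param path TSV with header `marker_id`, `chrom`, `pos_bp`, `pos_cM`.
#' @return Tibble with those columns, positions numeric.
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) {
    stop_parse(sprintf("genetic map not found: %s", path))
  }
  gmap <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(
      marker_id = "c", chrom = "c", pos_bp = "d", pos_cM = "d"
    ), progress = FALSE),
    error = function(e) stop_parse(sprintf(
      "failed to parse genetic map %s: %s", path, conditionMessage(e)))
  )
  assert_columns(gmap, c("marker_id", "chrom", "pos_bp", "pos_cM"),
                 "genetic map")
  gmap
}

#' Windowed recombination rates from a genetic map
#'
#' Assigns each window the genetic position of the grid row it contains and
#' differences consecutive windows: `rate(k) = cM(k+1) - cM(k)`, so the
#' last window of each chromosome is undefined (`NA`). Grid-level maps from
#' [map_from_genotypes()] are used as-is; marker-anchored maps
#' ([read_genetic_map()]) are first imputed to the window grid by copying
#' the cM of the nearest anchor. Tiny negative differences (imputation
#' artifacts up to 1e-6 cM) are clipped to zero and counted; larger
#' non-monotonicity is an error naming the offending anchors.
#'
#' @param map Either a grid map (`chrom`, `grid_bp`, `cM`) or a marker map
#'   (`chrom`, `pos_bp`, `pos_cM`).
#' @param window_size Window width in bp (default 100,000). For a grid map
#'   this must equal the grid spacing.
#' @param chrom_lengths Optional named lengths used when imputing a marker
#'   map to the window grid.
#' @return Tibble `chrom`, `window_index`, `start`, `end`, `rate` (cM per
#'   window; `NA` on each chromosome's last window); attribute `n_clipped`
#'   counts negative differences clipped to zero.
#' @export
rates_from_map <- function(map, window_size = 1e5, chrom_lengths = NULL) {
  assert_scalar_number(window_size, "window_size", min = 1)
  if (all(c("grid_bp", "cM") %in% names(map))) {
    grid <- map
  } else if (all(c("pos_bp", "pos_cM") %in% names(map))) {
    grid <- impute_map_grid(map, window_size, chrom_lengths)
  } else {
    stop_invalid(
      "map must have columns grid_bp/cM (grid map) or pos_bp/pos_cM (marker map)")
  }

  n_clipped <- 0L
  per_chrom <- lapply(split(grid, grid$chrom), function(sub) {
    sub <- sub[order(sub$grid_bp), , drop = FALSE]
    spacing <- unique(diff(sub$grid_bp))
    if (length(spacing) > 0 &&
        any(abs(spacing - window_size) > 1e-6)) {
      stop_invalid(sprintf(
        "grid spacing on %s does not match window_size = %g",
        sub$chrom[1], window_size))
    }
    rate <- diff(sub$cM)
    bad <- rate < -1e-6
    if (any(bad)) {
      at <- sub$grid_bp[which(bad)]
      stop_invalid(sprintf(
        "map on %s decreases by more than 1e-6 cM after bp %s",
        sub$chrom[1], paste(format(at), collapse = ", ")))
    }
    n_clipped <<- n_clipped + sum(rate < 0)
    rate <- pmax(rate, 0)
    k <- nrow(sub)
    tibble(
      chrom = sub$chrom[1],
      window_index = seq_len(k) - 1L,
      start = (seq_len(k) - 1L) * window_size + 1,
      end = seq_len(k) * window_size,
      rate = c(rate, NA_real_)
    )
  })
  out <- dplyr::bind_rows(per_chrom)
  attr(out, "n_clipped") <- n_clipped
  out
}

# Nearest-anchor imputation of a marker-level cM map onto the window grid.
impute_map_grid <- function(map, window_size, chrom_lengths = NULL) {
  per_chrom <- lapply(split(map, map$chrom), function(sub) {
    sub <- sub[order(sub$pos_bp), , drop = FALSE]
    len <- if (!is.null(chrom_lengths) && sub$chrom[1] %in% names(chrom_lengths))
      chrom_lengths[[sub$chrom[1]]]
    else ceiling(max(sub$pos_bp) / window_size) * window_size
    grid <- seq(window_size, len, by = window_size)
    idx <- nearest_index(sub$pos_bp, grid)
    tibble(chrom = sub$chrom[1], grid_bp = grid, cM = sub$pos_cM[idx])
  })
  dplyr::bind_rows(per_chrom)
}

#' Write a grid genetic map / rate track
#'
#' @param x Grid map (`chrom`, `grid_bp`, `cM`) or rate track tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_map_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
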