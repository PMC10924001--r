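# Shared validation helpers and error classes.
#
# Three error classes partition failures by stage so callers (and the
# pipeline driver) can map them to distinct exit codes:
#   methrecomb_parse_error       -- malformed input files
#   methrecomb_validation_error  -- inputs parse but violate a contract
#   methrecomb_computation_error -- a stage fails during computation

stop_parse <- function(msg, ...) {
  abort(msg, class = "methrecomb_parse_error", ...)
}

stop_invalid <- function(msg, ...) {
  abort(msg, class = "methrecomb_validation_error", ...)
}

stop_compute <- function(msg, ...) {
  abort(msg, class = "methrecomb_computation_error", ...)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(sprintf("`%s` must be a single non-missing number", name))
  }
  if (x < min || x > max) {
    stop_invalid(sprintf("`%s` = %g is outside [%g, %g]", name, x, min, max))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop_invalid(sprintf("`%s` must be a whole number", name))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_invalid(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Reverse-complement of trinucleotide strings (vectorised, base alphabet ACGTN).
revcomp3 <- function(x) {
  flipped <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Context implied by a 5'->3' trinucleotide starting at a cytosine.
context_of_trinuc <- function(tri) {
  b2 <- substr(tri, 2, 2)
  b3 <- substr(tri, 3, 3)
  ctx <- rep(NA_character_, length(tri))
  ctx[b2 == "G"] <- "CG"
  ctx[b2 %in% c("A", "C", "T") & b3 == "G"] <- "CHG"
  ctx[b2 %in% c("A", "C", "T") & b3 %in% c("A", "C", "T")] <- "CHH"
  ctx
}

# The nine CHH trinucleotide motifs (H in {A, C, T}).
chh_motifs <- function() {
  h <- c("A", "C", "T")
  paste0("C", rep(h, each = 3), rep(h, times = 3))
}
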