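#' Write genome sequences to FASTA
#'
#' @param genome Named character vector of chromosome sequences (as in a
#'   [simulate_methylome()] result) or a `Biostrings::DNAStringSet`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!inherits(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  Biostrings::writeXStringSet(genome, filepath = path)
  invisible(path)
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("FASTA not found: %s", path))
  seqs <- Biostrings::readDNAStringSet(path)
  out <- as.character(seqs)
  # FASTA headers may carry descriptions after the identifier
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write a genotype matrix TSV
#'
#' @param genotypes Tibble `marker_id`, `chrom`, `pos_bp`, individuals...
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  assert_columns(genotypes, c("marker_id", "chrom", "pos_bp"),
                 "genotype matrix")
  readr::write_tsv(genotypes, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Write a ground-truth rate track TSV
#'
#' @param truth Landscape track ([make_landscape()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_track <- function(truth, path) {
  assert_columns(truth, c("chrom", "window_index", "start", "end", "rate"),
                 "truth track")
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(path)
}

#' Read a landscape spec from a YAML config
#'
#' The file maps 1:1 onto [landscape_spec()] arguments; `seed` is
#' mandatory.
#'
#' @param path YAML file of `landscape_spec()` fields.
#' @return A `landscape_spec`.
#' @export
read_landscape_config <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("config not found: %s", path))
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_parse(sprintf(
                    "failed to parse config %s: %s", path,
                    conditionMessage(e))))
  if (is.null(cfg$seed)) stop_invalid("config must set `seed`")
  known <- names(formals(landscape_spec))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop_invalid(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  do.call(landscape_spec, cfg)
}
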