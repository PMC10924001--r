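#' Run the full methylome-to-recombination pipeline
#'
#' Wires the stages together: parse a cytosine report, filter and count per
#' window; build windowed recombination rates from a genotype matrix or a
#' genetic map; assemble and smooth the consensus table; correlate contexts
#' with recombination; run the leave-one-chromosome-out Extra Trees
#' evaluation with quartile correlations and feature attributions. All
#' tabular artifacts are written as TSV (metrics also as JSON) into
#' `out_dir`, together with a machine-readable provenance record
#' (`provenance.json`: configuration, input checksums, package version), so
#' a rerun with the same config and inputs is byte-identical.
#'
#' @param report_path Path to a Bismark-style cytosine report TSV.
#' @param genotypes_path Path to a parental-origin genotype matrix TSV
#'   (exclusive with `map_path`).
#' @param map_path Path to a marker-level genetic map TSV (exclusive with
#'   `genotypes_path`).
#' @param out_dir Output directory (created if missing).
#' @param window_size Window width in bp (default 100,000).
#' @param level_threshold Methylation-level cutoff (default 0.75).
#' @param min_coverage Minimum reads per cytosine (default 10).
#' @param alpha Exponential-smoothing factor (default 0.1).
#' @param significance_level Correlation flag threshold (default 0.05).
#' @param features Model features (default all three smoothed contexts).
#' @param seed Integer seed for the model fits.
#' @return Invisibly, a list with every stage's in-memory result
#'   (`windows`, `motifs`, `rates`, `consensus`, `correlations`, `eval`)
#'   plus `out_dir`.
#' @export
run_pipeline <- function(report_path,
                         genotypes_path = NULL,
                         map_path = NULL,
                         out_dir,
                         window_size = 1e5,
                         level_threshold = 0.75,
                         min_coverage = 10,
                         alpha = 0.1,
                         significance_level = 0.05,
                         features = c("cg_s", "chg_s", "chh_s"),
                         seed = 42L) {
  if (is.null(genotypes_path) == is.null(map_path)) {
    stop_invalid("provide exactly one of `genotypes_path` or `map_path`")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = class(e)[1], parent = e)
    })
  }

  report <- stage("methylome-windows", read_cytosine_report(report_path))
  windows <- stage("methylome-windows", filter_and_count(
    report, window_size = window_size, level_threshold = level_threshold,
    min_coverage = min_coverage))
  retained <- report[
    report$n_meth + report$n_unmeth >= min_coverage &
      report$n_meth / (report$n_meth + report$n_unmeth) >= level_threshold, ]
  motifs <- stage("motifs", tally_chh_motifs(retained))

  rates <- stage("recomb-map", {
    if (!is.null(genotypes_path)) {
      gm <- read_genotypes(genotypes_path)
      gmap <- map_from_genotypes(gm, step = window_size)
      rates_from_map(gmap, window_size = window_size)
    } else {
      gmap <- read_genetic_map(map_path)
      rates_from_map(gmap, window_size = window_size)
    }
  })

  consensus <- stage("consensus", build_consensus(windows, rates,
                                                  alpha = alpha))
  correlations <- stage("correlate", correlate_contexts(
    consensus, significance_level = significance_level))
  eval <- stage("train-predict", loco_evaluate(
    consensus, features = features, seed = seed,
    significance_level = significance_level))

  write_window_counts(windows, file.path(out_dir, "window_counts.tsv"))
  readr::write_tsv(motifs, file.path(out_dir, "chh_motifs.tsv"),
                   progress = FALSE)
  write_map_tsv(rates, file.path(out_dir, "rate_track.tsv"))
  readr::write_tsv(consensus, file.path(out_dir, "consensus.tsv"),
                   progress = FALSE)
  readr::write_tsv(correlations, file.path(out_dir, "correlations.tsv"),
                   progress = FALSE)
  readr::write_tsv(tidy(eval), file.path(out_dir, "loco_metrics.tsv"),
                   progress = FALSE)
  readr::write_tsv(augment(eval), file.path(out_dir, "predictions.tsv"),
                   progress = FALSE)
  readr::write_tsv(eval$quartiles, file.path(out_dir, "quartiles.tsv"),
                   progress = FALSE)
  if (!is.null(eval$contributions)) {
    readr::write_tsv(eval$contributions$ranking,
                     file.path(out_dir, "contribution_ranking.tsv"),
                     progress = FALSE)
    readr::write_tsv(eval$contributions$phi,
                     file.path(out_dir, "contributions.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(
    c(as.list(glance(eval)),
      list(per_chromosome = tidy(eval))),
    file.path(out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )

  inputs <- c(report = report_path, genotypes = genotypes_path,
              map = map_path)
  write_provenance(out_dir, config = list(
    window_size = window_size, level_threshold = level_threshold,
    min_coverage = min_coverage, alpha = alpha,
    significance_level = significance_level, features = features,
    seed = seed
  ), inputs = inputs[!vapply(inputs, is.null, logical(1))])

  invisible(list(windows = windows, motifs = motifs, rates = rates,
                 consensus = consensus, correlations = correlations,
                 eval = eval, out_dir = out_dir))
}

write_provenance <- function(out_dir, config, inputs) {
  checksums <- vapply(inputs, function(p) unname(tools::md5sum(p)),
                      character(1))
  jsonlite::write_json(
    list(
      package = "methrecomb",
      version = as.character(utils::packageVersion("methrecomb")),
      config = config,
      inputs = as.list(checksums)
    ),
    file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(NULL)
}

#' One-command synthetic end-to-end demonstration
#'
#' Simulates two small synthetic "species" (three chromosomes each, one
#' with strong CHH-recombination coupling and one decoupled), writes their
#' raw inputs (cytosine reports, genotype matrices, genome FASTA, truth
#' tracks) under `out_dir/inputs`, runs the full pipeline on the coupled
#' species, and additionally evaluates cross-dataset transfer from the
#' coupled to the decoupled species. Deterministic given `seed`: rerunning
#' with the same seed reproduces byte-identical outputs.
#'
#' @param out_dir Output directory.
#' @param seed Integer master seed.
#' @param n_chrom Chromosomes per species (default 3).
#' @param n_windows Windows per chromosome (default 60).
#' @param window_size Window width in bp (default 20,000 — desk-scale).
#' @param n_individuals Mapping-population size (default 300).
#' @return Invisibly, the [run_pipeline()] result list, plus `transfer`
#'   (the cross-dataset `recomb_eval`).
#' @export
run_demo <- function(out_dir, seed = 42L, n_chrom = 3, n_windows = 60,
                     window_size = 2e4, n_individuals = 300) {
  assert_scalar_number(seed, "seed", integerish = TRUE)
  seed <- as.integer(seed)
  in_dir <- file.path(out_dir, "inputs")
  dir.create(in_dir, showWarnings = FALSE, recursive = TRUE)

  make_species <- function(coupling, seed0, tag) {
    reports <- list(); windows <- list(); rates <- list()
    genos <- list(); truths <- list(); genomes <- character(0)
    for (i in seq_len(n_chrom)) {
      spec <- landscape_spec(
        chrom_length = n_windows * window_size, window_size = window_size,
        total_cM = 60, cg_base = 120, chg_base = 80, chh_base = 40,
        chh_coupling = coupling, seed = seed0 + i
      )
      chrom <- paste0("chr", i)
      truth <- make_landscape(spec, chrom = chrom)
      sim <- simulate_methylome(spec, truth, chrom = chrom,
                                decoys_per_window = 10)
      g <- simulate_genotypes(truth, n_individuals = n_individuals,
                              missing_rate = 0.05, seed = seed0 + 100 + i)
      reports[[i]] <- sim$report
      genos[[i]] <- g$genotypes
      truths[[i]] <- truth
      genomes[chrom] <- sim$genome
    }
    report <- dplyr::bind_rows(reports)
    geno <- dplyr::bind_rows(genos)
    truth <- dplyr::bind_rows(truths)
    write_cytosine_report(report,
                          file.path(in_dir, paste0(tag, "_report.tsv")))
    write_genotypes(geno, file.path(in_dir, paste0(tag, "_genotypes.tsv")))
    write_truth_track(truth, file.path(in_dir, paste0(tag, "_truth.tsv")))
    write_genome_fasta(genomes, file.path(in_dir, paste0(tag, ".fa")))
    list(report = file.path(in_dir, paste0(tag, "_report.tsv")),
         genotypes = file.path(in_dir, paste0(tag, "_genotypes.tsv")))
  }

  sp_a <- make_species(0.9, seed, "speciesA")
  sp_b <- make_species(0.9, seed + 1000L, "speciesB")

  res <- run_pipeline(
    report_path = sp_a$report, genotypes_path = sp_a$genotypes,
    out_dir = file.path(out_dir, "speciesA"),
    window_size = window_size, seed = seed
  )

  # consensus for species B, then cross-dataset transfer A -> B
  report_b <- read_cytosine_report(sp_b$report)
  windows_b <- filter_and_count(report_b, window_size = window_size)
  gmap_b <- map_from_genotypes(read_genotypes(sp_b$genotypes),
                               step = window_size)
  rates_b <- rates_from_map(gmap_b, window_size = window_size)
  ct_b <- build_consensus(windows_b, rates_b)
  transfer <- transfer_evaluate(res$consensus, ct_b, seed = seed)
  readr::write_tsv(tidy(transfer),
                   file.path(out_dir, "transfer_metrics.tsv"),
                   progress = FALSE)

  out <- c(res, list(transfer = transfer))
  invisible(out)
}
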