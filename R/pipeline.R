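#' Run the classification pipeline end to end
#'
#' Reads an experiment (config file or [experiment_design()]), classifies
#' a read set (FASTQ or allele-frequency table), and writes the outcome
#' table, the per-read classification stream, the top-variant profile and
#' a run manifest into `out_dir`. Outputs are byte-stable for identical
#' inputs; timestamps live only in the manifest.
#'
#' @param config Path to a YAML experiment config, or a list with
#'   `design` and optionally `cfg` as returned by
#'   [read_experiment_config()].
#' @param reads Path to a FASTQ / allele-table file, or a reads tibble.
#' @param out_dir Output directory (created if missing).
#' @param top_n,flank Top-variant profile parameters.
#' @param quiet Suppress progress messages.
#' @return The `outcome_table`, invisibly.
#' @export
run_classify <- function(config, reads, out_dir, top_n = 10L, flank = 30L,
                         quiet = FALSE) {
  exp <- if (is.character(config)) read_experiment_config(config) else config
  design <- exp$design %||% exp
  cfg <- exp$cfg %||% classifier_config()
  stopifnot(inherits(design, "experiment_design"))

  read_path <- NULL
  if (is.character(reads)) {
    read_path <- reads
    reads <- read_reads_any(reads)
  }
  reads <- as_tibble(reads)

  note <- function(...) if (!quiet) message(sprintf(...))
  note("classify: %d reads (%d total counts) against %s",
       nrow(reads), sum(reads$count %||% rep(1L, nrow(reads))),
       design$amplicon_name)

  cl <- classify_reads(reads, design, cfg = cfg)
  tab <- tally_outcomes(cl, cfg)
  tv <- top_variants(cl, design, n = top_n, flank = flank)
  note("classify: %d mapped, %d mutated, %d discarded",
       tab$mapped_reads, tab$mutated_reads, tab$discarded_reads)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_tab <- tidy(tab)
  out_tab$pct_of_mapped <- 100 * out_tab$frac_mapped
  out_tab$pct_of_mutated <- 100 * out_tab$frac_mutated
  readr::write_tsv(out_tab[, c("category", "count", "pct_of_mapped",
                               "pct_of_mutated")],
                   file.path(out_dir, "outcome_table.tsv"))
  readr::write_tsv(cl, file.path(out_dir, "classifications.tsv"))
  readr::write_tsv(tv, file.path(out_dir, "top_variants.tsv"))

  write_manifest(out_dir,
                 inputs = c(config = if (is.character(config)) config else NULL,
                            reads = read_path),
                 seed = NULL,
                 counts = list(input = tab$total_reads,
                               discarded = tab$discarded_reads,
                               mapped = tab$mapped_reads))
  invisible(tab)
}

#' Simulate a read set and write it to disk
#'
#' @param design A [make_fixture()] design (or config path readable by
#'   [read_experiment_config()]).
#' @param mix A [mixture_spec()].
#' @param out_dir Output directory.
#' @param quiet Suppress messages.
#' @return A list with the paths of the FASTQ and truth-label TSV.
#' @export
run_simulate <- function(design, mix, out_dir, quiet = FALSE) {
  if (is.character(design)) design <- read_experiment_config(design)$design
  stopifnot(inherits(design, "experiment_design"), inherits(mix, "mixture_spec"))
  sim <- simulate_reads(design, mix)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fastq <- file.path(out_dir, "reads.fastq")
  truth <- file.path(out_dir, "truth.tsv")
  write_fastq(sim$reads, fastq)
  readr::write_tsv(sim$truth, truth)
  write_experiment_config(design, file.path(out_dir, "experiment.yaml"))
  if (!quiet) message(sprintf("simulate: wrote %d reads to %s", nrow(sim$reads), fastq))
  write_manifest(out_dir, inputs = NULL, seed = mix$seed,
                 counts = list(input = nrow(sim$reads),
                               discarded = 0L, mapped = nrow(sim$reads)))
  list(fastq = fastq, truth = truth)
}

#' Compute long-read deletion statistics
#'
#' @param treated Coverage TSV path (see [read_coverage_tsv()]), a
#'   `coverage_profile`, or an aligned-read tibble plus `amplicon_length`.
#' @param control Optional control input of the same forms.
#' @param amplicon_length Required when passing aligned-read tibbles.
#' @param quiet Suppress messages.
#' @return A tibble with `deletion_proportion_treated`,
#'   `deletion_proportion_control` (`NA` without control) and
#'   `deletion_index` (`NA` without control).
#' @export
run_longread <- function(treated, control = NULL, amplicon_length = NULL,
                         quiet = FALSE) {
  as_profile <- function(x) {
    if (is.character(x)) return(read_coverage_tsv(x))
    if (inherits(x, "coverage_profile")) return(x)
    if (is.data.frame(x)) {
      if (is.null(amplicon_length)) {
        abort("amplicon_length is required for aligned-read input",
              class = "ampliclass_bad_config")
      }
      return(coverage_from_alignments(x, amplicon_length))
    }
    abort("unsupported long-read input", class = "ampliclass_bad_config")
  }
  tp <- deletion_proportion(as_profile(treated))
  cp <- if (!is.null(control)) deletion_proportion(as_profile(control)) else NA_real_
  idx <- if (!is.null(control)) tp - cp else NA_real_
  if (!quiet) {
    message(sprintf("deletion proportion (treated) = %.4f", tp))
    if (!is.null(control)) {
      message(sprintf("deletion proportion (control) = %.4f; deletion index = %.4f",
                      cp, idx))
    }
  }
  tibble(deletion_proportion_treated = tp,
         deletion_proportion_control = cp,
         deletion_index = idx)
}

# one manifest per output directory: version, inputs, digests, seed, counts
write_manifest <- function(out_dir, inputs, seed, counts) {
  digests <- NULL
  if (!is.null(inputs)) {
    inputs <- inputs[!vapply(inputs, is.null, logical(1))]
    existing <- vapply(inputs, file.exists, logical(1))
    digests <- as.list(tools::md5sum(unlist(inputs[existing])))
  }
  manifest <- list(
    tool = "ampliclass",
    version = as.character(utils::packageVersion("ampliclass")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = digests,
    seed = seed,
    read_counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
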