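#' Read amplicon reads from FASTQ
#'
#' Sanger (Phred+33) FASTQ, single-end or pre-merged.
#'
#' @param path FASTQ file path.
#' @return Tibble with `read_id`, `sequence`, `quality`, `count` (= 1).
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    read_id = names(x) %||% sprintf("read_%06d", seq_along(x)),
    sequence = unname(as.character(x)),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities)),
    count = 1L
  )
}

#' Write reads to FASTQ
#'
#' @param reads Tibble with `read_id`, `sequence` and optional `quality`
#'   (defaults to Q40 for every base).
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  reads <- as_tibble(reads)
  qual <- if ("quality" %in% names(reads)) reads$quality else strrep("I", nchar(reads$sequence))
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Read a pre-computed allele-frequency table
#'
#' Tab-delimited table with columns `aligned_sequence` and `read_count`
#' (the variant-table export dialect of amplicon variant callers). Only
#' the sequence and the count are trusted: gap characters are stripped and
#' every sequence is re-aligned internally.
#'
#' @param path TSV path.
#' @return Tibble with `read_id`, `sequence`, `count` (no qualities).
#' @export
read_allele_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("aligned_sequence", "read_count") %in% names(df))) {
    abort("allele table needs columns 'aligned_sequence' and 'read_count'",
          class = "ampliclass_bad_table")
  }
  tibble(
    read_id = sprintf("variant_%06d", seq_len(nrow(df))),
    sequence = toupper(gsub("-", "", df$aligned_sequence, fixed = TRUE)),
    count = as.integer(df$read_count)
  )
}

# read reads from FASTQ or an allele-frequency table, by extension
read_reads_any <- function(path) {
  if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)) {
    read_reads_fastq(path)
  } else {
    read_allele_table(path)
  }
}

#' Read an experiment configuration file
#'
#' Flat YAML key-value file describing one editing experiment. Recognised
#' keys: `amplicon_fasta`, `guide_name`, `protospacer`, `pam`,
#' `cut_mode`, `quant_window`, `donor_kind`, `donor_fasta` or
#' `donor_insert`, `donor_left_arm`, `donor_right_arm`, `donor_overhang`,
#' `intended_substitutions` (list of `"pos:base"`), and the classifier
#' thresholds of [classifier_config()] (`mh_min`, `nhej_indel_max`,
#' `donor_min_identity`, `hdr_requires_perfect_window`,
#' `mapped_min_score_frac`, `min_mean_qual`). Relative paths resolve
#' against the config file's directory.
#'
#' @param path YAML config path.
#' @return A list with `design` ([experiment_design()]) and `cfg`
#'   ([classifier_config()]).
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  amp_path <- resolve(cfg$amplicon_fasta)
  if (is.null(amp_path) || !file.exists(amp_path)) {
    abort("config must name an existing amplicon_fasta",
          class = "ampliclass_bad_config")
  }
  amp <- Biostrings::readDNAStringSet(amp_path)
  reference <- as.character(amp[[1]])
  amplicon_name <- names(amp)[1] %||% "amplicon"

  guide <- guide_spec(cfg$guide_name %||% "guide", cfg$protospacer, cfg$pam)

  donor <- NULL
  if (!is.null(cfg$donor_kind) && cfg$donor_kind != "none") {
    insert <- cfg$donor_insert
    if (is.null(insert) && !is.null(cfg$donor_fasta)) {
      dn <- Biostrings::readDNAStringSet(resolve(cfg$donor_fasta))
      insert <- as.character(dn[[1]])
    }
    subs <- NULL
    if (!is.null(cfg$intended_substitutions)) {
      parts <- strsplit(unlist(cfg$intended_substitutions), ":", fixed = TRUE)
      subs <- tibble(pos = as.integer(vapply(parts, `[`, "", 1)),
                     base = toupper(vapply(parts, `[`, "", 2)))
    }
    donor <- donor_spec(cfg$donor_kind, insert,
                        left_arm = cfg$donor_left_arm %||% "",
                        right_arm = cfg$donor_right_arm %||% "",
                        intended_substitutions = subs,
                        overhang = cfg$donor_overhang)
  }

  design <- experiment_design(
    reference, guide, donor = donor,
    cut_mode = cfg$cut_mode %||% "blunt",
    quant_window = cfg$quant_window %||% 8L,
    amplicon_name = amplicon_name)

  classifier <- classifier_config(
    mh_min = cfg$mh_min %||% 2L,
    nhej_indel_max = cfg$nhej_indel_max %||% 1L,
    donor_min_identity = cfg$donor_min_identity %||% 0.90,
    hdr_requires_perfect_window = cfg$hdr_requires_perfect_window %||% TRUE,
    mapped_min_score_frac = cfg$mapped_min_score_frac %||% 0.60,
    min_mean_qual = cfg$min_mean_qual %||% 20)

  list(design = design, cfg = classifier)
}

#' Write an experiment design to a config file (plus FASTA)
#'
#' Serializes a design to the flat YAML format read by
#' [read_experiment_config()], writing the amplicon (and any donor
#' payload) as FASTA next to it.
#'
#' @param design An [experiment_design()].
#' @param path Output YAML path.
#' @export
write_experiment_config <- function(design, path) {
  base_dir <- dirname(path)
  stem <- sub("\\.ya?ml$", "", basename(path))
  amp_fa <- file.path(base_dir, paste0(stem, "_amplicon.fa"))
  amp <- Biostrings::DNAStringSet(design$reference)
  names(amp) <- design$amplicon_name
  Biostrings::writeXStringSet(amp, amp_fa)
  cfg <- list(
    amplicon_fasta = basename(amp_fa),
    guide_name = design$guide$name,
    protospacer = design$guide$protospacer,
    pam = design$guide$pam,
    cut_mode = design$cut$mode,
    quant_window = design$quant_window
  )
  donor <- design$donor
  if (!is.null(donor)) {
    cfg$donor_kind <- donor$kind
    cfg$donor_insert <- donor$insert
    if (nzchar(donor$left_arm)) cfg$donor_left_arm <- donor$left_arm
    if (nzchar(donor$right_arm)) cfg$donor_right_arm <- donor$right_arm
    if (!is.null(donor$overhang)) cfg$donor_overhang <- donor$overhang
    if (!is.null(donor$intended_substitutions)) {
      cfg$intended_substitutions <-
        sprintf("%d:%s", donor$intended_substitutions$pos,
                donor$intended_substitutions$base)
    }
  } else {
    cfg$donor_kind <- "none"
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}
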