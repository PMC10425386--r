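#' Classifier configuration
#'
#' Thresholds of the repair-outcome decision cascade.
#'
#' @param mh_min Minimum junction microhomology (bp) for a deletion to be
#'   called microhomology-mediated (default 2).
#' @param nhej_indel_max Maximum indel length called NHEJ (default 1,
#'   i.e. +/-1 bp).
#' @param donor_min_identity Minimum identity (matches / payload length)
#'   for an insertion to be called a donor integration (default 0.90).
#' @param hdr_requires_perfect_window If `TRUE` (default) an HDR call
#'   additionally requires every intended substitution to be present.
#' @param mapped_min_score_frac Mapping filter: a read is mapped when its
#'   best alignment score reaches this fraction of the best-matching
#'   allele's self-alignment score (default 0.60).
#' @param min_mean_qual Mean Phred quality below which a read is discarded
#'   (default 20; ignored when no qualities are available).
#' @param ratio_denominator Categories forming the denominator of the
#'   HDR:indel ratio; `"indels"` (default) uses NHEJ + MH_DEL + OTHER,
#'   `"non_hdr_mutated"` additionally includes NHEJ_KI.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(mh_min = 2L,
                              nhej_indel_max = 1L,
                              donor_min_identity = 0.90,
                              hdr_requires_perfect_window = TRUE,
                              mapped_min_score_frac = 0.60,
                              min_mean_qual = 20,
                              ratio_denominator = c("indels", "non_hdr_mutated")) {
  stopifnot(mh_min >= 1L, nhej_indel_max >= 1L,
            donor_min_identity > 0, donor_min_identity <= 1,
            mapped_min_score_frac > 0, mapped_min_score_frac <= 1)
  structure(list(mh_min = as.integer(mh_min),
                 nhej_indel_max = as.integer(nhej_indel_max),
                 donor_min_identity = donor_min_identity,
                 hdr_requires_perfect_window = isTRUE(hdr_requires_perfect_window),
                 mapped_min_score_frac = mapped_min_score_frac,
                 min_mean_qual = min_mean_qual,
                 ratio_denominator = match.arg(ratio_denominator)),
            class = "classifier_config")
}

OUTCOME_LEVELS <- c("UNMODIFIED", "NHEJ", "MH_DEL", "NHEJ_KI", "HDR_KI",
                    "OTHER", "DISCARDED")

#' Junction microhomology length of a deletion
#'
#' Length of the microhomology shared by the two flanks of a deletion
#' junction, computed in a placement-invariant way as the number of
#' alternative equal-length deletion placements producing the identical
#' edited sequence: the deletion of bases `del_start .. del_start +
#' del_length - 1` can shift right by `j` positions while `ref[del_start +
#' i] == ref[del_end + i]` for all `i < j` (and symmetrically left), and
#' the microhomology is the total number of valid single-base shifts. This
#' continues through repeats shorter than the deletion (homopolymers,
#' dinucleotide runs), matching the placement-count definition exactly.
#'
#' @param reference Reference sequence.
#' @param del_start 1-based first deleted base.
#' @param del_length Deletion length (bp).
#' @return Integer microhomology length (>= 0).
#' @export
#' @examples
#' mh_length("TTACGACGTT", 3, 3)  # ACG|ACG repeat: 3
#' mh_length("GGAAAAGG", 3, 2)    # AA in AAAA: 2
mh_length <- function(reference, del_start, del_length) {
  r <- charToRaw(reference)
  L <- length(r)
  s <- as.integer(del_start)
  len <- as.integer(del_length)
  stopifnot(s >= 1L, len >= 1L, s + len - 1L <= L)
  e <- s + len  # first base after the deleted segment
  k_right <- 0L
  while (e + k_right <= L && r[s + k_right] == r[e + k_right]) {
    k_right <- k_right + 1L
  }
  k_left <- 0L
  while (s - k_left - 1L >= 1L && r[s - k_left - 1L] == r[e - k_left - 1L]) {
    k_left <- k_left + 1L
  }
  k_left + k_right
}

#' Detect a donor payload within an inserted sequence
#'
#' Globally aligns an inserted sequence against the donor payload and its
#' reverse complement and reports the better-matching orientation when its
#' identity (alignment matches divided by payload length) reaches
#' `donor_min_identity`. An exact identity tie between orientations is
#' ambiguous and returns no call.
#'
#' @param inserted_seq Inserted bases from a read's reference alignment.
#' @param payload Donor payload sequence.
#' @param cfg A [classifier_config()].
#' @param scoring An [align_scoring()].
#' @return `NULL`, or a list with `orientation` (`"forward"`/`"reverse"`)
#'   and `identity`.
#' @export
detect_donor_insertion <- function(inserted_seq, payload,
                                   cfg = classifier_config(),
                                   scoring = align_scoring()) {
  if (!is_dna(inserted_seq)) return(NULL)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  idents <- vapply(c(payload, revcomp(payload)), function(target) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(inserted_seq),
      subject = Biostrings::DNAString(target),
      type = "global", substitutionMatrix = mat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    Biostrings::nmatch(aln) / nchar(payload)
  }, numeric(1), USE.NAMES = FALSE)
  if (idents[1] == idents[2]) return(NULL)
  best <- which.max(idents)
  if (idents[best] < cfg$donor_min_identity) return(NULL)
  list(orientation = c("forward", "reverse")[best], identity = idents[best])
}

#' Classify reads into repair-outcome categories
#'
#' Assigns every read to exactly one category. Reads failing the quality
#' or mapping filter are `DISCARDED`; every other read enters a first-match
#' decision cascade:
#'
#' 1. `HDR_KI` — an HDR allele exists and the read's alignment to it has no
#'    indel inside the (insert-expanded) quantification window, with all
#'    intended substitutions present.
#' 2. `NHEJ_KI` — the reference alignment carries exactly one in-window
#'    indel, an insertion matching the donor payload in either orientation.
#' 3. `UNMODIFIED` — no in-window indel against the reference
#'    (substitution-only reads count here: sequencing errors dominate and
#'    the outcome scheme has no substitution class).
#' 4. `NHEJ` — exactly one in-window indel of length <= `nhej_indel_max`.
#' 5. `MH_DEL` — exactly one in-window deletion of length >= 2 with
#'    junction microhomology >= `mh_min`.
#' 6. `OTHER` — everything else (multi-indel reads, long insertions not
#'    matching the donor, deletions without microhomology, imperfect HDR
#'    junctions).
#'
#' @param reads Tibble with columns `read_id`, `sequence`, optional
#'   `quality` (Phred+33 string) and `count` (defaults to 1), e.g. from
#'   [read_reads_fastq()], [read_allele_table()] or [simulate_reads()].
#' @param design An [experiment_design()].
#' @param alleles Optional [build_allele_model()] result; built on the fly
#'   when the design has a donor.
#' @param cfg A [classifier_config()].
#' @param scoring An [align_scoring()].
#' @return A tibble with one row per input read: `read_id`, `count`,
#'   `category` (factor over the outcome levels), `orientation`
#'   (`NHEJ_KI` only, else `NA`), `variant_key` (canonical encoding of the
#'   in-window indels of the reference alignment; `"WT"` when none,
#'   `NA` for discarded reads).
#' @export
classify_reads <- function(reads, design, alleles = NULL,
                           cfg = classifier_config(),
                           scoring = align_scoring()) {
  stopifnot(inherits(design, "experiment_design"))
  reads <- as_tibble(reads)
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  if (!"count" %in% names(reads)) reads$count <- 1L
  stopifnot(all(reads$count >= 1L))
  if (is.null(alleles) && !is.null(design$donor)) {
    alleles <- build_allele_model(design)
  }

  # quality filter
  low_qual <- rep(FALSE, nrow(reads))
  if ("quality" %in% names(reads)) {
    has_q <- !is.na(reads$quality) & nzchar(reads$quality)
    mq <- rep(NA_real_, nrow(reads))
    mq[has_q] <- vapply(reads$quality[has_q],
                        function(q) mean(utf8ToInt(q)) - 33, numeric(1),
                        USE.NAMES = FALSE)
    low_qual <- has_q & mq < cfg$min_mean_qual
  }

  keep <- reads[!low_qual, , drop = FALSE]
  uniq <- unique(keep$sequence)
  cls <- classify_sequences(uniq, design, alleles, cfg, scoring)

  res <- tibble(read_id = reads$read_id, count = as.integer(reads$count),
                category = "DISCARDED", orientation = NA_character_,
                variant_key = NA_character_)
  idx <- match(reads$sequence, cls$sequence)
  ok <- !low_qual & !is.na(idx)
  res$category[ok] <- cls$category[idx[ok]]
  res$orientation[ok] <- cls$orientation[idx[ok]]
  res$variant_key[ok] <- cls$variant_key[idx[ok]]
  res$category <- factor(res$category, levels = OUTCOME_LEVELS)
  res
}

# classification of unique sequences (the per-read cascade)
classify_sequences <- function(sequences, design, alleles, cfg, scoring) {
  ref <- design$reference
  if (length(sequences) == 0L) {
    return(tibble(sequence = character(), category = character(),
                  orientation = character(), variant_key = character()))
  }
  ref_aln <- align_to_allele(sequences, ref, scoring)
  best_score <- ref_aln$score
  best_self <- rep(self_score(ref, scoring), length(sequences))
  hdr_aln <- NULL
  if (!is.null(alleles) && !is.null(alleles$hdr_allele)) {
    hdr_aln <- align_to_allele(sequences, alleles$hdr_allele, scoring)
    hdr_self <- self_score(alleles$hdr_allele, scoring)
    better <- hdr_aln$score > best_score
    best_score[better] <- hdr_aln$score[better]
    best_self[better] <- hdr_self
  }
  mapped <- best_score >= cfg$mapped_min_score_frac * best_self

  category <- rep("DISCARDED", length(sequences))
  orientation <- rep(NA_character_, length(sequences))
  variant_key <- rep(NA_character_, length(sequences))

  for (i in seq_along(sequences)) {
    if (!mapped[i]) next
    ev <- extract_variants(ref_aln$aligned_query[i], ref_aln$aligned_ref[i], ref)
    ev <- flag_in_window(ev, design)
    win <- ev[ev$in_window & ev$etype != "substitution", , drop = FALSE]
    variant_key[i] <- variant_key_of(win)

    # (1) HDR knock-in: perfect window against the HDR allele
    if (!is.null(hdr_aln) && hdr_matches(hdr_aln[i, ], design, alleles, cfg)) {
      category[i] <- "HDR_KI"
      next
    }
    # (2) NHEJ knock-in: a single in-window insertion carrying the payload
    if (!is.null(alleles) && !is.null(alleles$payload) &&
        nrow(win) == 1L && win$etype == "insertion") {
      hit <- detect_donor_insertion(win$seq, alleles$payload, cfg, scoring)
      if (!is.null(hit)) {
        category[i] <- "NHEJ_KI"
        orientation[i] <- hit$orientation
        next
      }
    }
    # (3) no in-window indel
    if (nrow(win) == 0L) {
      category[i] <- "UNMODIFIED"
      next
    }
    # (4) single +/-1 bp indel
    if (nrow(win) == 1L && win$length <= cfg$nhej_indel_max) {
      category[i] <- "NHEJ"
      next
    }
    # (5) single deletion >= 2 bp with junction microhomology
    if (nrow(win) == 1L && win$etype == "deletion" && win$length >= 2L &&
        mh_length(ref, win$ref_start, win$length) >= cfg$mh_min) {
      category[i] <- "MH_DEL"
      next
    }
    # (6) everything else
    category[i] <- "OTHER"
  }
  tibble(sequence = sequences, category = category,
         orientation = orientation, variant_key = variant_key)
}

# HDR rule: zero indels inside the insert-expanded window of the HDR
# allele, and (optionally) every intended substitution present
hdr_matches <- function(aln_row, design, alleles, cfg) {
  hdr <- alleles$hdr_allele
  j <- alleles$hdr_junction
  n_ins <- nchar(design$donor$insert)
  b <- design$cut$site
  w <- design$quant_window
  map_pos <- function(x) ifelse(x <= j, x, x + n_ins)   # ref -> hdr coords
  lo <- map_pos(b - w)      # inter-base window bounds on the HDR allele
  hi <- map_pos(b + w)
  ev <- extract_variants(aln_row$aligned_query, aln_row$aligned_ref, hdr)
  indel <- ev[ev$etype != "substitution", , drop = FALSE]
  if (nrow(indel) > 0L) {
    ins <- indel$etype == "insertion"
    in_win <- logical(nrow(indel))
    in_win[ins] <- indel$ref_start[ins] >= lo & indel$ref_start[ins] < hi
    in_win[!ins] <- indel$ref_start[!ins] <= hi &
      (indel$ref_start[!ins] + indel$length[!ins] - 1L) >= lo + 1L
    if (any(in_win)) return(FALSE)
  }
  if (cfg$hdr_requires_perfect_window) {
    subs <- design$donor$intended_substitutions
    if (!is.null(subs) && nrow(subs) > 0L) {
      sub_pos_hdr <- vapply(subs$pos, function(p) {
        if (p <= j) p else p + n_ins
      }, integer(1))
      ev_sub <- ev[ev$etype == "substitution", , drop = FALSE]
      if (any(ev_sub$ref_start %in% sub_pos_hdr)) return(FALSE)
    }
  }
  TRUE
}

# canonical text key of a set of in-window indel events
variant_key_of <- function(win_events) {
  if (nrow(win_events) == 0L) return("WT")
  parts <- vapply(seq_len(nrow(win_events)), function(i) {
    ev <- win_events[i, ]
    if (ev$etype == "deletion") {
      sprintf("D%d:%d", ev$ref_start, ev$length)
    } else {
      sprintf("I%d:%s", ev$ref_start, ev$seq)
    }
  }, character(1))
  paste(parts, collapse = "|")
}

# parse a variant key back into an event tibble (inverse of variant_key_of)
parse_variant_key <- function(key) {
  if (is.na(key) || key == "WT") {
    return(tibble(etype = character(), ref_start = integer(),
                  length = integer(), seq = character()))
  }
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  bind_rows(lapply(parts, function(p) {
    type <- substr(p, 1, 1)
    body <- substring(p, 2)
    fields <- strsplit(body, ":", fixed = TRUE)[[1]]
    if (type == "D") {
      tibble(etype = "deletion", ref_start = as.integer(fields[1]),
             length = as.integer(fields[2]), seq = "")
    } else {
      tibble(etype = "insertion", ref_start = as.integer(fields[1]),
             length = nchar(fields[2]), seq = fields[2])
    }
  }))
}
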