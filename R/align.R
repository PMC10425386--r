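#' Alignment scoring parameters
#'
#' Global (Needleman-Wunsch) alignment with affine gaps. The defaults
#' (match +2, mismatch -2, gap open -10, gap extend -1; a length-L gap
#' costs `gap_open + L * gap_extend`) favour one contiguous indel at the
#' cut over scattered gaps, which is the behaviour amplicon variant
#' callers rely on.
#'
#' @param match Match score (positive).
#' @param mismatch Mismatch score (negative).
#' @param gap_open Gap opening penalty (positive number, subtracted).
#' @param gap_extend Per-base gap extension penalty (positive, subtracted).
#' @return An object of class `align_scoring`.
#' @export
align_scoring <- function(match = 2, mismatch = -2, gap_open = 10, gap_extend = 1) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

#' Globally align sequences to an allele
#'
#' Thin wrapper over [Biostrings::pairwiseAlignment()] returning a tibble
#' of aligned string pairs. Deterministic for fixed inputs and scoring.
#'
#' @param sequences Character vector of read sequences.
#' @param allele Allele sequence to align against.
#' @param scoring An [align_scoring()].
#' @return A tibble with columns `sequence`, `score`, `aligned_query`,
#'   `aligned_ref` (gap character `-`).
#' @export
align_to_allele <- function(sequences, allele, scoring = align_scoring()) {
  assert_dna(allele, "allele")
  if (length(sequences) == 0L) {
    return(tibble(sequence = character(), score = numeric(),
                  aligned_query = character(), aligned_ref = character()))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(sequences),
    subject = Biostrings::DNAString(allele),
    type = "global",
    substitutionMatrix = mat,
    gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_extend)
  tibble(
    sequence = sequences,
    score = Biostrings::score(aln),
    aligned_query = as.character(Biostrings::alignedPattern(aln)),
    aligned_ref = as.character(Biostrings::alignedSubject(aln))
  )
}

# self-alignment score of an allele: perfect match over its full length
self_score <- function(allele, scoring = align_scoring()) {
  scoring$match * nchar(allele)
}

#' Extract normalized variant events from an aligned pair
#'
#' Walks a gapped alignment (query vs reference allele) and emits one row
#' per variant event in reference coordinates. Adjacent gap columns form a
#' single event; runs of mismatches are split into per-base substitutions.
#' Every indel is left-normalized to its smallest reference start among
#' sequence-equivalent placements, so equal variants always share a key.
#'
#' Coordinates: `ref_start` for deletions and substitutions is the 1-based
#' first affected base; for insertions it is the inter-base position after
#' which the bases are inserted (0 = before the first base).
#'
#' @param aligned_query,aligned_ref Gapped alignment strings of equal length.
#' @param reference The ungapped reference allele (used for normalization).
#' @return A tibble with columns `etype` (`"insertion"`, `"deletion"`,
#'   `"substitution"`), `ref_start`, `length`, `seq` (inserted bases /
#'   substituted query base, `""` for deletions), sorted by position.
#' @export
extract_variants <- function(aligned_query, aligned_ref, reference) {
  q <- strsplit(aligned_query, "", fixed = TRUE)[[1]]
  s <- strsplit(aligned_ref, "", fixed = TRUE)[[1]]
  stopifnot(length(q) == length(s))
  ref_chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  # reference position consumed at or before each column
  ref_pos <- cumsum(s != "-")
  state <- ifelse(s == "-", "insertion", ifelse(q == "-", "deletion",
                  ifelse(q == s, "match", "substitution")))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  # left shifts stop at the last reference base consumed by a previous
  # event, so events stay non-overlapping and the round trip is exact
  floor_pos <- 0L
  for (i in seq_along(r$values)) {
    st <- r$values[i]
    if (st == "match") next
    cols <- starts[i]:ends[i]
    if (st == "insertion") {
      ev <- normalize_insertion(ref_chars,
                                pos = ref_pos[starts[i]],
                                seq = paste(q[cols], collapse = ""),
                                floor_pos = floor_pos)
      out[[length(out) + 1L]] <- ev
      floor_pos <- max(floor_pos, ev$ref_start)
    } else if (st == "deletion") {
      ev <- normalize_deletion(ref_chars,
                               start = ref_pos[starts[i]],
                               len = r$lengths[i],
                               floor_pos = floor_pos)
      out[[length(out) + 1L]] <- ev
      floor_pos <- ref_pos[ends[i]]
    } else { # substitutions: one event per base
      for (cc in cols) {
        out[[length(out) + 1L]] <- tibble(etype = "substitution",
                                          ref_start = ref_pos[cc],
                                          length = 1L, seq = q[cc])
      }
      floor_pos <- ref_pos[ends[i]]
    }
  }
  if (length(out) == 0L) {
    return(tibble(etype = character(), ref_start = integer(),
                  length = integer(), seq = character()))
  }
  ev <- bind_rows(out)
  ev <- ev[order(ev$ref_start, ev$etype), , drop = FALSE]
  ev
}

# left-shift a deletion of `len` bases starting at 1-based `start`;
# `floor_pos` is the last reference position claimed by an earlier event
normalize_deletion <- function(ref_chars, start, len, floor_pos = 0L) {
  while (start > floor_pos + 1L &&
         ref_chars[start - 1L] == ref_chars[start + len - 1L]) {
    start <- start - 1L
  }
  tibble(etype = "deletion", ref_start = start, length = len, seq = "")
}

# left-shift an insertion of `seq` at inter-base `pos` (after base `pos`)
normalize_insertion <- function(ref_chars, pos, seq, floor_pos = 0L) {
  ins <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ins)
  while (pos > floor_pos && ref_chars[pos] == ins[n]) {
    ins <- c(ref_chars[pos], ins[-n])
    pos <- pos - 1L
  }
  tibble(etype = "insertion", ref_start = pos, length = n,
         seq = paste(ins, collapse = ""))
}

#' Flag events inside the quantification window
#'
#' An event is in-window when its reference interval intersects the
#' inter-base window `[site - w, site + w)` around the cut: deletions and
#' substitutions when any affected base lies within bases
#' `(site - w + 1) .. (site + w)`, insertions when the (left-normalized)
#' insertion point falls in `[site - w, site + w)`.
#'
#' @param events Event tibble from [extract_variants()].
#' @param design An [experiment_design()].
#' @return `events` with a logical `in_window` column added.
#' @export
flag_in_window <- function(events, design) {
  b <- design$cut$site
  w <- design$quant_window
  if (nrow(events) == 0L) {
    events$in_window <- logical(0)
    return(events)
  }
  iw <- logical(nrow(events))
  ins <- events$etype == "insertion"
  iw[ins] <- events$ref_start[ins] >= (b - w) & events$ref_start[ins] < (b + w)
  span <- !ins
  # bases covered: ref_start .. ref_start + length - 1
  iw[span] <- events$ref_start[span] <= (b + w) &
    (events$ref_start[span] + events$length[span] - 1L) >= (b - w + 1L)
  events$in_window <- iw
  events
}

#' Apply variant events to a reference sequence
#'
#' Reconstructs the edited sequence described by an event tibble. Used for
#' round-trip checks and for rendering variant windows.
#'
#' @param reference Reference sequence.
#' @param events Event tibble ([extract_variants()] layout).
#' @return The edited sequence.
#' @export
apply_variants <- function(reference, events) {
  if (nrow(events) == 0L) return(reference)
  chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  pieces <- as.list(chars)
  lead <- ""  # bases inserted before the first reference base
  # pass order matters where events abut at one position: substitutions
  # replace the base, deletions blank it, and insertions then append
  # after whatever remains
  for (i in which(events$etype == "substitution")) {
    pieces[[events$ref_start[i]]] <- events$seq[i]
  }
  for (i in which(events$etype == "deletion")) {
    s <- events$ref_start[i]
    pieces[s:(s + events$length[i] - 1L)] <- list("")
  }
  for (i in which(events$etype == "insertion")) {
    p <- events$ref_start[i]
    if (p == 0L) {
      lead <- paste0(lead, events$seq[i])
    } else {
      pieces[[p]] <- paste0(pieces[[p]], events$seq[i])
    }
  }
  paste0(lead, paste(unlist(pieces), collapse = ""))
}
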