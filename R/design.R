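#' Guide RNA specification
#'
#' A 20-nt SpCas9 protospacer with its NGG protospacer-adjacent motif (PAM).
#' Only SpCas9-style NGG PAMs are accepted; other nucleases are rejected.
#'
#' @param name Guide name (e.g. `"gMej"`).
#' @param protospacer 20-nt A/C/G/T string, written 5'->3' on the strand the
#'   guide matches (the protospacer strand).
#' @param pam 3-nt PAM, must match `[ACGT]GG`.
#' @return An object of class `guide_spec`.
#' @export
#' @examples
#' guide_spec("g1", "GACGATACGATACGATACGA", "TGG")
guide_spec <- function(name, protospacer, pam) {
  stopifnot(is.character(name), length(name) == 1L)
  assert_dna(protospacer, "protospacer")
  if (nchar(protospacer) != 20L) {
    abort("protospacer must be exactly 20 nt (SpCas9)",
          class = "ampliclass_bad_guide")
  }
  if (!grepl("^[ACGT]GG$", pam)) {
    abort("PAM must match NGG; only SpCas9 is supported",
          class = "ampliclass_bad_pam")
  }
  structure(
    list(name = name, protospacer = toupper(protospacer), pam = toupper(pam)),
    class = "guide_spec"
  )
}

#' Locate a protospacer on the reference amplicon
#'
#' Searches for the exact 23-mer protospacer + PAM on the forward strand and
#' its reverse complement on the reverse strand. The placement must be
#' unique: the classification coordinate frame depends on it, so zero
#' matches and multiple matches are both errors (no mismatch tolerance).
#'
#' @param reference Reference amplicon sequence.
#' @param guide A [guide_spec()].
#' @return A list with `strand` (`"+"` or `"-"`) and `protospacer_start`,
#'   the 1-based reference position of the leftmost protospacer base (for
#'   `"-"` guides this is the leftmost base of the reverse-complemented
#'   protospacer in reference coordinates).
#' @export
locate_protospacer <- function(reference, guide) {
  assert_dna(reference, "reference")
  stopifnot(inherits(guide, "guide_spec"))
  if (nchar(reference) < 23L) {
    abort("reference must be at least 23 nt", class = "ampliclass_bad_reference")
  }
  fwd23 <- paste0(guide$protospacer, guide$pam)
  rev23 <- revcomp(fwd23)
  n_fwd <- count_matches(fwd23, reference)
  n_rev <- count_matches(rev23, reference)
  total <- n_fwd + n_rev
  if (total == 0L) {
    abort(sprintf("protospacer+PAM for guide '%s' not found in reference", guide$name),
          class = "ampliclass_guide_not_found")
  }
  if (total > 1L) {
    abort(sprintf("protospacer+PAM for guide '%s' matches the reference %d times; placement must be unique",
                  guide$name, total),
          class = "ampliclass_guide_ambiguous")
  }
  if (n_fwd == 1L) {
    list(strand = "+", protospacer_start = first_match(fwd23, reference))
  } else {
    # rev23 = rc(PAM) (3 nt) followed by rc(protospacer) (20 nt)
    q <- first_match(rev23, reference)
    list(strand = "-", protospacer_start = q + 3L)
  }
}

#' Predict the SpCas9 cut geometry
#'
#' The blunt cut falls 3 nt 5' of the PAM, between protospacer positions 17
#' and 18. In `staggered_1nt` mode the cut on the protospacer-carrying
#' strand shifts one base towards the PAM-distal side, leaving 1-nt 5'
#' overhangs; the overhang base (the base between the two strand cuts) is
#' reported.
#'
#' Cut coordinates are inter-base: a cut at `c` separates base `c` from
#' base `c + 1`.
#'
#' @param reference Reference amplicon sequence.
#' @param strand Guide strand, `"+"` or `"-"`.
#' @param protospacer_start 1-based protospacer start as returned by
#'   [locate_protospacer()].
#' @param mode `"blunt"` or `"staggered_1nt"`.
#' @return A list of class `cut_geometry` with `top_cut` (protospacer
#'   strand), `bottom_cut`, `site` (the blunt position used as the anchor
#'   for quantification windows and donor splices), `mode`, and
#'   `overhang_base` (staggered mode only, else `NA`).
#' @export
predict_cut <- function(reference, strand, protospacer_start,
                        mode = c("blunt", "staggered_1nt")) {
  mode <- match.arg(mode)
  stopifnot(strand %in% c("+", "-"))
  p <- as.integer(protospacer_start)
  # inter-base blunt position: between protospacer bases 17|18, 3 nt 5' of PAM
  b <- if (strand == "+") p + 16L else p + 2L
  if (mode == "blunt") {
    geom <- list(top_cut = b, bottom_cut = b, site = b, mode = mode,
                 overhang_base = NA_character_)
  } else {
    # protospacer-strand cut moves 1 nt PAM-distal; the base between the
    # two cuts becomes the single-base 5' overhang
    if (strand == "+") {
      geom <- list(top_cut = b - 1L, bottom_cut = b, site = b, mode = mode,
                   overhang_base = substr(reference, b, b))
    } else {
      geom <- list(top_cut = b + 1L, bottom_cut = b, site = b, mode = mode,
                   overhang_base = substr(reference, b + 1L, b + 1L))
    }
  }
  structure(geom, class = "cut_geometry")
}

#' Donor specification
#'
#' Three donor chemistries are modelled:
#' * `ssodn_hdr` — single-stranded oligonucleotide with homology arms; the
#'   arms must be exact reference substrings flanking the integration
#'   junction. Drives seamless HDR knock-in, optionally with intended
#'   substitutions (PAM-blocking / silent edits) inside the arms.
#' * `dsdna_blunt` — blunt double-stranded donor without homology arms,
#'   captured by NHEJ in either orientation.
#' * `dsdna_overhang` — double-stranded donor with 1-nt 5' overhangs for
#'   directional ligation into an SpCas9 staggered cut. `insert` is the
#'   duplex core and `overhang` the single overhang base carried (as a 5'
#'   extension) on both strands; the donor's top-strand payload is
#'   `overhang + insert`.
#'
#' @param kind One of `"ssodn_hdr"`, `"dsdna_blunt"`, `"dsdna_overhang"`.
#' @param insert Donor payload (duplex core for `dsdna_overhang`).
#' @param left_arm,right_arm Homology arms (ssODN only; must be empty for
#'   dsDNA donors).
#' @param intended_substitutions Optional data frame with columns `pos`
#'   (1-based reference position) and `base`, applied to the HDR allele.
#' @param overhang Single overhang base (`dsdna_overhang` only).
#' @return An object of class `donor_spec`.
#' @export
donor_spec <- function(kind = c("ssodn_hdr", "dsdna_blunt", "dsdna_overhang"),
                       insert,
                       left_arm = "",
                       right_arm = "",
                       intended_substitutions = NULL,
                       overhang = NULL) {
  kind <- match.arg(kind)
  assert_dna(insert, "donor insert")
  if (kind == "ssodn_hdr") {
    assert_dna(left_arm, "left_arm")
    assert_dna(right_arm, "right_arm")
  } else if (nzchar(left_arm) || nzchar(right_arm)) {
    abort("dsDNA donors carry no homology arms", class = "ampliclass_bad_donor")
  }
  if (kind == "dsdna_overhang") {
    if (is.null(overhang) || !is_dna(overhang) || nchar(overhang) != 1L) {
      abort("dsdna_overhang requires a single overhang base",
            class = "ampliclass_bad_donor")
    }
  } else {
    overhang <- NULL
  }
  subs <- NULL
  if (!is.null(intended_substitutions) && nrow(as.data.frame(intended_substitutions)) > 0) {
    subs <- as_tibble(intended_substitutions)
    stopifnot(all(c("pos", "base") %in% names(subs)))
    subs$pos <- as.integer(subs$pos)
    subs$base <- toupper(subs$base)
    stopifnot(all(subs$base %in% DNA_BASES))
  }
  structure(
    list(kind = kind, insert = toupper(insert),
         left_arm = toupper(left_arm), right_arm = toupper(right_arm),
         intended_substitutions = subs, overhang = overhang),
    class = "donor_spec"
  )
}

#' Editing experiment design
#'
#' Bundles the reference amplicon, the guide placement, the predicted cut
#' geometry, the optional donor, and the quantification window half-width.
#' This is the coordinate frame used by every downstream step: variants are
#' attributed to editing only when they touch the window of `quant_window`
#' bases on either side of the cut.
#'
#' @param reference Reference amplicon sequence (or a named length-1
#'   character vector; the name becomes the amplicon name).
#' @param guide A [guide_spec()].
#' @param donor Optional [donor_spec()].
#' @param cut_mode `"blunt"` or `"staggered_1nt"`.
#' @param quant_window Window half-width in bp (default 8).
#' @param amplicon_name Amplicon name.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(reference, guide, donor = NULL,
                              cut_mode = c("blunt", "staggered_1nt"),
                              quant_window = 8L,
                              amplicon_name = NULL) {
  cut_mode <- match.arg(cut_mode)
  if (is.null(amplicon_name)) {
    amplicon_name <- names(reference) %||% "amplicon"
  }
  reference <- toupper(unname(reference))
  assert_dna(reference, "reference")
  stopifnot(inherits(guide, "guide_spec"))
  if (!is.null(donor)) stopifnot(inherits(donor, "donor_spec"))
  quant_window <- as.integer(quant_window)
  if (quant_window < 1L) {
    abort("quant_window must be >= 1", class = "ampliclass_bad_design")
  }
  placement <- locate_protospacer(reference, guide)
  cut <- predict_cut(reference, placement$strand, placement$protospacer_start,
                     cut_mode)
  if (cut$site - quant_window < 0L || cut$site + quant_window > nchar(reference)) {
    abort("quantification window extends outside the reference amplicon",
          class = "ampliclass_bad_design")
  }
  structure(
    list(amplicon_name = amplicon_name,
         reference = reference,
         guide = guide,
         guide_strand = placement$strand,
         protospacer_start = placement$protospacer_start,
         cut = cut,
         donor = donor,
         quant_window = quant_window),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> %s (%d bp)\n", x$amplicon_name, nchar(x$reference)))
  cat(sprintf("  guide %s on %s strand, protospacer at %d\n",
              x$guide$name, x$guide_strand, x$protospacer_start))
  cat(sprintf("  cut: %s at inter-base %d (window +/-%d bp)\n",
              x$cut$mode, x$cut$site, x$quant_window))
  if (!is.null(x$donor)) {
    cat(sprintf("  donor: %s, %d bp payload\n", x$donor$kind, nchar(x$donor$insert)))
  }
  invisible(x)
}

# quantification window in base coordinates: bases (site - w + 1) .. (site + w)
window_bases <- function(design) {
  b <- design$cut$site
  w <- design$quant_window
  c(lo = b - w + 1L, hi = b + w)
}
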