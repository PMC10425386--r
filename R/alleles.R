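#' Derive the expected knock-in alleles for a design
#'
#' Builds the edited sequences the classifier compares reads against:
#'
#' * ssODN donors yield a single `hdr_allele`: the reference with the
#'   intended substitutions applied and the insert spliced seamlessly at
#'   the junction defined by the homology arms.
#' * Blunt dsDNA donors yield `nhej_ki_fwd` / `nhej_ki_rev`: the payload
#'   (or its reverse complement) ligated into the blunt cut.
#' * 1-nt 5'-overhang dsDNA donors model ligation into the staggered cut.
#'   The donor's top strand is `overhang + insert` and its bottom strand
#'   carries the complementary single-base 5' overhang. An orientation
#'   whose overhang base pairs with the genomic overhang ligates seamlessly
#'   (sticky ends anneal); the incompatible orientation is modelled as
#'   fill-in of all 1-nt overhangs followed by blunt ligation, which leaves
#'   single-base anomalies at both junctions.
#'
#' @param design An [experiment_design()] with a donor.
#' @param arm_search_radius Maximum distance (bp) between the arm-defined
#'   junction and the cut site for ssODN donors.
#' @return An object of class `allele_model`: a list with `reference`,
#'   `hdr_allele`, `nhej_ki_fwd`, `nhej_ki_rev` (unused slots `NULL`),
#'   `payload` (the donor sequence used for insertion detection),
#'   `insert_coords` (1-based payload interval within the defined allele)
#'   and `hdr_junction` (ssODN only).
#' @export
build_allele_model <- function(design, arm_search_radius = 20L) {
  stopifnot(inherits(design, "experiment_design"))
  donor <- design$donor
  if (is.null(donor)) {
    abort("design has no donor; no knock-in alleles to build",
          class = "ampliclass_no_donor")
  }
  ref <- design$reference
  L <- nchar(ref)
  b <- design$cut$site

  model <- list(reference = ref, hdr_allele = NULL,
                nhej_ki_fwd = NULL, nhej_ki_rev = NULL,
                payload = NULL, insert_coords = NULL, hdr_junction = NULL)

  if (donor$kind == "ssodn_hdr") {
    arms <- paste0(donor$left_arm, donor$right_arm)
    hits <- gregexpr(arms, ref, fixed = TRUE)[[1]]
    if (length(hits) == 1L && hits[1] == -1L) hits <- integer(0)
    junctions <- as.integer(hits) + nchar(donor$left_arm) - 1L
    junctions <- junctions[abs(junctions - b) <= arm_search_radius]
    if (length(junctions) == 0L) {
      abort("homology arms do not flank the cut site within the search radius",
            class = "ampliclass_arm_mismatch")
    }
    j <- junctions[which.min(abs(junctions - b))]
    mut_ref <- apply_substitutions(ref, donor$intended_substitutions)
    model$hdr_allele <- paste0(seq_slice(mut_ref, 1L, j), donor$insert,
                               seq_slice(mut_ref, j + 1L, L))
    model$payload <- donor$insert
    model$insert_coords <- c(j + 1L, j + nchar(donor$insert))
    model$hdr_junction <- j
  } else if (donor$kind == "dsdna_blunt") {
    model$nhej_ki_fwd <- paste0(seq_slice(ref, 1L, b), donor$insert,
                                seq_slice(ref, b + 1L, L))
    model$nhej_ki_rev <- paste0(seq_slice(ref, 1L, b), revcomp(donor$insert),
                                seq_slice(ref, b + 1L, L))
    model$payload <- donor$insert
    model$insert_coords <- c(b + 1L, b + nchar(donor$insert))
  } else { # dsdna_overhang
    if (design$cut$mode != "staggered_1nt") {
      abort("an overhang donor requires cut_mode = 'staggered_1nt'",
            class = "ampliclass_bad_donor")
    }
    cuts <- sort(c(design$cut$top_cut, design$cut$bottom_cut))
    c_lo <- cuts[1]
    c_hi <- cuts[2]
    genomic_overhang <- design$cut$overhang_base  # base at position c_hi
    o <- donor$overhang
    core <- donor$insert
    top_fwd <- paste0(o, core)                    # donor top strand
    top_rev <- paste0(complement_base(o), revcomp(core)) # flipped donor top strand
    build_orient <- function(top, ov) {
      if (ov == genomic_overhang) {
        # sticky ends anneal: the donor overhang pairs the genomic overhang
        # base and both junctions seal seamlessly
        paste0(seq_slice(ref, 1L, c_lo), top, seq_slice(ref, c_hi, L))
      } else {
        # incompatible overhangs: fill-in to blunt, then ligate; the filled
        # bases and the duplicated genomic overhang base remain as 1-nt
        # junction anomalies (the donor bottom-strand overhang is comp(ov),
        # so fill-in extends the top strand by ov)
        paste0(seq_slice(ref, 1L, c_hi), top, ov, seq_slice(ref, c_hi, L))
      }
    }
    model$nhej_ki_fwd <- build_orient(top_fwd, o)
    model$nhej_ki_rev <- build_orient(top_rev, complement_base(o))
    model$payload <- top_fwd
    model$insert_coords <- c(c_lo + 1L, c_lo + nchar(top_fwd))
  }
  structure(model, class = "allele_model")
}

apply_substitutions <- function(reference, subs) {
  if (is.null(subs) || nrow(subs) == 0L) return(reference)
  chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  stopifnot(all(subs$pos >= 1L), all(subs$pos <= length(chars)))
  chars[subs$pos] <- subs$base
  paste(chars, collapse = "")
}

#' @export
print.allele_model <- function(x, ...) {
  cat("<allele_model>\n")
  for (slot in c("hdr_allele", "nhej_ki_fwd", "nhej_ki_rev")) {
    if (!is.null(x[[slot]])) {
      cat(sprintf("  %s: %d bp\n", slot, nchar(x[[slot]])))
    }
  }
  invisible(x)
}
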