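#' Mixture specification for the read simulator
#'
#' Proportions of the eight simulated repair outcomes. Proportions must
#' sum to 1; reads are drawn i.i.d. from the mixture.
#'
#' @param unmodified,nhej_plus1,nhej_minus1,mh_del,nhej_ki_fwd,nhej_ki_rev,hdr_ki,other
#'   Mixture proportions.
#' @param n_reads Number of reads to emit.
#' @param error_rate Per-base substitution error probability (0 to 0.05).
#'   Substitution-only by default: amplicon short-read error profiles are
#'   substitution-dominated and indel noise would blur the ground truth.
#' @param seed Integer seed; identical specs produce byte-identical output.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(unmodified = 0, nhej_plus1 = 0, nhej_minus1 = 0,
                         mh_del = 0, nhej_ki_fwd = 0, nhej_ki_rev = 0,
                         hdr_ki = 0, other = 0,
                         n_reads = 1000L, error_rate = 0, seed = 1L) {
  p <- c(unmodified = unmodified, nhej_plus1 = nhej_plus1,
         nhej_minus1 = nhej_minus1, mh_del = mh_del,
         nhej_ki_fwd = nhej_ki_fwd, nhej_ki_rev = nhej_ki_rev,
         hdr_ki = hdr_ki, other = other)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort("mixture proportions must be non-negative and sum to 1",
          class = "ampliclass_bad_mixture")
  }
  if (error_rate < 0 || error_rate > 0.05) {
    abort("error_rate must lie in [0, 0.05]", class = "ampliclass_bad_mixture")
  }
  stopifnot(n_reads >= 1L)
  structure(list(proportions = p, n_reads = as.integer(n_reads),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Build a synthetic editing fixture with engineered microhomology
#'
#' Generates a random amplicon carrying a unique protospacer + NGG PAM and
#' an engineered repeat such that the designed deletion of `del_len` bases
#' immediately 3' of the cut has junction microhomology exactly `mh_len`
#' (verified against [mh_length()] during construction). A second
#' engineered deletion (4 bp ending at the cut, microhomology 0) provides
#' a deterministic template for the residual `OTHER` class. Optionally
#' attaches a donor:
#'
#' * `"ssodn_hdr"` — 20-bp arms flanking the cut, a random payload, and a
#'   PAM-disrupting intended substitution.
#' * `"dsdna_blunt"` — random blunt payload.
#' * `"dsdna_overhang"` — random duplex core plus the overhang base
#'   complementary to the staggered cut (forces
#'   `cut_mode = "staggered_1nt"`).
#'
#' @param seed Integer seed; identical arguments give a byte-identical
#'   fixture.
#' @param mh_len Engineered junction microhomology (>= 0).
#' @param del_len Engineered deletion length (>= 1).
#' @param amplicon_length Amplicon length (>= 150).
#' @param donor Donor kind or `"none"`.
#' @param insert_length Donor payload length (default 34).
#' @param cut_mode Cut geometry; defaults to blunt except for overhang
#'   donors.
#' @param quant_window Quantification window half-width.
#' @param max_tries Bounded construction retries before failing.
#' @return An [experiment_design()] with an `engineered` field describing
#'   the designed MH deletion and the OTHER-template deletion.
#' @export
make_fixture <- function(seed, mh_len = 3L, del_len = 3L,
                         amplicon_length = 200L,
                         donor = c("none", "ssodn_hdr", "dsdna_blunt",
                                   "dsdna_overhang"),
                         insert_length = 34L,
                         cut_mode = NULL,
                         quant_window = 8L,
                         max_tries = 100L) {
  donor <- match.arg(donor)
  stopifnot(mh_len >= 0L, del_len >= 1L, amplicon_length >= 150L)
  if (is.null(cut_mode)) {
    cut_mode <- if (donor == "dsdna_overhang") "staggered_1nt" else "blunt"
  }
  withr::with_seed(as.integer(seed), {
    for (try in seq_len(max_tries)) {
      fixture <- try_build_fixture(mh_len, del_len, amplicon_length,
                                   donor, insert_length, cut_mode,
                                   quant_window)
      if (!is.null(fixture)) return(fixture)
    }
    abort(sprintf("fixture construction failed after %d attempts", max_tries),
          class = "ampliclass_construction_failure")
  })
}

# one randomized construction attempt; NULL on constraint violation
try_build_fixture <- function(mh_len, del_len, amplicon_length, donor,
                              insert_length, cut_mode, quant_window) {
  L <- amplicon_length
  p <- 80L                      # protospacer start; cut lands near mid-amplicon
  b <- p + 16L                  # blunt cut inter-base position
  chars <- sample(DNA_BASES, L, replace = TRUE)
  chars[c(p + 21L, p + 22L)] <- "G"   # NGG PAM

  # engineered MH deletion: bases s..s+del-1 directly 3' of the cut, with
  # k_right == mh_len enforced by copying and k_left == 0 by breaking
  s <- b + 1L
  e <- s + del_len
  if (e + mh_len + 1L > L) return(NULL)
  if (mh_len > 0L) {
    for (i in seq_len(mh_len) - 1L) chars[e + i] <- chars[s + i]
  }
  chars[c(p + 21L, p + 22L)] <- "G"   # re-force PAM after copying
  # break the continuation one base past the engineered homology
  brk <- function(pos, must_differ_from) {
    sample(setdiff(DNA_BASES, must_differ_from), 1L)
  }
  stop_pos <- e + mh_len
  if (!(stop_pos %in% c(p + 21L, p + 22L))) {
    chars[stop_pos] <- brk(stop_pos, chars[s + mh_len])
  } else if (chars[s + mh_len] == "G") {
    chars[s + mh_len] <- brk(s + mh_len, "G")
  }
  chars[s - 1L] <- brk(s - 1L, chars[e - 1L])  # k_left = 0

  # OTHER template: 4-bp deletion ending at the cut with microhomology 0
  os <- b - 3L
  oe <- b + 1L                  # first base after the OTHER deletion
  chars[os - 1L] <- brk(os - 1L, chars[oe - 1L])
  # k_right break: chars[os] != chars[oe]; chars[oe] == chars[s] was just set
  if (chars[os] == chars[oe]) {
    chars[os] <- brk(os, chars[oe])
  }

  ref <- paste(chars, collapse = "")

  # verify the engineered constraints with the production primitive
  if (mh_length(ref, s, del_len) != mh_len) return(NULL)
  if (mh_length(ref, os, 4L) != 0L) return(NULL)

  protospacer <- seq_slice(ref, p, p + 19L)
  pam <- seq_slice(ref, p + 20L, p + 22L)
  guide <- guide_spec("gFix", protospacer, pam)
  # uniqueness of the 23-mer placement
  fwd23 <- paste0(protospacer, pam)
  if (count_matches(fwd23, ref) + count_matches(revcomp(fwd23), ref) != 1L) {
    return(NULL)
  }

  donor_obj <- NULL
  if (donor == "ssodn_hdr") {
    insert <- random_dna(insert_length)
    left_arm <- seq_slice(ref, b - 19L, b)
    right_arm <- seq_slice(ref, b + 1L, b + 20L)
    pam_pos <- p + 22L
    donor_obj <- donor_spec("ssodn_hdr", insert, left_arm, right_arm,
                            intended_substitutions = tibble(
                              pos = pam_pos,
                              base = brk(pam_pos, chars[pam_pos])))
  } else if (donor == "dsdna_blunt") {
    donor_obj <- donor_spec("dsdna_blunt", random_dna(insert_length))
  } else if (donor == "dsdna_overhang") {
    cut <- predict_cut(ref, "+", p, "staggered_1nt")
    donor_obj <- donor_spec("dsdna_overhang", random_dna(insert_length - 1L),
                            overhang = cut$overhang_base)
  }

  design <- experiment_design(ref, guide, donor = donor_obj,
                              cut_mode = cut_mode,
                              quant_window = quant_window,
                              amplicon_name = "synthetic_amplicon")
  design$engineered <- list(
    mh_del = list(start = s, length = del_len, mh_len = mh_len),
    other_del = list(start = os, length = 4L)
  )
  design
}

#' Simulate amplicon reads from a mixture of repair outcomes
#'
#' Emits merged single-end reads drawn i.i.d. from the mixture, built from
#' deterministic per-category templates: the reference (`unmodified`), a
#' 1-bp duplication at the cut (`nhej_plus1`), a 1-bp deletion at the cut
#' (`nhej_minus1`), the fixture's engineered microhomology deletion
#' (`mh_del`), the knock-in alleles from [build_allele_model()]
#' (`hdr_ki`, `nhej_ki_fwd`, `nhej_ki_rev`) and the engineered
#' no-microhomology 4-bp deletion (`other`). Uniform substitution errors
#' are applied at `error_rate`; all randomness derives from `mix$seed`.
#'
#' @param design A fixture from [make_fixture()] (or any
#'   [experiment_design()]; `mh_del`/`other` templates require the
#'   fixture's `engineered` field).
#' @param mix A [mixture_spec()].
#' @return A list with `reads` (tibble: `read_id`, `sequence`, `quality`,
#'   `count`) and `truth` (tibble: `read_id`, `true_category`,
#'   `true_orientation`, `true_variant_key`).
#' @export
simulate_reads <- function(design, mix) {
  stopifnot(inherits(design, "experiment_design"), inherits(mix, "mixture_spec"))
  p <- mix$proportions
  ki_mass <- sum(p[c("nhej_ki_fwd", "nhej_ki_rev", "hdr_ki")])
  if (ki_mass > 0 && is.null(design$donor)) {
    abort("mixture assigns mass to knock-in classes but the design has no donor",
          class = "ampliclass_inconsistent_spec")
  }
  templates <- build_templates(design, names(p)[p > 0])

  withr::with_seed(mix$seed, {
    cats <- sample(names(p), mix$n_reads, replace = TRUE, prob = p)
    seqs <- vapply(templates, function(t) t$sequence, character(1))[cats]
    seqs <- add_substitution_errors(seqs, mix$error_rate)
    ids <- sprintf("read_%06d", seq_len(mix$n_reads))
    seqs <- unname(seqs)
    reads <- tibble(read_id = ids, sequence = seqs,
                    quality = strrep("I", nchar(seqs)), count = 1L)
    pick <- function(field) {
      unname(vapply(templates, function(t) t[[field]], character(1))[cats])
    }
    truth <- tibble(
      read_id = ids,
      true_category = pick("category"),
      true_orientation = pick("orientation"),
      true_variant_key = pick("variant_key")
    )
    list(reads = reads, truth = truth)
  })
}

# deterministic per-category templates with their truth annotations
build_templates <- function(design, needed) {
  ref <- design$reference
  b <- design$cut$site
  L <- nchar(ref)
  eng <- design$engineered
  alleles <- if (!is.null(design$donor)) build_allele_model(design) else NULL

  tpl <- list()
  make <- function(events, category, orientation = NA_character_) {
    seqn <- apply_variants(ref, events)
    key <- canonical_key(events, ref, design)
    list(sequence = seqn, category = category,
         orientation = orientation, variant_key = key)
  }
  ev <- function(etype, ref_start, length, seq = "") {
    tibble(etype = etype, ref_start = as.integer(ref_start),
           length = as.integer(length), seq = seq)
  }

  for (cat in needed) {
    tpl[[cat]] <- switch(
      cat,
      unmodified = make(ev(character(0), integer(0), integer(0), character(0)),
                        "UNMODIFIED"),
      nhej_plus1 = make(ev("insertion", b, 1L, substr(ref, b, b)), "NHEJ"),
      nhej_minus1 = make(ev("deletion", b, 1L), "NHEJ"),
      mh_del = {
        if (is.null(eng)) {
          abort("mh_del reads need a make_fixture() design",
                class = "ampliclass_inconsistent_spec")
        }
        make(ev("deletion", eng$mh_del$start, eng$mh_del$length), "MH_DEL")
      },
      other = {
        if (is.null(eng)) {
          abort("other reads need a make_fixture() design",
                class = "ampliclass_inconsistent_spec")
        }
        make(ev("deletion", eng$other_del$start, eng$other_del$length), "OTHER")
      },
      hdr_ki = {
        if (is.null(alleles$hdr_allele)) {
          abort("hdr_ki reads need an ssODN donor",
                class = "ampliclass_inconsistent_spec")
        }
        list(sequence = alleles$hdr_allele, category = "HDR_KI",
             orientation = NA_character_,
             variant_key = allele_key(alleles$hdr_allele, design))
      },
      nhej_ki_fwd = {
        seqn <- nhej_capture_allele(alleles, design, "forward")
        list(sequence = seqn, category = "NHEJ_KI", orientation = "forward",
             variant_key = allele_key(seqn, design))
      },
      nhej_ki_rev = {
        seqn <- nhej_capture_allele(alleles, design, "reverse")
        list(sequence = seqn, category = "NHEJ_KI", orientation = "reverse",
             variant_key = allele_key(seqn, design))
      },
      abort(sprintf("unknown mixture class '%s'", cat)))
  }
  tpl
}

# NHEJ end-capture sequence for a donor: the modelled knock-in allele for
# dsDNA donors; for ssODN donors, blunt capture of the payload at the cut
# (templated arms are not used by end joining)
nhej_capture_allele <- function(alleles, design, orientation) {
  if (is.null(alleles)) {
    abort("nhej_ki reads need a donor", class = "ampliclass_inconsistent_spec")
  }
  slot <- if (orientation == "forward") "nhej_ki_fwd" else "nhej_ki_rev"
  if (!is.null(alleles[[slot]])) return(alleles[[slot]])
  ref <- design$reference
  b <- design$cut$site
  payload <- if (orientation == "forward") alleles$payload else revcomp(alleles$payload)
  paste0(seq_slice(ref, 1L, b), payload, seq_slice(ref, b + 1L, nchar(ref)))
}

# canonical in-window key of a hand-built event list (left-normalized the
# same way the classifier normalizes)
canonical_key <- function(events, ref, design) {
  if (nrow(events) == 0L) return("WT")
  ref_chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  norm <- bind_rows(lapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    if (e$etype == "deletion") {
      normalize_deletion(ref_chars, e$ref_start, e$length)
    } else {
      normalize_insertion(ref_chars, e$ref_start, e$seq)
    }
  }))
  norm <- flag_in_window(norm, design)
  variant_key_of(norm[norm$in_window, , drop = FALSE])
}

# canonical key of a full allele sequence: align it to the reference once
allele_key <- function(allele, design) {
  aln <- align_to_allele(allele, design$reference)
  evs <- extract_variants(aln$aligned_query, aln$aligned_ref, design$reference)
  evs <- flag_in_window(evs, design)
  variant_key_of(evs[evs$in_window & evs$etype != "substitution", , drop = FALSE])
}

# uniform substitution errors; the substituted base always differs
add_substitution_errors <- function(seqs, error_rate) {
  if (error_rate == 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(chars), n_err[i])
    chars[pos] <- vapply(chars[pos], function(base) {
      sample(setdiff(DNA_BASES, base), 1L)
    }, character(1), USE.NAMES = FALSE)
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Simulate aligned long reads with a large deletion subpopulation
#'
#' Emits full-span aligned reads over the amplicon, a fraction of which
#' carry one fixed deletion segment. Feed to
#' [coverage_from_alignments()] to exercise the deletion-proportion
#' statistic against the analytic expectation.
#'
#' @param amplicon_length Amplicon length (bp).
#' @param large_del_fraction Fraction of reads carrying the deletion.
#' @param del_interval Length-2 integer vector, 1-based inclusive deletion
#'   segment.
#' @param n_reads Number of reads.
#' @param seed Integer seed.
#' @return Tibble with `read_id`, `span_start`, `span_end`, `del_start`,
#'   `del_end` (`NA` for reads without the deletion) and `has_deletion`.
#' @export
simulate_long_reads <- function(amplicon_length, large_del_fraction,
                                del_interval, n_reads, seed = 1L) {
  L <- as.integer(amplicon_length)
  stopifnot(large_del_fraction >= 0, large_del_fraction <= 1,
            length(del_interval) == 2L,
            del_interval[1] >= 1L, del_interval[2] <= L,
            del_interval[1] <= del_interval[2], n_reads >= 1L)
  withr::with_seed(as.integer(seed), {
    has_del <- stats::runif(n_reads) < large_del_fraction
    tibble(
      read_id = sprintf("lr_%06d", seq_len(n_reads)),
      span_start = 1L, span_end = L,
      del_start = ifelse(has_del, as.integer(del_interval[1]), NA_integer_),
      del_end = ifelse(has_del, as.integer(del_interval[2]), NA_integer_),
      has_deletion = has_del
    )
  })
}
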