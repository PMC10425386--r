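# Expected knock-in allele construction.

make_design <- function(seed = 1, donor = NULL, cut_mode = "blunt") {
  set.seed(seed)
  proto <- rand_seq(20)
  guide <- guide_spec("g", proto, "TGG")
  ref <- paste0(rand_seq(60), proto, "TGG", rand_seq(60))
  experiment_design(ref, guide, donor = donor, cut_mode = cut_mode)
}

test_that("ssODN arms splice the insert seamlessly at the cut", {
  d0 <- make_design(11)
  ref <- d0$reference
  b <- d0$cut$site
  insert <- rand_seq(34)
  donor <- donor_spec("ssodn_hdr", insert,
                      left_arm = substr(ref, b - 19, b),
                      right_arm = substr(ref, b + 1, b + 20))
  d <- make_design(11, donor = donor)
  am <- build_allele_model(d)
  expect_equal(am$hdr_allele,
               paste0(substr(ref, 1, b), insert,
                      substr(ref, b + 1, nchar(ref))))
  expect_equal(am$insert_coords, c(b + 1L, b + 34L))
  # outside the insert, the HDR allele equals the reference exactly
  expect_equal(substr(am$hdr_allele, 1, b), substr(ref, 1, b))
  expect_equal(substring(am$hdr_allele, b + 35L), substring(ref, b + 1L))
})

test_that("intended substitutions are the only differences outside the insert", {
  d0 <- make_design(12)
  ref <- d0$reference
  b <- d0$cut$site
  subs <- data.frame(pos = c(b + 5L, b - 3L), base = c("A", "T"))
  # force the substitutions to actually change the base
  subs$base <- vapply(seq_len(nrow(subs)), function(i) {
    setdiff(c("A", "C", "G", "T"), substr(ref, subs$pos[i], subs$pos[i]))[1]
  }, character(1))
  donor <- donor_spec("ssodn_hdr", rand_seq(34),
                      left_arm = substr(ref, b - 19, b),
                      right_arm = substr(ref, b + 1, b + 20),
                      intended_substitutions = subs)
  d <- make_design(12, donor = donor)
  am <- build_allele_model(d)
  # strip the insert back out and diff against the reference
  no_insert <- paste0(substr(am$hdr_allele, 1, b),
                      substring(am$hdr_allele, b + 35L))
  diffs <- which(strsplit(no_insert, "")[[1]] != strsplit(ref, "")[[1]])
  expect_setequal(diffs, subs$pos)
})

test_that("arm mismatch within the search radius is an error", {
  d0 <- make_design(13)
  donor <- donor_spec("ssodn_hdr", rand_seq(34),
                      left_arm = rand_seq(20), right_arm = rand_seq(20))
  d <- make_design(13, donor = donor)
  expect_error(build_allele_model(d), class = "ampliclass_arm_mismatch")
})

test_that("blunt dsDNA alleles are payload splices; reverse is the reverse complement", {
  insert <- rand_seq(34)
  donor <- donor_spec("dsdna_blunt", insert)
  d <- make_design(14, donor = donor)
  ref <- d$reference
  b <- d$cut$site
  am <- build_allele_model(d)
  expect_equal(am$nhej_ki_fwd,
               paste0(substr(ref, 1, b), insert, substring(ref, b + 1)))
  expect_equal(am$nhej_ki_rev,
               paste0(substr(ref, 1, b), revcomp(insert), substring(ref, b + 1)))
  # inserted segment of rev is the rc of fwd's
  expect_equal(substr(am$nhej_ki_rev, b + 1, b + 34),
               revcomp(substr(am$nhej_ki_fwd, b + 1, b + 34)))
  expect_null(am$hdr_allele)
})

test_that("overhang dsDNA ligates seamlessly only in the compatible orientation", {
  core <- rand_seq(33)
  d0 <- make_design(15, cut_mode = "staggered_1nt")
  ref <- d0$reference
  ov <- d0$cut$overhang_base
  donor <- donor_spec("dsdna_overhang", core, overhang = ov)
  d <- make_design(15, donor = donor, cut_mode = "staggered_1nt")
  am <- build_allele_model(d)
  cuts <- sort(c(d$cut$top_cut, d$cut$bottom_cut))
  c_lo <- cuts[1]
  c_hi <- cuts[2]
  L <- nchar(ref)

  # enumerate the ligation products of the 1-nt 5'-overhang ends by string
  # reconstruction: sticky annealing requires the donor overhang to equal
  # the genomic overhang base
  seamless <- paste0(substr(ref, 1, c_lo), ov, core, substring(ref, c_hi))
  expect_equal(am$nhej_ki_fwd, seamless)
  # the seamless product is a clean n-length insertion: removing it
  # restores the reference
  expect_equal(nchar(am$nhej_ki_fwd) - L, nchar(core) + 1L)

  # incompatible orientation: filled-in ends leave junction anomalies
  comp_ov <- chartr("ACGT", "TGCA", ov)
  flipped_top <- paste0(comp_ov, revcomp(core))
  filled <- paste0(flipped_top, comp_ov)
  expect_equal(am$nhej_ki_rev,
               paste0(substr(ref, 1, c_hi), filled, substring(ref, c_hi)))
  expect_equal(nchar(am$nhej_ki_rev) - L, nchar(core) + 3L)

  # donors whose overhang cannot pair the cut never ligate seamlessly
  bad_ov <- setdiff(c("A", "C", "G", "T"), c(ov, chartr("ACGT", "TGCA", ov)))[1]
  donor_bad <- donor_spec("dsdna_overhang", core, overhang = bad_ov)
  d_bad <- make_design(15, donor = donor_bad, cut_mode = "staggered_1nt")
  am_bad <- build_allele_model(d_bad)
  expect_equal(nchar(am_bad$nhej_ki_fwd) - L, nchar(core) + 3L)
  expect_equal(nchar(am_bad$nhej_ki_rev) - L, nchar(core) + 3L)
})

test_that("overhang donors demand a staggered cut and dsDNA donors reject arms", {
  core <- rand_seq(33)
  donor <- donor_spec("dsdna_overhang", core, overhang = "A")
  d <- make_design(16, donor = donor, cut_mode = "blunt")
  expect_error(build_allele_model(d), class = "ampliclass_bad_donor")
  expect_error(donor_spec("dsdna_blunt", core, left_arm = "ACGT"),
               class = "ampliclass_bad_donor")
})
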