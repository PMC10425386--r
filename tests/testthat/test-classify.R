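# Microhomology annotation, donor detection, and the decision cascade.

test_that("mh_length matches hand-worked repeat examples", {
  # ACG|ACG repeat: deleting bases 3..5 of TTACGACGTT leaves TTACGTT,
  # reachable from 4 placements
  expect_equal(mh_length("TTACGACGTT", 3, 3), 3L)
  # AA within AAAA
  expect_equal(mh_length("GGAAAAGG", 3, 2), 2L)
  # no flanking repeat
  expect_equal(mh_length("AACGTTGCAA", 3, 3), 0L)
  # periodic context shorter than the deletion still counts all placements
  expect_equal(mh_length("ACACAC", 2, 2), 4L)
  expect_equal(mh_length("AAAAAA", 1, 2), 4L)
})

test_that("mh_length equals the placement-count oracle on random references", {
  set.seed(31)
  for (i in 1:60) {
    ref <- rand_seq(120)
    for (len in 2:8) {
      starts <- sample(seq_len(nchar(ref) - len + 1L), 5)
      for (s in starts) {
        expect_equal(mh_length(ref, s, len), oracle_mh(ref, s, len),
                     info = sprintf("ref %d start %d len %d", i, s, len))
      }
    }
  }
})

test_that("donor insertions are detected with orientation and identity", {
  set.seed(32)
  payload <- rand_seq(34)
  cfg <- classifier_config()
  hit <- detect_donor_insertion(payload, payload, cfg)
  expect_equal(hit$orientation, "forward")
  expect_equal(hit$identity, 1.0)

  hit <- detect_donor_insertion(revcomp(payload), payload, cfg)
  expect_equal(hit$orientation, "reverse")
  expect_equal(hit$identity, 1.0)

  # two substitutions: identity 32/34
  mutated <- payload
  substr(mutated, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(payload, 5, 5))[1]
  substr(mutated, 20, 20) <- setdiff(c("A", "C", "G", "T"), substr(payload, 20, 20))[1]
  hit <- detect_donor_insertion(mutated, payload, cfg)
  expect_equal(hit$orientation, "forward")
  expect_equal(hit$identity, 32 / 34)

  # unrelated sequence falls below the identity floor
  expect_null(detect_donor_insertion(rand_seq(34), payload, cfg))
  # palindromic tie is ambiguous
  pal <- "ACGT"
  expect_null(detect_donor_insertion(pal, pal, cfg))
})

test_that("the cascade assigns the canonical example reads", {
  d <- make_fixture(seed = 41, mh_len = 3, del_len = 3, donor = "ssodn_hdr")
  ref <- d$reference
  b <- d$cut$site
  am <- build_allele_model(d)
  eng <- d$engineered

  reads <- tibble::tibble(
    read_id = c("wt", "dup1", "hdr", "mhdel", "nomh", "bigins"),
    sequence = c(
      ref,
      paste0(substr(ref, 1, b), substr(ref, b, b), substring(ref, b + 1)),
      am$hdr_allele,
      paste0(substr(ref, 1, eng$mh_del$start - 1),
             substring(ref, eng$mh_del$start + eng$mh_del$length)),
      paste0(substr(ref, 1, eng$other_del$start - 1),
             substring(ref, eng$other_del$start + eng$other_del$length)),
      paste0(substr(ref, 1, b), rand_seq(25), substring(ref, b + 1))),
    count = 1L)
  cl <- classify_reads(reads, d, alleles = am)
  got <- setNames(as.character(cl$category), cl$read_id)
  expect_equal(got[["wt"]], "UNMODIFIED")
  expect_equal(got[["dup1"]], "NHEJ")
  expect_equal(got[["hdr"]], "HDR_KI")
  expect_equal(got[["mhdel"]], "MH_DEL")
  expect_equal(got[["nomh"]], "OTHER")       # >=2 bp deletion without MH
  expect_equal(got[["bigins"]], "OTHER")     # long insertion not matching donor
  expect_true(all(is.na(cl$orientation)))
})

test_that("dsDNA payload reads are NHEJ_KI with the correct orientation", {
  d <- make_fixture(seed = 42, donor = "dsdna_blunt")
  am <- build_allele_model(d)
  reads <- tibble::tibble(
    read_id = c("fwd", "rev"),
    sequence = c(am$nhej_ki_fwd, am$nhej_ki_rev),
    count = 1L)
  cl <- classify_reads(reads, d, alleles = am)
  expect_equal(as.character(cl$category), c("NHEJ_KI", "NHEJ_KI"))
  expect_equal(cl$orientation, c("forward", "reverse"))
})

test_that("a 1-bp deletion is always NHEJ, never MH_DEL", {
  # even in a homopolymer where the junction shows microhomology
  set.seed(43)
  proto <- rand_seq(20)
  guide <- guide_spec("g", proto, "TGG")
  ref <- paste0(rand_seq(36), "AAAA", proto, "TGG", rand_seq(40))
  d <- experiment_design(ref, guide)
  b <- d$cut$site
  read <- paste0(substr(ref, 1, b - 1), substring(ref, b + 1))
  cl <- classify_reads(tibble::tibble(read_id = "r", sequence = read, count = 1L), d)
  expect_equal(as.character(cl$category), "NHEJ")
})

test_that("raising mh_min only moves reads from MH_DEL to OTHER", {
  d <- make_fixture(seed = 44, mh_len = 3, del_len = 4)
  mix <- mixture_spec(unmodified = .3, nhej_plus1 = .2, mh_del = .3,
                      other = .2, n_reads = 300, error_rate = 0, seed = 4)
  sim <- simulate_reads(d, mix)
  cl_lo <- classify_reads(sim$reads, d, cfg = classifier_config(mh_min = 2))
  cl_hi <- classify_reads(sim$reads, d, cfg = classifier_config(mh_min = 4))
  tab <- table(lo = as.character(cl_lo$category), hi = as.character(cl_hi$category))
  moved <- as.character(cl_lo$category) != as.character(cl_hi$category)
  expect_true(all(as.character(cl_lo$category)[moved] == "MH_DEL"))
  expect_true(all(as.character(cl_hi$category)[moved] == "OTHER"))
})

test_that("low-quality reads are discarded, not classified", {
  d <- make_fixture(seed = 45)
  ref <- d$reference
  reads <- tibble::tibble(
    read_id = c("good", "bad"),
    sequence = c(ref, ref),
    quality = c(strrep("I", nchar(ref)), strrep("#", nchar(ref))),  # Q40 vs Q2
    count = 1L)
  cl <- classify_reads(reads, d)
  expect_equal(as.character(cl$category), c("UNMODIFIED", "DISCARDED"))
  expect_true(is.na(cl$variant_key[2]))
})

test_that("unmappable sequences are discarded by the score floor", {
  d <- make_fixture(seed = 46)
  reads <- tibble::tibble(read_id = c("r1", "junk"),
                          sequence = c(d$reference, rand_seq(nchar(d$reference))),
                          count = 1L)
  cl <- classify_reads(reads, d)
  expect_equal(as.character(cl$category), c("UNMODIFIED", "DISCARDED"))
})
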