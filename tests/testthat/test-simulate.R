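# Fixture construction and the mixture read simulator.

test_that("fixtures carry verified engineered microhomology", {
  for (params in list(c(0, 3), c(1, 2), c(2, 2), c(3, 3), c(4, 5), c(3, 8))) {
    mh <- params[1]
    del <- params[2]
    d <- make_fixture(seed = 100 + mh * 10 + del, mh_len = mh, del_len = del)
    eng <- d$engineered$mh_del
    expect_equal(mh_length(d$reference, eng$start, eng$length), mh)
    expect_equal(oracle_mh(d$reference, eng$start, eng$length), mh)
    # the OTHER template deletion has no junction homology
    expect_equal(mh_length(d$reference, d$engineered$other_del$start,
                           d$engineered$other_del$length), 0L)
  }
})

test_that("fixture construction is deterministic and seed-sensitive", {
  d1 <- make_fixture(seed = 5, mh_len = 3, del_len = 3, donor = "ssodn_hdr")
  d2 <- make_fixture(seed = 5, mh_len = 3, del_len = 3, donor = "ssodn_hdr")
  d3 <- make_fixture(seed = 6, mh_len = 3, del_len = 3, donor = "ssodn_hdr")
  expect_identical(d1$reference, d2$reference)
  expect_identical(d1$donor$insert, d2$donor$insert)
  expect_false(identical(d1$reference, d3$reference))
})

test_that("simulated reads are deterministic given the seed", {
  d <- make_fixture(seed = 8, donor = "dsdna_blunt")
  mix <- mixture_spec(unmodified = .5, nhej_ki_fwd = .25, nhej_ki_rev = .25,
                      n_reads = 200, error_rate = 0.01, seed = 3)
  s1 <- simulate_reads(d, mix)
  s2 <- simulate_reads(d, mix)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  mix2 <- mixture_spec(unmodified = .5, nhej_ki_fwd = .25, nhej_ki_rev = .25,
                       n_reads = 200, error_rate = 0.01, seed = 4)
  expect_false(identical(simulate_reads(d, mix2)$reads$sequence,
                         s1$reads$sequence))
})

test_that("mixture validation rejects bad specs", {
  expect_error(mixture_spec(unmodified = 0.5, nhej_plus1 = 0.4),
               class = "ampliclass_bad_mixture")
  expect_error(mixture_spec(unmodified = 1, error_rate = 0.2),
               class = "ampliclass_bad_mixture")
  d <- make_fixture(seed = 9)  # no donor
  mix <- mixture_spec(unmodified = .5, hdr_ki = .5, n_reads = 10)
  expect_error(simulate_reads(d, mix), class = "ampliclass_inconsistent_spec")
})

test_that("at zero noise the classifier recovers every truth label", {
  d <- make_fixture(seed = 10, mh_len = 3, del_len = 3, donor = "ssodn_hdr")
  mix <- mixture_spec(unmodified = .2, nhej_plus1 = .15, nhej_minus1 = .15,
                      mh_del = .15, hdr_ki = .15, nhej_ki_fwd = .05,
                      nhej_ki_rev = .05, other = .1,
                      n_reads = 800, error_rate = 0, seed = 2)
  sim <- simulate_reads(d, mix)
  cl <- classify_reads(sim$reads, d)
  expect_equal(as.character(cl$category), sim$truth$true_category)
  ki <- sim$truth$true_category == "NHEJ_KI"
  expect_equal(cl$orientation[ki], sim$truth$true_orientation[ki])
  # truth variant keys match the classifier's canonical keys
  expect_equal(cl$variant_key, sim$truth$true_variant_key)
})

test_that("an all-unmodified mixture yields zero mutated reads", {
  d <- make_fixture(seed = 11)
  sim <- simulate_reads(d, mixture_spec(unmodified = 1, n_reads = 50, seed = 1))
  tab <- tally_outcomes(classify_reads(sim$reads, d))
  expect_equal(tab$mutated_reads, 0L)
})

test_that("empirical category fractions concentrate around the mixture", {
  d <- make_fixture(seed = 12, donor = "ssodn_hdr")
  mix <- mixture_spec(unmodified = .4, hdr_ki = .3, nhej_plus1 = .3,
                      n_reads = 4000, error_rate = 0.001, seed = 13)
  sim <- simulate_reads(d, mix)
  cl <- classify_reads(sim$reads, d)
  fr <- tidy(tally_outcomes(cl))
  est <- setNames(fr$frac_mapped, as.character(fr$category))
  # 3-sigma binomial bounds at n = 4000
  expect_lt(abs(est[["HDR_KI"]] - 0.3), 3 * sqrt(0.3 * 0.7 / 4000) + 0.005)
  expect_lt(abs(est[["NHEJ"]] - 0.3), 3 * sqrt(0.3 * 0.7 / 4000) + 0.005)
  expect_lt(abs(est[["UNMODIFIED"]] - 0.4), 3 * sqrt(0.4 * 0.6 / 4000) + 0.005)
})

test_that("simulated long reads honour the deletion fraction exactly at the extremes", {
  lr0 <- simulate_long_reads(400, 0, c(101, 300), n_reads = 100, seed = 1)
  expect_equal(deletion_proportion(coverage_from_alignments(lr0, 400)), 0)
  # fraction 0.5 with a deletion covering half the amplicon: Cm/Ct = 0.75
  lr <- simulate_long_reads(400, 0.5, c(101, 300), n_reads = 2000, seed = 2)
  prof <- coverage_from_alignments(lr, 400)
  f_hat <- mean(lr$has_deletion)
  expect_equal(prof$mean_depth / prof$unique_reads, 1 - f_hat / 2,
               tolerance = 1e-12)
})
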