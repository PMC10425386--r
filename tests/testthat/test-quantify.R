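# Outcome tabulation, ratios and the top-variant profile.

fake_classifications <- function(categories, counts = NULL, keys = NULL) {
  n <- length(categories)
  tibble::tibble(
    read_id = sprintf("r%03d", seq_len(n)),
    count = counts %||% rep(1L, n),
    category = factor(categories,
                      levels = c("UNMODIFIED", "NHEJ", "MH_DEL", "NHEJ_KI",
                                 "HDR_KI", "OTHER", "DISCARDED")),
    orientation = NA_character_,
    variant_key = keys %||% ifelse(categories == "UNMODIFIED", "WT",
                                   sprintf("D10:%d", seq_len(n))))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("fractions of mapped and mutated reads follow the worked example", {
  cl <- fake_classifications(c(rep("UNMODIFIED", 4), rep("HDR_KI", 3),
                               rep("NHEJ", 2), "MH_DEL"))
  tab <- tally_outcomes(cl)
  expect_equal(tab$mapped_reads, 10L)
  expect_equal(tab$mutated_reads, 6L)
  td <- tidy(tab)
  fr <- setNames(td$frac_mapped, as.character(td$category))
  expect_equal(fr[["UNMODIFIED"]], 0.4)
  expect_equal(fr[["HDR_KI"]], 0.3)
  expect_equal(fr[["NHEJ"]], 0.2)
  expect_equal(fr[["MH_DEL"]], 0.1)
  rel <- setNames(td$frac_mutated, as.character(td$category))
  expect_equal(rel[["HDR_KI"]], 0.5)
  expect_true(is.na(rel[["UNMODIFIED"]]))
  expect_equal(sum(td$frac_mapped), 1, tolerance = 1e-15)
})

test_that("degenerate inputs are handled: all unmodified, or nothing mapped", {
  cl <- fake_classifications(rep("UNMODIFIED", 5))
  tab <- tally_outcomes(cl)
  expect_equal(tab$mutated_reads, 0L)
  expect_true(tab$no_mutated_reads)
  expect_equal(tidy(tab)$frac_mutated[tidy(tab)$category == "NHEJ"], 0)

  cl <- fake_classifications(rep("DISCARDED", 3))
  expect_error(tally_outcomes(cl), class = "ampliclass_empty_input")
})

test_that("the HDR to indel ratio divides HDR by mutagenic indels", {
  # HDR 10%, indels 1% -> 10; mirrors the x:1 reporting convention
  cl <- fake_classifications(c(rep("HDR_KI", 10), "NHEJ", rep("UNMODIFIED", 89)))
  expect_equal(hdr_indel_ratio(tally_outcomes(cl)), 10)

  cl <- fake_classifications(c(rep("NHEJ", 5), rep("UNMODIFIED", 5)))
  expect_equal(hdr_indel_ratio(tally_outcomes(cl)), 0)

  # no indels at all: infinity flag
  cl <- fake_classifications(c(rep("HDR_KI", 5), rep("UNMODIFIED", 5)))
  expect_equal(hdr_indel_ratio(tally_outcomes(cl)), Inf)

  # NHEJ_KI excluded from the default denominator, included on request
  cl <- fake_classifications(c(rep("HDR_KI", 4), rep("NHEJ_KI", 2), rep("NHEJ", 2),
                               rep("UNMODIFIED", 2)))
  expect_equal(hdr_indel_ratio(tally_outcomes(cl)), 2)
  tab2 <- tally_outcomes(cl, classifier_config(ratio_denominator = "non_hdr_mutated"))
  expect_equal(hdr_indel_ratio(tab2), 1)
})

test_that("tabulation is invariant to order and to splitting the stream", {
  set.seed(51)
  cats <- sample(c("UNMODIFIED", "NHEJ", "MH_DEL", "HDR_KI", "OTHER", "DISCARDED"),
                 200, replace = TRUE)
  cl <- fake_classifications(cats, counts = sample(1:5, 200, replace = TRUE))
  tab_full <- tally_outcomes(cl)
  tab_perm <- tally_outcomes(cl[sample(nrow(cl)), ])
  expect_equal(tidy(tab_full), tidy(tab_perm))
  # merging partial tallies equals tallying the concatenation
  half <- nrow(cl) %/% 2
  merged <- tally_outcomes(dplyr::bind_rows(cl[seq_len(half), ],
                                            cl[(half + 1):nrow(cl), ]))
  expect_equal(tidy(tab_full), tidy(merged))
  expect_equal(glance(tab_full)$mapped_reads + tab_full$discarded_reads,
               sum(cl$count))
})

test_that("top_variants ranks by absolute frequency with stable rendering", {
  d <- make_fixture(seed = 52, mh_len = 3, del_len = 3)
  b <- d$cut$site
  keys <- c(rep("WT", 0), rep(sprintf("D%d:3", b + 1), 60),
            rep(sprintf("I%d:A", b), 40))
  cl <- fake_classifications(c(rep("MH_DEL", 60), rep("NHEJ", 40)), keys = keys)
  tv <- top_variants(cl, d, n = 10, flank = 30)
  expect_equal(tv$abs_freq, c(0.6, 0.4))
  expect_equal(tv$rank, c(1L, 2L))
  # n larger than distinct variants returns all of them
  expect_equal(nrow(top_variants(cl, d, n = 50)), 2L)
  # deletion rendered as gaps, insertion as lower case
  expect_true(grepl("---", tv$window_sequence[1]))
  expect_true(grepl("[a-z]", tv$window_sequence[2]))
  expect_equal(nchar(tv$window_sequence[1]), 60L)
})

test_that("window rendering reproduces the variant sequence context", {
  d <- make_fixture(seed = 53)
  ref <- d$reference
  b <- d$cut$site
  tvw <- ampliclass:::render_variant_window("WT", d, flank = 30)
  expect_equal(tvw, substr(ref, b - 29, b + 30))
})
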