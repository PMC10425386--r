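#' Tabulate classified reads into an outcome table
#'
#' Aggregates per-read classifications into category counts and the two
#' reporting conventions used for editing outcomes: fraction of mapped
#' reads (all non-discarded reads; includes `UNMODIFIED`, sums to 1) and
#' fraction of mutated reads (mapped minus `UNMODIFIED`; defined for the
#' edited categories).
#'
#' @param classifications Tibble from [classify_reads()].
#' @param cfg A [classifier_config()] (controls the HDR:indel ratio
#'   denominator).
#' @return An object of class `outcome_table`.
#' @export
tally_outcomes <- function(classifications, cfg = classifier_config()) {
  cl <- as_tibble(classifications)
  stopifnot(all(c("category", "count") %in% names(cl)))
  cat_chr <- as.character(cl$category)
  counts <- vapply(OUTCOME_LEVELS, function(lv) {
    sum(cl$count[cat_chr == lv])
  }, numeric(1))
  total <- sum(cl$count)
  discarded <- counts[["DISCARDED"]]
  mapped <- total - discarded
  if (mapped == 0) {
    abort("no mapped reads to tabulate", class = "ampliclass_empty_input")
  }
  mutated <- mapped - counts[["UNMODIFIED"]]
  mapped_levels <- setdiff(OUTCOME_LEVELS, "DISCARDED")
  categories <- tibble(
    category = factor(mapped_levels, levels = OUTCOME_LEVELS),
    count = as.integer(counts[mapped_levels]),
    frac_mapped = counts[mapped_levels] / mapped,
    frac_mutated = ifelse(mapped_levels == "UNMODIFIED", NA_real_,
                          if (mutated > 0) counts[mapped_levels] / mutated else 0)
  )
  structure(
    list(categories = categories,
         total_reads = as.integer(total),
         discarded_reads = as.integer(discarded),
         mapped_reads = as.integer(mapped),
         mutated_reads = as.integer(mutated),
         no_mutated_reads = mutated == 0,
         hdr_indel_ratio = hdr_indel_ratio_from_counts(counts, mapped, cfg)),
    class = "outcome_table"
  )
}

hdr_indel_ratio_from_counts <- function(counts, mapped, cfg) {
  denom_levels <- c("NHEJ", "MH_DEL", "OTHER")
  if (cfg$ratio_denominator == "non_hdr_mutated") {
    denom_levels <- c(denom_levels, "NHEJ_KI")
  }
  hdr <- counts[["HDR_KI"]] / mapped
  denom <- sum(counts[denom_levels]) / mapped
  if (denom == 0) {
    if (hdr == 0) NA_real_ else Inf
  } else {
    hdr / denom
  }
}

#' HDR to indel ratio
#'
#' Ratio of the HDR knock-in fraction to the mutagenic-indel fraction
#' (`NHEJ + MH_DEL + OTHER` by default; `NHEJ_KI` is excluded because the
#' ratio contrasts precise knock-in with mutagenic outcomes). `Inf` when
#' indels are absent but HDR reads exist; `NA` when both are zero.
#'
#' @param x An `outcome_table`.
#' @return A single number (e.g. `7.7` for a 7.7:1 ratio).
#' @export
hdr_indel_ratio <- function(x) {
  stopifnot(inherits(x, "outcome_table"))
  x$hdr_indel_ratio
}

#' @export
print.outcome_table <- function(x, ...) {
  cat(sprintf("<outcome_table> %d reads: %d mapped, %d mutated, %d discarded\n",
              x$total_reads, x$mapped_reads, x$mutated_reads, x$discarded_reads))
  df <- as.data.frame(x$categories)
  df$frac_mapped <- sprintf("%.4f", df$frac_mapped)
  df$frac_mutated <- ifelse(is.na(df$frac_mutated), "",
                            sprintf("%.4f", as.numeric(df$frac_mutated)))
  print(df, row.names = FALSE)
  if (!is.na(x$hdr_indel_ratio)) {
    cat(sprintf("HDR:indel ratio = %.2f\n", x$hdr_indel_ratio))
  }
  invisible(x)
}

#' @rdname tally_outcomes
#' @param x An `outcome_table`.
#' @param ... Unused.
#' @method tidy outcome_table
#' @export
tidy.outcome_table <- function(x, ...) {
  x$categories
}

#' @rdname tally_outcomes
#' @method glance outcome_table
#' @export
glance.outcome_table <- function(x, ...) {
  tibble(total_reads = x$total_reads,
         mapped_reads = x$mapped_reads,
         mutated_reads = x$mutated_reads,
         discarded_reads = x$discarded_reads,
         hdr_indel_ratio = x$hdr_indel_ratio)
}

#' @rdname tally_outcomes
#' @param object An `outcome_table`.
#' @method autoplot outcome_table
#' @export
autoplot.outcome_table <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$count > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = "sample", y = .data$frac_mapped,
                                   fill = .data$category)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "fraction of mapped reads", fill = "outcome") +
    ggplot2::theme_minimal()
}

#' Top variants around the cut site
#'
#' Groups mapped reads by their canonical in-window variant key and
#' renders the most frequent variants as gapped sequences over a window of
#' `flank` bases on each side of the cut (deleted bases as `-`, inserted
#' bases in lower case), annotated with the absolute frequency (fraction
#' of mapped reads) and the relative frequency (fraction of mutated
#' reads; `NA` for the unmodified variant).
#'
#' @param classifications Tibble from [classify_reads()].
#' @param design The [experiment_design()].
#' @param n Number of variants to report (default 10).
#' @param flank Bases shown on each side of the cut (default 30).
#' @return A tibble with columns `rank`, `variant_key`, `category`,
#'   `count`, `abs_freq`, `rel_freq`, `window_sequence`, sorted by
#'   `abs_freq` descending (ties by key).
#' @export
top_variants <- function(classifications, design, n = 10L, flank = 30L) {
  stopifnot(n >= 1L, flank >= 1L)
  cl <- as_tibble(classifications)
  cl <- cl[as.character(cl$category) != "DISCARDED", , drop = FALSE]
  if (nrow(cl) == 0L) {
    abort("no mapped reads", class = "ampliclass_empty_input")
  }
  mapped <- sum(cl$count)
  mutated <- sum(cl$count[as.character(cl$category) != "UNMODIFIED"])
  grp <- cl |>
    group_by(.data$variant_key) |>
    summarise(count = sum(.data$count),
              category = names(sort(table(as.character(.data$category)),
                                    decreasing = TRUE))[1],
              .groups = "drop") |>
    arrange(desc(.data$count), .data$variant_key)
  grp$rank <- seq_len(nrow(grp))
  grp <- grp[seq_len(min(n, nrow(grp))), , drop = FALSE]
  grp$abs_freq <- grp$count / mapped
  grp$rel_freq <- ifelse(grp$variant_key == "WT", NA_real_,
                         if (mutated > 0) grp$count / mutated else NA_real_)
  grp$window_sequence <- vapply(grp$variant_key, render_variant_window,
                                character(1), design = design, flank = flank,
                                USE.NAMES = FALSE)
  grp[, c("rank", "variant_key", "category", "count", "abs_freq",
          "rel_freq", "window_sequence")]
}

# render the +/-flank window of a variant: reference bases with deletions
# as '-' and insertions in lower case after their insertion point
render_variant_window <- function(key, design, flank = 30L) {
  ref <- design$reference
  b <- design$cut$site
  L <- nchar(ref)
  lo <- max(1L, b - flank + 1L)
  hi <- min(L, b + flank)
  ev <- parse_variant_key(key)
  chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  disp <- as.list(chars)
  if (nrow(ev) > 0L) {
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      if (e$etype == "deletion") {
        idx <- e$ref_start:(e$ref_start + e$length - 1L)
        disp[idx] <- list("-")
      } else {
        p <- max(1L, e$ref_start)
        ins <- tolower(e$seq)
        disp[[p]] <- if (e$ref_start == 0L) paste0(ins, disp[[p]])
                     else paste0(disp[[p]], ins)
      }
    }
  }
  paste(unlist(disp[lo:hi]), collapse = "")
}

#' Plot a top-variant profile
#'
#' Horizontal bar panel of the most frequent variants, labelled with their
#' windowed sequence and frequencies.
#'
#' @param variants Tibble from [top_variants()].
#' @return A ggplot object.
#' @export
plot_variant_profile <- function(variants) {
  df <- variants
  df$label <- sprintf("%s  Freq. %.1f%%%s", df$window_sequence,
                      100 * df$abs_freq,
                      ifelse(is.na(df$rel_freq), "",
                             sprintf(" (Rel. %.1f%%)", 100 * df$rel_freq)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$abs_freq,
                                   y = stats::reorder(.data$label, .data$abs_freq),
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "fraction of mapped reads", y = NULL, fill = "outcome") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(family = "mono", size = 7))
}
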