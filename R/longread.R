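#' Per-base coverage profile of a long-read amplicon
#'
#' Computes raw per-base depth over the amplicon from aligned long reads:
#' `depth[i]` counts the reads whose alignment covers base `i` outside any
#' deletion segment. `Ct` (unique reads) counts distinct read ids whose
#' span intersects the amplicon and covers at least `min_span_frac` of it;
#' `Cm` is the mean per-base depth. Large deletions remove coverage, so
#' `Cm` drops below `Ct` in proportion to the deleted fraction — the basis
#' of the deletion-proportion statistic.
#'
#' @param reads Tibble of aligned reads with columns `read_id`,
#'   `span_start`, `span_end` (1-based, inclusive) and optional
#'   `del_start`, `del_end` (one deletion segment per row; `NA` for none).
#' @param amplicon_length Amplicon length in bp.
#' @param min_span_frac Minimum fraction of the amplicon a read's span
#'   must cover to count towards `Ct` (default 0: any intersecting read).
#' @return An object of class `coverage_profile` with fields `depth`
#'   (integer vector of length `amplicon_length`), `unique_reads` (Ct),
#'   `mean_depth` (Cm) and `amplicon_length`.
#' @export
coverage_from_alignments <- function(reads, amplicon_length, min_span_frac = 0) {
  reads <- as_tibble(reads)
  stopifnot(all(c("read_id", "span_start", "span_end") %in% names(reads)))
  L <- as.integer(amplicon_length)
  stopifnot(L >= 1L)
  if (!"del_start" %in% names(reads)) reads$del_start <- NA_integer_
  if (!"del_end" %in% names(reads)) reads$del_end <- NA_integer_

  # clip spans to the amplicon and drop non-intersecting reads
  s <- pmax(as.integer(reads$span_start), 1L)
  e <- pmin(as.integer(reads$span_end), L)
  keep <- s <= e
  span_len <- (e - s + 1L)
  counted <- keep & span_len >= min_span_frac * L
  ct <- length(unique(reads$read_id[counted]))

  # difference-array accumulation of span coverage minus deletion segments
  d <- numeric(L + 1L)
  add_interval <- function(d, from, to, val) {
    d[from] <- d[from] + val
    d[to + 1L] <- d[to + 1L] - val
    d
  }
  for (i in which(counted)) {
    d <- add_interval(d, s[i], e[i], 1)
    ds <- reads$del_start[i]
    de <- reads$del_end[i]
    if (!is.na(ds) && !is.na(de)) {
      ds <- max(as.integer(ds), s[i])
      de <- min(as.integer(de), e[i])
      if (ds <= de) d <- add_interval(d, ds, de, -1)
    }
  }
  depth <- as.integer(cumsum(d[seq_len(L)]))
  structure(
    list(depth = depth, unique_reads = ct, mean_depth = mean(depth),
         amplicon_length = L),
    class = "coverage_profile"
  )
}

#' Construct a coverage profile from a depth vector
#'
#' @param depth Integer per-base depth vector.
#' @param unique_reads Number of unique reads aligned within the amplicon
#'   (Ct).
#' @return A `coverage_profile`.
#' @export
coverage_profile <- function(depth, unique_reads) {
  depth <- as.integer(depth)
  stopifnot(length(depth) >= 1L, all(depth >= 0L), unique_reads >= 0L)
  structure(
    list(depth = depth, unique_reads = as.integer(unique_reads),
         mean_depth = mean(depth), amplicon_length = length(depth)),
    class = "coverage_profile"
  )
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %d bp, Ct = %d unique reads, Cm = %.2f mean depth\n",
              x$amplicon_length, x$unique_reads, x$mean_depth))
  invisible(x)
}

#' Large-deletion proportion of a long-read amplicon
#'
#' `(Ct - Cm) / Ct`, where `Ct` is the number of unique reads aligned
#' within the amplicon and `Cm` the mean per-base coverage. With every
#' read spanning the full amplicon and no deletions, `Cm == Ct` and the
#' proportion is 0; reads carrying large deletions depress `Cm` and raise
#' the proportion towards 1.
#'
#' @param profile A `coverage_profile` (or a number taken as a
#'   pre-computed proportion, passed through unchanged).
#' @return Deletion proportion in `[0, 1]` for spanning reads.
#' @export
deletion_proportion <- function(profile) {
  if (is.numeric(profile) && length(profile) == 1L) return(profile)
  stopifnot(inherits(profile, "coverage_profile"))
  ct <- profile$unique_reads
  if (ct == 0L) {
    abort("Ct is zero: no reads aligned within the amplicon",
          class = "ampliclass_division_by_zero")
  }
  (ct - profile$mean_depth) / ct
}

#' Deletion index between treated and control samples
#'
#' Difference in deletion proportion between a treated and a control
#' group: an estimate of the treatment-induced large-deletion burden.
#'
#' @param treated,control `coverage_profile`s or numeric deletion
#'   proportions.
#' @return `deletion_proportion(treated) - deletion_proportion(control)`.
#' @export
deletion_index <- function(treated, control) {
  deletion_proportion(treated) - deletion_proportion(control)
}

#' Read / write a per-base coverage table
#'
#' Plain-TSV coverage exchange format: a manifest comment line `# Ct=<n>`
#' followed by a header and two columns `pos` (0-based) and `depth`.
#'
#' @param path File path.
#' @return [read_coverage_tsv()] returns a `coverage_profile`.
#' @export
read_coverage_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("^#\\s*Ct\\s*=\\s*(\\d+)", header))[[1]]
  if (length(m) < 2L) {
    abort("coverage TSV must start with a '# Ct=<n>' manifest line",
          class = "ampliclass_bad_coverage")
  }
  ct <- as.integer(m[2])
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("pos", "depth") %in% names(df)))
  df <- df[order(df$pos), , drop = FALSE]
  stopifnot(identical(as.integer(df$pos), seq_len(nrow(df)) - 1L))
  coverage_profile(df$depth, ct)
}

#' @rdname read_coverage_tsv
#' @param profile A `coverage_profile`.
#' @export
write_coverage_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "coverage_profile"))
  writeLines(sprintf("# Ct=%d", profile$unique_reads), path)
  df <- tibble(pos = seq_along(profile$depth) - 1L, depth = profile$depth)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
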