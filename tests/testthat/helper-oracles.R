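# Independent oracles used to validate the package primitives.
# Everything here is deliberately brute-force and shares no code with the
# package implementation paths it checks.

# --- microhomology oracle: count equal-length deletion placements ---------

# all removal results for deletions of `len` from `ref`
oracle_removal_strings <- function(ref, len) {
  L <- nchar(ref)
  vapply(seq_len(L - len + 1L), function(s) {
    paste0(substr(ref, 1L, s - 1L), substr(ref, s + len, L))
  }, character(1))
}

# number of distinct equal-length placements yielding the same edited
# sequence as deleting ref[start .. start+len-1], minus one
oracle_mh <- function(ref, start, len) {
  removals <- oracle_removal_strings(ref, len)
  sum(removals == removals[start]) - 1L
}

# --- exhaustive affine-gap global alignment oracle (Gotoh) ----------------

# optimal global alignment score with affine gaps; gap of length k costs
# open + k * ext. Returns the score and the full set of optimal event
# lists (each left-normalized), enumerated by traceback.
oracle_align <- function(query, ref, match = 2, mismatch = -2,
                         open = 10, ext = 1, max_paths = 500L) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(q)
  m <- length(r)
  NEG <- -1e9
  # M: ends in diagonal; IQ: gap in ref (insertion, consumes query);
  # DR: gap in query (deletion, consumes ref)
  M <- matrix(NEG, n + 1L, m + 1L)
  IQ <- matrix(NEG, n + 1L, m + 1L)
  DR <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  for (i in seq_len(n)) IQ[i + 1L, 1L] <- -(open + ext * i)
  for (j in seq_len(m)) DR[1L, j + 1L] <- -(open + ext * j)
  for (i in seq_len(n + 1L)) {
    for (j in seq_len(m + 1L)) {
      if (i > 1L && j > 1L) {
        s <- if (q[i - 1L] == r[j - 1L]) match else mismatch
        M[i, j] <- max(M[i - 1L, j - 1L], IQ[i - 1L, j - 1L],
                       DR[i - 1L, j - 1L]) + s
      }
      if (i > 1L && !(i == 2L && j == 1L)) {
        IQ[i, j] <- max(IQ[i, j],
                        M[i - 1L, j] - open - ext,
                        IQ[i - 1L, j] - ext,
                        DR[i - 1L, j] - open - ext)
      }
      if (j > 1L && !(j == 2L && i == 1L)) {
        DR[i, j] <- max(DR[i, j],
                        M[i, j - 1L] - open - ext,
                        DR[i, j - 1L] - ext,
                        IQ[i, j - 1L] - open - ext)
      }
    }
  }
  best <- max(M[n + 1L, m + 1L], IQ[n + 1L, m + 1L], DR[n + 1L, m + 1L])

  # enumerate all optimal paths backwards; ops are recorded reversed
  paths <- list()
  walk <- function(i, j, state, ops) {
    if (length(paths) >= max_paths) return()
    if (i == 1L && j == 1L && state == "M") {
      paths[[length(paths) + 1L]] <<- rev(ops)
      return()
    }
    if (state == "M") {
      if (i > 1L && j > 1L) {
        s <- if (q[i - 1L] == r[j - 1L]) match else mismatch
        target <- M[i, j] - s
        op <- if (q[i - 1L] == r[j - 1L]) "=" else "X"
        for (prev in c("M", "IQ", "DR")) {
          val <- switch(prev, M = M[i - 1L, j - 1L], IQ = IQ[i - 1L, j - 1L],
                        DR = DR[i - 1L, j - 1L])
          if (val == target) walk(i - 1L, j - 1L, prev, c(ops, op))
        }
      } else if (i == 1L && j == 1L) {
        paths[[length(paths) + 1L]] <<- rev(ops)
      }
    } else if (state == "IQ") {
      if (IQ[i, j] == IQ[i - 1L, j] - ext && i > 2L) {
        walk(i - 1L, j, "IQ", c(ops, "I"))
      }
      if (IQ[i, j] == M[i - 1L, j] - open - ext) walk(i - 1L, j, "M", c(ops, "I"))
      if (IQ[i, j] == DR[i - 1L, j] - open - ext) walk(i - 1L, j, "DR", c(ops, "I"))
    } else { # DR
      if (DR[i, j] == DR[i, j - 1L] - ext && j > 2L) {
        walk(i, j - 1L, "DR", c(ops, "D"))
      }
      if (DR[i, j] == M[i, j - 1L] - open - ext) walk(i, j - 1L, "M", c(ops, "D"))
      if (DR[i, j] == IQ[i, j - 1L] - open - ext) walk(i, j - 1L, "IQ", c(ops, "D"))
    }
  }
  for (state in c("M", "IQ", "DR")) {
    val <- switch(state, M = M[n + 1L, m + 1L], IQ = IQ[n + 1L, m + 1L],
                  DR = DR[n + 1L, m + 1L])
    if (val == best) walk(n + 1L, m + 1L, state, character(0))
  }

  event_sets <- unique(lapply(paths, function(ops) {
    oracle_ops_to_events(ops, q, r)
  }))
  list(score = best, event_sets = event_sets)
}

# convert an op string vector (=, X, I, D) into a left-normalized indel
# event data frame in reference coordinates
oracle_ops_to_events <- function(ops, q, r) {
  qi <- 0L
  rj <- 0L
  events <- list()
  runs <- rle(ops)
  floor_pos <- 0L  # left shifts never cross an earlier event (same rule
                   # as the package normalizer)
  for (k in seq_along(runs$values)) {
    op <- runs$values[k]
    len <- runs$lengths[k]
    if (op == "=") {
      qi <- qi + len
      rj <- rj + len
    } else if (op == "X") {
      for (t in seq_len(len)) {
        events[[length(events) + 1L]] <-
          data.frame(etype = "substitution", ref_start = rj + t,
                     length = 1L, seq = q[qi + t])
      }
      qi <- qi + len
      rj <- rj + len
      floor_pos <- rj
    } else if (op == "I") {
      ins <- paste(q[(qi + 1L):(qi + len)], collapse = "")
      ev <- oracle_normalize_insertion(r, rj, ins, floor_pos)
      events[[length(events) + 1L]] <- ev
      floor_pos <- max(floor_pos, ev$ref_start)
      qi <- qi + len
    } else { # D
      events[[length(events) + 1L]] <-
        oracle_normalize_deletion(r, rj + 1L, len, floor_pos)
      rj <- rj + len
      floor_pos <- rj
    }
  }
  if (length(events) == 0L) {
    return(data.frame(etype = character(0), ref_start = integer(0),
                      length = integer(0), seq = character(0)))
  }
  df <- do.call(rbind, events)
  df[order(df$ref_start, df$etype), , drop = FALSE]
}

oracle_normalize_deletion <- function(r, start, len, floor_pos = 0L) {
  while (start > floor_pos + 1L && r[start - 1L] == r[start + len - 1L]) {
    start <- start - 1L
  }
  data.frame(etype = "deletion", ref_start = start, length = len, seq = "")
}

oracle_normalize_insertion <- function(r, pos, seq, floor_pos = 0L) {
  ins <- strsplit(seq, "", fixed = TRUE)[[1]]
  nn <- length(ins)
  while (pos > floor_pos && r[pos] == ins[nn]) {
    ins <- c(r[pos], ins[-nn])
    pos <- pos - 1L
  }
  data.frame(etype = "insertion", ref_start = pos, length = nn,
             seq = paste(ins, collapse = ""))
}

# random DNA of length n (for test fixtures)
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# introduce a random mutation burden into a sequence (for alignment tests)
mutate_seq <- function(s, n_sub = 0L, n_del = 0L, n_ins = 0L) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  for (k in seq_len(n_sub)) {
    i <- sample.int(length(chars), 1L)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  if (n_del > 0L && length(chars) > n_del + 2L) {
    i <- sample.int(length(chars) - n_del, 1L)
    chars <- chars[-(i:(i + n_del - 1L))]
  }
  if (n_ins > 0L) {
    i <- sample.int(length(chars), 1L)
    chars <- append(chars, sample(c("A", "C", "G", "T"), n_ins, replace = TRUE), after = i)
  }
  paste(chars, collapse = "")
}
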