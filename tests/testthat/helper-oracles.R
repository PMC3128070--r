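# Independent brute-force oracles. Each reimplements the quantity under test
# from first principles, sharing no code with the package internals.

# Smith-Waterman score by explicit Gotoh dynamic programming over three
# matrices; gap of length L costs open + L * ext.
sw_score_oracle <- function(q, s, match = 1, mismatch = -3, open = 5,
                            ext = 2) {
  qc <- strsplit(q, "")[[1L]]
  sc <- strsplit(s, "")[[1L]]
  m <- length(qc); n <- length(sc)
  NEG <- -1e9
  M <- matrix(0, m + 1L, n + 1L)   # alignment ends in a match/mismatch
  X <- matrix(NEG, m + 1L, n + 1L) # ends in a gap in the subject
  Y <- matrix(NEG, m + 1L, n + 1L) # ends in a gap in the query
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sub <- if (qc[i] == sc[j]) match else mismatch
      diag_best <- max(M[i, j], X[i, j], Y[i, j], 0)
      M[i + 1L, j + 1L] <- diag_best + sub
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext,
                               X[i, j + 1L] - ext)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext,
                               Y[i + 1L, j] - ext)
      best <- max(best, M[i + 1L, j + 1L], X[i + 1L, j + 1L],
                  Y[i + 1L, j + 1L])
    }
  }
  best
}

# Union length of 0-based half-open intervals via a boolean position array.
coverage_oracle <- function(start, end, gene_length) {
  covered <- logical(gene_length)
  for (i in seq_along(start)) {
    if (end[i] > start[i]) covered[(start[i] + 1L):end[i]] <- TRUE
  }
  sum(covered)
}

# Exhaustive microsatellite enumeration: every start and unit length, count
# whole-unit copies by direct substring comparison. A candidate is reported
# when it has >= min_units copies, its motif is not a repetition of a
# shorter motif, and the tandem region cannot be extended left by even one
# base (so each maximal region is reported once, at its leftmost phase).
ssr_oracle <- function(seq, unit_lengths = 2:5, min_units = 6L) {
  n <- nchar(seq)
  out <- list()
  for (k in unit_lengths) {
    for (i in seq_len(max(0L, n - k * min_units + 1L))) {
      unit <- substr(seq, i, i + k - 1L)
      # primitive motif?
      primitive <- TRUE
      for (d in seq_len(k - 1L)) {
        if (k %% d == 0L && strrep(substr(unit, 1L, d), k / d) == unit) {
          primitive <- FALSE
          break
        }
      }
      if (!primitive) next
      # left-maximal: the base before must break the period
      if (i > 1L && substr(seq, i - 1L, i - 1L) ==
            substr(seq, i - 1L + k, i - 1L + k)) {
        next
      }
      copies <- 1L
      while (i + (copies + 1L) * k - 1L <= n &&
               substr(seq, i + copies * k, i + (copies + 1L) * k - 1L) ==
                 unit) {
        copies <- copies + 1L
      }
      if (copies >= min_units) {
        out[[length(out) + 1L]] <- data.frame(
          motif = unit, unit_length = k, n_units = copies,
          start = i - 1L, end = i - 1L + k * copies)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(motif = character(), unit_length = integer(),
                      n_units = integer(), start = integer(),
                      end = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$unit_length), , drop = FALSE]
}

# Site classification re-derived directly from the stated rules.
classify_oracle <- function(depth, ref_count, max_alt_count) {
  vf <- if (depth > 0) max_alt_count / depth else 0
  deviating <- depth - ref_count
  if (depth >= 5 && vf >= 0.2) return("SNP")
  if (depth >= 10 && deviating == 1) return("sequencing_error")
  "none"
}

# Best hit per subject by explicit split-apply, ties by bitscore then query.
unigene_oracle <- function(hits) {
  parts <- split(seq_len(nrow(hits)), hits$subject_id)
  idx <- vapply(parts, function(rows) {
    h <- hits[rows, ]
    o <- order(h$evalue, -h$bitscore, h$query_id)
    rows[o[1L]]
  }, integer(1L))
  hits[idx[order(names(idx))], , drop = FALSE]
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
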