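#' Find perfect microsatellite (SSR) repeats
#'
#' Scans sequences for maximal perfect tandem repeats of 2–5 nt motifs with
#' at least `min_units` copies (default six repeat units, the conventional
#' reporting threshold). Only perfect repeats are reported. A region whose
#' motif is itself a tandem repetition of a shorter motif (e.g. `ACAC` as a
#' tetramer) is reported once, at the shortest unit length; mononucleotide
#' runs are excluded by the same rule. Spans are full-unit maximal: a run is
#' never extendable by a complete unit copy on either side, and any partial
#' trailing unit is excluded from the reported span, so
#' `end - start == unit_length * n_units` always holds.
#'
#' @param seqs Sequence tibble (`id`, `seq`), or a single sequence string.
#' @param unit_lengths Motif lengths to search, a subset of 2:5.
#' @param min_units Minimum number of repeat units (default 6).
#' @return Tibble with one row per repeat: `contig_id`, `motif`,
#'   `unit_length`, `n_units`, `start`, `end` (0-based half-open), sorted by
#'   contig, position and unit length.
#' @export
find_microsatellites <- function(seqs, unit_lengths = 2:5, min_units = 6L) {
  stopifnot(all(unit_lengths %in% 2:5), min_units >= 2L)
  if (is.character(seqs)) {
    seqs <- tibble::tibble(id = paste0("seq", seq_along(seqs)), seq = seqs)
  }
  rows <- lapply(seq_len(nrow(seqs)), function(i) {
    hits <- scan_ssr(seqs$seq[i], unit_lengths, min_units)
    if (nrow(hits) > 0L) hits$contig_id <- seqs$id[i]
    hits
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(contig_id = character(), motif = character(),
                          unit_length = integer(), n_units = integer(),
                          start = integer(), end = integer()))
  }
  out <- out[order(out$contig_id, out$start, out$unit_length), ,
             drop = FALSE]
  out[c("contig_id", "motif", "unit_length", "n_units", "start", "end")]
}

scan_ssr <- function(seq, unit_lengths, min_units) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  found <- list()
  for (k in sort(unit_lengths)) {
    if (n < k * min_units) next
    # eq[i] says position i matches position i+k; a maximal TRUE run of
    # length L starting at i marks a tandem region of L + k bases.
    eq <- chars[seq_len(n - k)] == chars[(k + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= k * (min_units - 1L))) {
      s <- starts[j]                       # 1-based start of the run
      n_units <- (r$lengths[j] + k) %/% k  # full unit copies
      motif <- substr(seq, s, s + k - 1L)
      if (!is_primitive_motif(motif)) next
      found[[length(found) + 1L]] <- tibble::tibble(
        motif = motif,
        unit_length = k,
        n_units = n_units,
        start = s - 1L,
        end = s - 1L + k * n_units
      )
    }
  }
  dplyr::bind_rows(found)
}

# TRUE unless the motif is a whole-number repetition of a shorter motif
# (including homopolymers).
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        strrep(substr(motif, 1L, d), k %/% d) == motif) {
      return(FALSE)
    }
  }
  TRUE
}
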