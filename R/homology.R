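#' Nucleotide local-alignment scoring scheme
#'
#' Match/mismatch scores and affine gap penalties for the internal local
#' aligner, plus the Karlin–Altschul parameters used to convert raw scores
#' into E-values. A gap of length L scores `gap_open + L * gap_extend`
#' (the convention used by BLAST-family tools).
#'
#' The defaults (+1/-3, gap open -5, gap extend -2, ungapped
#' `lambda = 1.374`, `K = 0.711` for +1/-3) mimic standard nucleotide-BLAST
#' settings so that the conventional 1e-5 / 1e-10 cutoffs remain meaningful
#' when hits are computed internally instead of imported. The E-values are
#' an approximation: ungapped lambda/K applied to gapped scores.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap_open Gap opening score (< 0).
#' @param gap_extend Per-base gap extension score (< 0).
#' @param lambda,K Karlin–Altschul parameters (> 0) for [evalue_of()].
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 1, mismatch = -3, gap_open = -5,
                           gap_extend = -2, lambda = 1.374, K = 0.711) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0,
            lambda > 0, K > 0)
  structure(
    list(match = match, mismatch = mismatch, gap_open = gap_open,
         gap_extend = gap_extend, lambda = lambda, K = K),
    class = "scoring_scheme"
  )
}

# Substitution matrix over the cleaned alphabet; N never counts as a match.
scheme_matrix <- function(scheme) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(scheme$mismatch, 5L, 5L, dimnames = list(letters, letters))
  diag(m) <- scheme$match
  m["N", "N"] <- scheme$mismatch
  m
}

#' Optimal local alignment of two sequences
#'
#' Smith–Waterman local alignment with affine gaps. The heavy lifting is
#' done by `Biostrings::pairwiseAlignment()`; this wrapper fixes the scoring
#' conventions, converts coordinates to 0-based half-open intervals, and
#' extracts the query segments that fall inside the aligned span but are
#' absent from the subject (needed for defect diagnosis). When no cell of
#' the dynamic-programming matrix is positive the result is the empty
#' alignment with score 0.
#'
#' @param query,subject Nucleotide strings (character scalars).
#' @param scheme A [scoring_scheme()].
#' @param query_id,subject_id Identifiers carried into the result.
#' @return A one-row tibble: `query_id`, `subject_id`, `score`,
#'   `q_start`, `q_end`, `s_start`, `s_end` (0-based half-open),
#'   `aligned_length` (alignment columns incl. gaps), `identities`,
#'   `pident`, and a list-column `q_inserts` of tibbles (`start`, `end`,
#'   0-based half-open on the query) of internal query-only segments.
#' @export
smith_waterman <- function(query, subject, scheme = scoring_scheme(),
                           query_id = "query", subject_id = "subject") {
  stopifnot(nchar(query) >= 1L, nchar(subject) >= 1L)
  res <- sw_batch(query, subject, scheme)
  res$query_id <- query_id
  res$subject_id <- subject_id
  res[c("query_id", "subject_id", "score", "q_start", "q_end",
        "s_start", "s_end", "aligned_length", "identities", "pident",
        "q_inserts")]
}

# Vectorised core: many queries against one subject.
sw_batch <- function(queries, subject, scheme) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = queries, subject = subject, type = "local",
    substitutionMatrix = scheme_matrix(scheme),
    gapOpening = abs(scheme$gap_open), gapExtension = abs(scheme$gap_extend)
  )
  score <- Biostrings::score(pa)
  n <- length(queries)
  out <- tibble::tibble(
    score = pmax(score, 0),
    q_start = ifelse(score > 0, IRanges::start(Biostrings::pattern(pa)) - 1L, 0L),
    q_end = ifelse(score > 0, IRanges::end(Biostrings::pattern(pa)), 0L),
    s_start = ifelse(score > 0, IRanges::start(Biostrings::subject(pa)) - 1L, 0L),
    s_end = ifelse(score > 0, IRanges::end(Biostrings::subject(pa)), 0L),
    aligned_length = ifelse(score > 0, Biostrings::nchar(pa), 0L),
    identities = ifelse(score > 0, Biostrings::nmatch(pa), 0L)
  )
  out$pident <- ifelse(out$aligned_length > 0,
                       100 * out$identities / out$aligned_length, 0)
  ap <- as.character(Biostrings::alignedPattern(pa))
  as <- as.character(Biostrings::alignedSubject(pa))
  out$q_inserts <- lapply(seq_len(n), function(i) {
    if (score[i] <= 0) return(empty_interval_tbl())
    query_only_segments(ap[i], as[i], out$q_start[i])
  })
  out
}

empty_interval_tbl <- function() {
  tibble::tibble(start = integer(), end = integer())
}

# Query coordinates (0-based half-open) of alignment columns where the
# subject carries a gap, i.e. query sequence inside the aligned span that has
# no counterpart in the subject.
query_only_segments <- function(aligned_pattern, aligned_subject, q_offset) {
  p <- strsplit(aligned_pattern, "", fixed = TRUE)[[1L]]
  s <- strsplit(aligned_subject, "", fixed = TRUE)[[1L]]
  qpos <- cumsum(p != "-")  # 1-based query position within aligned span
  gap_cols <- s == "-" & p != "-"
  if (!any(gap_cols)) return(empty_interval_tbl())
  r <- rle(gap_cols)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(
    start = q_offset + qpos[starts[keep]] - 1L,
    end = q_offset + qpos[ends[keep]]
  )
}

#' Karlin–Altschul E-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` between a query of length `m` and a
#' database of total length `n`. Computed in log space so large scores
#' underflow cleanly to 0 rather than producing `NaN`.
#'
#' @param score Raw alignment score(s), >= 0.
#' @param m Query length, bp.
#' @param n Subject/database total length, bp.
#' @param scheme A [scoring_scheme()] supplying `lambda` and `K`.
#' @return E-value(s), non-negative.
#' @export
evalue_of <- function(score, m, n, scheme = scoring_scheme()) {
  stopifnot(all(score >= 0), all(m >= 1), all(n >= 1))
  exp(log(scheme$K) + log(m) + log(n) - scheme$lambda * score)
}

# Normalised ("bit") score under the scheme's ungapped parameters.
bit_score_of <- function(score, scheme) {
  (scheme$lambda * score - log(scheme$K)) / log(2)
}

#' Align every query sequence against every subject sequence
#'
#' Computes the best local alignment for each (query, subject) pair with the
#' internal aligner, assigns E-values against the whole subject set (the
#' database length `n` is the summed subject length, as a database search
#' would use), and keeps pairs with `evalue < max_evalue`. This is the
#' internal substitute for an external homology search when the reference is
#' a small nucleotide gene set.
#'
#' @param queries,subjects Sequence tibbles (`id`, `seq`).
#' @param scheme A [scoring_scheme()].
#' @param max_evalue Strict E-value cutoff; `Inf` keeps every pair with a
#'   positive-scoring alignment.
#' @param db_size Database length used for E-values; defaults to the summed
#'   subject length.
#' @return Hit tibble: `query_id`, `subject_id`, `score`, `q_start`,
#'   `q_end`, `s_start`, `s_end` (0-based half-open), `aligned_length`,
#'   `identities`, `pident`, `evalue`, `bitscore`, `query_length`,
#'   `subject_length`, list-column `q_inserts`.
#' @export
align_contigs <- function(queries, subjects, scheme = scoring_scheme(),
                          max_evalue = Inf, db_size = NULL) {
  stopifnot(nrow(subjects) >= 1L)
  if (is.null(db_size)) db_size <- sum(nchar(subjects$seq))
  if (nrow(queries) == 0L) return(empty_alignment_table())
  per_subject <- lapply(seq_len(nrow(subjects)), function(j) {
    res <- sw_batch(queries$seq, subjects$seq[j], scheme)
    res$query_id <- queries$id
    res$subject_id <- subjects$id[j]
    res$query_length <- nchar(queries$seq)
    res$subject_length <- nchar(subjects$seq[j])
    res
  })
  hits <- dplyr::bind_rows(per_subject)
  hits$evalue <- evalue_of(hits$score, hits$query_length, db_size, scheme)
  hits$bitscore <- bit_score_of(hits$score, scheme)
  hits <- hits[hits$score > 0 & hits$evalue < max_evalue, , drop = FALSE]
  hits <- hits[order(hits$query_id, hits$subject_id), , drop = FALSE]
  hits[c("query_id", "subject_id", "score", "q_start", "q_end", "s_start",
         "s_end", "aligned_length", "identities", "pident", "evalue",
         "bitscore", "query_length", "subject_length", "q_inserts")]
}

empty_alignment_table <- function() {
  tibble::tibble(
    query_id = character(), subject_id = character(), score = double(),
    q_start = integer(), q_end = integer(), s_start = integer(),
    s_end = integer(), aligned_length = integer(), identities = integer(),
    pident = double(), evalue = double(), bitscore = double(),
    query_length = integer(), subject_length = integer(),
    q_inserts = list()
  )
}

#' Filter hits by E-value and minimum query length
#'
#' Keeps hits with `evalue` strictly below `max_evalue`, and — when
#' `min_query_length` is given — whose query is strictly longer than that
#' many bp (the conventional "> 200 bp" contig class).
#'
#' @param hits Hit tibble with at least `query_id` and `evalue`.
#' @param max_evalue Strict E-value cutoff.
#' @param min_query_length Optional strict lower bound on query length, bp.
#' @param query_lengths Where to find query lengths when filtering on
#'   length: a named numeric vector (names = query ids), a tibble with
#'   columns `id` and `length`, or a sequence tibble (`id`, `seq`). Not
#'   needed if `hits` already has a `query_length` column.
#' @return The surviving rows of `hits`.
#' @export
filter_hits <- function(hits, max_evalue, min_query_length = NULL,
                        query_lengths = NULL) {
  out <- hits[hits$evalue < max_evalue, , drop = FALSE]
  if (is.null(min_query_length)) return(out)
  len <- resolve_query_lengths(out, query_lengths)
  missing <- is.na(len)
  if (any(missing)) {
    stop("no length available for query '",
         out$query_id[which(missing)[1L]], "'")
  }
  out[len > min_query_length, , drop = FALSE]
}

resolve_query_lengths <- function(hits, query_lengths) {
  if (is.null(query_lengths)) {
    if (!"query_length" %in% names(hits)) {
      stop("query_lengths must be supplied when hits carry no ",
           "'query_length' column")
    }
    return(hits$query_length)
  }
  if (is.data.frame(query_lengths)) {
    lookup <- if ("length" %in% names(query_lengths)) {
      stats::setNames(query_lengths$length, query_lengths$id)
    } else {
      stats::setNames(nchar(query_lengths$seq), query_lengths$id)
    }
    return(unname(lookup[hits$query_id]))
  }
  unname(query_lengths[hits$query_id])
}

#' Reduce a hit table to unique gene hits (UniGens)
#'
#' Redundant hits to the same subject are collapsed to the single best hit:
#' lowest E-value, ties broken by higher bit score and then by lexicographic
#' query id. One query may contribute hits to many subjects, but each
#' subject is represented exactly once.
#'
#' @param hits Hit tibble with `query_id`, `subject_id`, `evalue` and
#'   `bitscore` columns.
#' @return One row per distinct `subject_id`: the best hit.
#' @export
unigene_reduce <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore),
                   .data$query_id) |>
    dplyr::distinct(.data$subject_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$subject_id)
}

#' Hit concordance between two UniGen sets
#'
#' Counts subjects hit by both assemblies and by each one alone. Agreement
#' between independent assemblies is evidence that the shared hits are
#' trustworthy.
#'
#' @param a,b UniGen tibbles (one row per subject, see [unigene_reduce()]).
#' @return One-row tibble: `shared`, `only_a`, `only_b`.
#' @export
shared_unigenes <- function(a, b) {
  sa <- unique(a$subject_id)
  sb <- unique(b$subject_id)
  tibble::tibble(
    shared = length(intersect(sa, sb)),
    only_a = length(setdiff(sa, sb)),
    only_b = length(setdiff(sb, sa))
  )
}
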