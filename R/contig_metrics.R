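#' Contig length summary statistics
#'
#' Summarises a contig set the way assembly-comparison tables usually do:
#' count, minimum, maximum, mean and median length, optionally restricted to
#' contigs strictly longer than `min_length` (the conventional "> 200 bp"
#' class is `min_length = 200`).
#'
#' @param contigs Sequence tibble with a `seq` column (see [read_fasta()]).
#' @param min_length If not `NULL`, keep only contigs with length strictly
#'   greater than this many bp before summarising.
#' @return A one-row tibble with columns `n_contigs`, `min_len`, `max_len`,
#'   `mean_len`, `median_len`, `min_length_filter`. When no contig survives
#'   the filter, `n_contigs` is 0 and the length columns are `NA`.
#' @export
length_stats <- function(contigs, min_length = NULL) {
  len <- nchar(contigs$seq)
  if (!is.null(min_length)) len <- len[len > min_length]
  tibble::tibble(
    n_contigs = length(len),
    min_len = if (length(len)) min(len) else NA_integer_,
    max_len = if (length(len)) max(len) else NA_integer_,
    mean_len = if (length(len)) mean(len) else NA_real_,
    median_len = if (length(len)) stats::median(len) else NA_real_,
    min_length_filter = if (is.null(min_length)) NA_integer_ else
      as.integer(min_length)
  )
}

#' Contig average coverage
#'
#' Average coverage of a contig is the summed length of all constituent
#' reads (`ssl`) divided by the contig length (`cl`): `ac = ssl / cl`.
#'
#' @param ssl Summed constituent-read length(s), bp.
#' @param cl Contig length(s), bp; must be >= 1.
#' @return Numeric vector of average coverages.
#' @export
average_coverage <- function(ssl, cl) {
  if (any(cl < 1)) stop("contig length (cl) must be >= 1")
  stopifnot(all(ssl >= 0))
  ssl / cl
}

#' Contig length versus average coverage table
#'
#' One row per contig with its length, summed read length and average
#' coverage — the data behind a length-versus-coverage scatter.
#'
#' @param records Tibble with columns `contig_id`, `cl`, `ssl`.
#' @return Tibble with columns `contig_id`, `cl`, `ssl`, `ac`.
#' @export
length_coverage_table <- function(records) {
  if (nrow(records) == 0L) {
    return(tibble::tibble(contig_id = character(), cl = integer(),
                          ssl = double(), ac = double()))
  }
  stopifnot(all(c("contig_id", "cl", "ssl") %in% names(records)))
  dplyr::mutate(
    tibble::as_tibble(records[c("contig_id", "cl", "ssl")]),
    ac = average_coverage(.data$ssl, .data$cl)
  )
}

#' cDNA normalization success check
#'
#' Library normalization is judged successful when the average number of
#' reads per ribosomal-gene contig does not exceed five times the average
#' for all other contigs. The 5x boundary is pass-inclusive.
#'
#' @param mean_ribosomal Mean reads per ribosomal-gene contig.
#' @param mean_other Mean reads per non-ribosomal contig; must be > 0.
#' @param max_ratio Pass threshold on the ratio (default 5).
#' @return One-row tibble with `mean_ribosomal`, `mean_other`, `ratio`,
#'   `passed`.
#' @export
normalization_check <- function(mean_ribosomal, mean_other, max_ratio = 5) {
  if (mean_other <= 0) stop("mean_other must be > 0")
  ratio <- mean_ribosomal / mean_other
  tibble::tibble(
    mean_ribosomal = mean_ribosomal,
    mean_other = mean_other,
    ratio = ratio,
    passed = ratio <= max_ratio
  )
}
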