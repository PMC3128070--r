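#' Build per-position pileups from gapless read alignments
#'
#' Tallies read bases per reference position. Alignments are gapless:
#' `bases` is the read sequence in reference orientation and maps one column
#' per reference position starting at `g_start`.
#'
#' @param alignments Tibble with columns `gene_id`, `g_start` (0-based) and
#'   `bases` (reference-oriented read bases, one character per covered
#'   position).
#' @param genes Reference gene tibble (`id`, `seq`).
#' @return Pileup tibble with one row per reference position of every gene:
#'   `gene_id`, `pos` (0-based), `ref`, `A`, `C`, `G`, `T`, `N`, `depth`.
#' @export
build_pileup <- function(alignments, genes) {
  stopifnot(all(c("gene_id", "g_start", "bases") %in% names(alignments)))
  bases <- c("A", "C", "G", "T", "N")
  per_gene <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes$id[i]
    glen <- nchar(genes$seq[i])
    a <- alignments[alignments$gene_id == g, , drop = FALSE]
    counts <- matrix(0L, nrow = glen, ncol = 5L,
                     dimnames = list(NULL, bases))
    if (nrow(a) > 0L) {
      lens <- nchar(a$bases)
      if (any(a$g_start < 0L | a$g_start + lens > glen)) {
        stop("alignment outside bounds of gene '", g, "'")
      }
      pos <- sequence(lens, from = a$g_start + 1L)  # 1-based positions
      obs <- unlist(strsplit(a$bases, "", fixed = TRUE), use.names = FALSE)
      for (b in bases) {
        sel <- obs == b
        if (any(sel)) counts[, b] <- tabulate(pos[sel], nbins = glen)
      }
    }
    tibble::tibble(
      gene_id = g,
      pos = seq_len(glen) - 1L,
      ref = strsplit(genes$seq[i], "", fixed = TRUE)[[1L]],
      A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
      T = counts[, "T"], N = counts[, "N"],
      depth = as.integer(rowSums(counts))
    )
  })
  dplyr::bind_rows(per_gene)
}

#' Per-gene read depth summary
#'
#' @param pileup Pileup tibble from [build_pileup()].
#' @return One row per gene: `gene_id`, `gene_length`, `mean_depth`,
#'   `min_depth`, `max_depth`, `covered_bp` (positions with depth >= 1).
#' @export
gene_depth_summary <- function(pileup) {
  pileup |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      gene_length = dplyr::n(),
      mean_depth = mean(.data$depth),
      min_depth = min(.data$depth),
      max_depth = max(.data$depth),
      covered_bp = sum(.data$depth >= 1L),
      .groups = "drop"
    )
}

#' Classify pileup sites as SNP, sequencing error, or neither
#'
#' The classification rules, applied in order:
#' * **SNP** — depth >= `min_coverage` (default 5) and variant frequency
#'   (count of the most frequent non-reference base divided by depth)
#'   >= `min_variant_freq` (default 0.2);
#' * **sequencing error** — otherwise, depth >= `error_min_coverage`
#'   (default 10) and exactly one deviating read observation at the site;
#' * **none** — otherwise.
#'
#' The two rules are mutually exclusive by construction: one deviating read
#' at depth >= 10 caps the variant frequency at 0.1 < 0.2. "One single
#' deviating nucleotide" is read as one deviating read observation, not one
#' deviating base type — the reading that makes the rules disjoint. Sites
#' with depth 5–9 and a single deviating read fall between the rules and are
#' classified `none`.
#'
#' @param pileup Pileup tibble from [build_pileup()].
#' @param min_coverage Minimum depth for SNP calling.
#' @param min_variant_freq Minimum variant frequency for SNP calling.
#' @param error_min_coverage Minimum depth for the sequencing-error rule.
#' @return `pileup` with added columns `variant_frequency`,
#'   `deviating_count` and `klass`
#'   (`"SNP"`, `"sequencing_error"` or `"none"`).
#' @export
classify_sites <- function(pileup, min_coverage = 5L, min_variant_freq = 0.2,
                           error_min_coverage = 10L) {
  bases <- c("A", "C", "G", "T", "N")
  counts <- as.matrix(pileup[bases])
  ref_idx <- match(pileup$ref, bases)
  ref_count <- counts[cbind(seq_len(nrow(counts)), ref_idx)]
  ref_count[is.na(ref_count)] <- 0L  # reference base outside ACGTN
  alt <- counts
  alt[cbind(seq_len(nrow(alt)), ref_idx)] <- 0L
  max_alt <- apply(alt, 1L, max)
  deviating <- pileup$depth - ref_count
  vf <- ifelse(pileup$depth > 0L, max_alt / pileup$depth, 0)
  klass <- ifelse(
    pileup$depth >= min_coverage & vf >= min_variant_freq, "SNP",
    ifelse(pileup$depth >= error_min_coverage & deviating == 1L,
           "sequencing_error", "none")
  )
  dplyr::mutate(pileup, variant_frequency = vf,
                deviating_count = as.integer(deviating), klass = klass)
}

#' SNP and sequencing-error rates from classified sites
#'
#' @param calls Classified pileup from [classify_sites()].
#' @param aligned_reference_bp Denominator in bp. The natural choice is the
#'   number of reference positions with depth >= 1 (see
#'   [gene_depth_summary()]); pass a different denominator to change the
#'   convention.
#' @return One-row tibble: `n_snps`, `n_errors`, `snps_per_kb`
#'   (1000 * SNP sites / denominator), `error_rate_percent`
#'   (100 * error sites / denominator).
#' @export
variant_rates <- function(calls, aligned_reference_bp) {
  stopifnot(aligned_reference_bp >= 1)
  n_snps <- sum(calls$klass == "SNP")
  n_errors <- sum(calls$klass == "sequencing_error")
  tibble::tibble(
    n_snps = n_snps,
    n_errors = n_errors,
    snps_per_kb = 1000 * n_snps / aligned_reference_bp,
    error_rate_percent = 100 * n_errors / aligned_reference_bp
  )
}
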