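#' Direct contig assessment against a trusted reference gene set
#'
#' Aligns every contig against every reference gene with the internal local
#' aligner, keeps the best alignment per (contig, gene) pair passing the
#' E-value cutoff, and aggregates the summary statistics used to compare
#' assemblies directly: hit count, average total and aligned contig lengths,
#' counts of contigs exceeding identity thresholds, and merged per-gene
#' coverage.
#'
#' @param contigs Contig tibble (`id`, `seq`).
#' @param genes Reference gene tibble (`id`, `seq`); non-empty.
#' @param max_evalue Strict E-value cutoff (default 1e-5).
#' @param scheme A [scoring_scheme()].
#' @return An object of class `gene_assessment`: a list with
#'   * `hits` — one row per passing (contig, gene) pair: `contig_id`,
#'     `gene_id`, `contig_length`, `gene_length`, `aligned_length`,
#'     `identities`, `pident`, `evalue`, `score`, contig and gene intervals
#'     (`c_start`, `c_end`, `g_start`, `g_end`, 0-based half-open), `ratio`
#'     (aligned contig span / total contig length) and the `q_inserts`
#'     list-column from the aligner;
#'   * `summary` — one-row tibble: `total_hits`, `avg_total_contig_length`,
#'     `avg_aligned_length`, `n_identity_gt80`, `n_identity_100`,
#'     `summed_aligned_coverage`, `avg_fraction_per_gene`;
#'   * `genes`, `max_evalue` — the inputs needed by downstream helpers.
#'
#'   `total_hits` counts (contig, gene) pairs; the identity counts count
#'   distinct contigs (strictly > 80%, and exactly 100%). Use [tidy()] for
#'   the hits and [glance()] for the summary.
#' @export
assess_against_genes <- function(contigs, genes, max_evalue = 1e-5,
                                 scheme = scoring_scheme()) {
  stopifnot(nrow(genes) >= 1L)
  aln <- align_contigs(contigs, genes, scheme = scheme,
                       max_evalue = max_evalue)
  hits <- tibble::tibble(
    contig_id = aln$query_id,
    gene_id = aln$subject_id,
    contig_length = aln$query_length,
    gene_length = aln$subject_length,
    aligned_length = aln$aligned_length,
    identities = aln$identities,
    pident = aln$pident,
    evalue = aln$evalue,
    score = aln$score,
    c_start = aln$q_start,
    c_end = aln$q_end,
    g_start = aln$s_start,
    g_end = aln$s_end,
    ratio = (aln$q_end - aln$q_start) / aln$query_length,
    q_inserts = aln$q_inserts
  )
  structure(
    list(
      hits = hits,
      summary = assessment_summary(hits, genes),
      genes = genes,
      max_evalue = max_evalue
    ),
    class = "gene_assessment"
  )
}

assessment_summary <- function(hits, genes) {
  per_contig <- if (nrow(hits) == 0L) {
    tibble::tibble(contig_id = character(), best_pident = double())
  } else {
    hits |>
      dplyr::group_by(.data$contig_id) |>
      dplyr::summarise(best_pident = max(.data$pident), .groups = "drop")
  }
  cov <- per_gene_coverage(hits, genes)
  tibble::tibble(
    total_hits = nrow(hits),
    avg_total_contig_length = if (nrow(hits)) mean(hits$contig_length) else 0,
    avg_aligned_length = if (nrow(hits))
      mean(hits$c_end - hits$c_start) else 0,
    n_identity_gt80 = sum(per_contig$best_pident > 80),
    n_identity_100 = sum(per_contig$best_pident == 100),
    summed_aligned_coverage = sum(cov$covered_bp),
    avg_fraction_per_gene = mean(cov$fraction_covered)
  )
}

#' @exportS3Method generics::tidy
tidy.gene_assessment <- function(x, ...) x$hits

#' @exportS3Method generics::glance
glance.gene_assessment <- function(x, ...) x$summary

#' @export
print.gene_assessment <- function(x, ...) {
  cat("<gene_assessment> ", nrow(x$hits), " hits against ",
      nrow(x$genes), " reference genes (E < ",
      format(x$max_evalue), ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Per-gene coverage from merged alignment intervals
#'
#' For each reference gene, hit intervals on the gene (optionally restricted
#' to hits with identity strictly above `min_identity`) are merged and the
#' union length is reported as covered bp.
#'
#' @param hits Hit tibble with `gene_id`, `g_start`, `g_end` (0-based
#'   half-open) and `pident` columns (e.g. `tidy()` of a `gene_assessment`).
#' @param genes Reference gene tibble (`id`, `seq`), or a tibble with `id`
#'   and `length` columns.
#' @param min_identity If not `NULL`, keep only hits with
#'   `pident > min_identity` before merging (e.g. 80).
#' @return One row per gene (every gene in `genes`, covered or not):
#'   `gene_id`, `gene_length`, `covered_bp`, `fraction_covered`,
#'   `contributing_contigs`.
#' @export
per_gene_coverage <- function(hits, genes, min_identity = NULL) {
  gene_len <- gene_length_lookup(genes)
  if (!is.null(min_identity)) {
    hits <- hits[hits$pident > min_identity, , drop = FALSE]
  }
  if (nrow(hits) > 0 &&
      any(hits$g_end > gene_len[hits$gene_id] | hits$g_start < 0)) {
    stop("hit interval exceeds gene bounds")
  }
  per_gene <- lapply(names(gene_len), function(g) {
    h <- hits[hits$gene_id == g, , drop = FALSE]
    covered <- merged_interval_length(h$g_start, h$g_end)
    tibble::tibble(
      gene_id = g,
      gene_length = unname(gene_len[g]),
      covered_bp = covered,
      fraction_covered = covered / unname(gene_len[g]),
      contributing_contigs = length(unique(h$contig_id))
    )
  })
  dplyr::bind_rows(per_gene)
}

gene_length_lookup <- function(genes) {
  if ("length" %in% names(genes)) {
    stats::setNames(as.integer(genes$length), genes$id)
  } else {
    stats::setNames(nchar(genes$seq), genes$id)
  }
}

# Union length of 0-based half-open intervals.
merged_interval_length <- function(start, end) {
  if (length(start) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start + 1L, end))))
}

#' Pooled coverage across several assemblies
#'
#' Merges the gene intervals of all assemblies' hits together and reports
#' the pooled fraction of the reference covered: total union bp across genes
#' divided by total gene bp. Pooling shows how much reference sequence is
#' recovered by at least one assembly even when each individual assembly
#' misses parts the others found.
#'
#' @param hit_sets A list of hit tibbles (as in [per_gene_coverage()]), one
#'   per assembly; a single hit tibble is also accepted.
#' @param genes Reference gene tibble.
#' @param min_identity Optional strict identity filter applied to every hit
#'   set before merging.
#' @return The pooled covered fraction, a number in \[0, 1\].
#' @export
pooled_coverage <- function(hit_sets, genes, min_identity = NULL) {
  if (is.data.frame(hit_sets)) hit_sets <- list(hit_sets)
  stopifnot(length(hit_sets) >= 1L)
  pooled <- dplyr::bind_rows(lapply(hit_sets, function(h) {
    h[c("contig_id", "gene_id", "g_start", "g_end", "pident")]
  }))
  cov <- per_gene_coverage(pooled, genes, min_identity = min_identity)
  sum(cov$covered_bp) / sum(cov$gene_length)
}

#' Flag putative chimeric contigs
#'
#' A chimeric contig — two unrelated sequences incorrectly joined — shows up
#' against a trusted reference as a hit with a strong E-value but an aligned
#' span that is only a small fraction of the contig: one half aligns
#' convincingly, the other half belongs elsewhere. A hit is flagged when
#' both `ratio <= max_ratio` and `evalue <= max_evalue` hold.
#'
#' @param hits Hit tibble with `contig_id`, `gene_id`, `ratio`, `evalue`.
#' @param max_ratio Maximum aligned-span fraction of the contig (default
#'   0.5).
#' @param max_evalue Maximum E-value for the alignment to count as strong
#'   (default 1e-20); note this is far more stringent than the hit-inclusion
#'   cutoff.
#' @return Defect-flag tibble: `contig_id`, `kind` (`"chimera_outlier"`),
#'   `gene_id`, `ratio`, `evalue`, `evidence`.
#' @export
flag_chimera_outliers <- function(hits, max_ratio = 0.5,
                                  max_evalue = 1e-20) {
  flagged <- hits[hits$ratio <= max_ratio & hits$evalue <= max_evalue, ,
                  drop = FALSE]
  tibble::tibble(
    contig_id = flagged$contig_id,
    kind = rep("chimera_outlier", nrow(flagged)),
    gene_id = flagged$gene_id,
    ratio = flagged$ratio,
    evalue = flagged$evalue,
    evidence = sprintf(
      "strong hit to %s (E=%.3g) covers only %.0f%% of contig",
      flagged$gene_id, flagged$evalue, 100 * flagged$ratio
    )
  )
}

#' Classify unaligned contig regions and detect adapter extensions
#'
#' For each hit, the contig sequence not covered by the alignment is split
#' into maximal segments of at least `min_segment` bp and labelled by
#' position: segments touching the contig's 5' or 3' end are `end_mismatch`,
#' segments strictly inside the aligned span (query-only gaps) are
#' `internal_mismatch`. End segments are then aligned against each adapter
#' sequence; a local alignment with at least `adapter_min_identity` percent
#' identity over at least `adapter_min_length` bp upgrades the flag to
#' `adapter_extension` (the 20–30 bp adapter remains typically found at
#' contig 5' ends).
#'
#' @param contigs Contig tibble (`id`, `seq`).
#' @param hits Hit tibble from a `gene_assessment` (needs `contig_id`,
#'   `gene_id`, `c_start`, `c_end`, `contig_length`, `q_inserts`).
#' @param adapters Adapter tibble (`id`, `seq`), or `NULL` to skip adapter
#'   matching.
#' @param min_segment Minimum unaligned segment length to report (bp).
#' @param adapter_min_identity,adapter_min_length Thresholds for calling an
#'   end segment an adapter match.
#' @param scheme [scoring_scheme()] used for segment-vs-adapter alignment.
#' @return Defect-flag tibble: `contig_id`, `kind` (`end_mismatch`,
#'   `internal_mismatch` or `adapter_extension`), `gene_id`, `start`, `end`
#'   (segment, 0-based half-open on the contig), `adapter_id` (`NA` unless
#'   upgraded), `evidence`.
#' @export
classify_unaligned_regions <- function(contigs, hits, adapters = NULL,
                                       min_segment = 15L,
                                       adapter_min_identity = 90,
                                       adapter_min_length = 15L,
                                       scheme = scoring_scheme()) {
  seq_of <- stats::setNames(contigs$seq, contigs$id)
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    segs <- unaligned_segments(h, min_segment)
    if (nrow(segs) == 0L) return(NULL)
    segs$contig_id <- h$contig_id
    segs$gene_id <- h$gene_id
    segs$adapter_id <- NA_character_
    segs$evidence <- sprintf("%d bp unaligned segment [%d,%d)",
                             segs$end - segs$start, segs$start, segs$end)
    if (!is.null(adapters) && nrow(adapters) > 0L) {
      ends <- which(segs$kind == "end_mismatch")
      for (k in ends) {
        seg_seq <- substr(seq_of[[h$contig_id]], segs$start[k] + 1L,
                          segs$end[k])
        m <- best_adapter_match(seg_seq, adapters, scheme)
        if (!is.null(m) && m$pident >= adapter_min_identity &&
            m$aligned_length >= adapter_min_length) {
          segs$kind[k] <- "adapter_extension"
          segs$adapter_id[k] <- m$subject_id
          segs$evidence[k] <- sprintf(
            "%d bp end segment matches adapter %s at %.1f%% identity over %d bp",
            segs$end[k] - segs$start[k], m$subject_id, m$pident,
            m$aligned_length)
        }
      }
    }
    segs
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(contig_id = character(), kind = character(),
                          gene_id = character(), start = integer(),
                          end = integer(), adapter_id = character(),
                          evidence = character()))
  }
  out[c("contig_id", "kind", "gene_id", "start", "end", "adapter_id",
        "evidence")]
}

unaligned_segments <- function(hit, min_segment) {
  segs <- tibble::tibble(start = integer(), end = integer(),
                         kind = character())
  if (hit$c_start >= min_segment) {
    segs <- dplyr::bind_rows(segs, tibble::tibble(
      start = 0L, end = hit$c_start, kind = "end_mismatch"))
  }
  if (hit$contig_length - hit$c_end >= min_segment) {
    segs <- dplyr::bind_rows(segs, tibble::tibble(
      start = hit$c_end, end = hit$contig_length, kind = "end_mismatch"))
  }
  ins <- hit$q_inserts[[1L]]
  if (!is.null(ins) && nrow(ins) > 0L) {
    ins <- ins[ins$end - ins$start >= min_segment, , drop = FALSE]
    if (nrow(ins) > 0L) {
      segs <- dplyr::bind_rows(segs, tibble::tibble(
        start = ins$start, end = ins$end, kind = "internal_mismatch"))
    }
  }
  segs
}

best_adapter_match <- function(segment, adapters, scheme) {
  if (nchar(segment) == 0L) return(NULL)
  best <- NULL
  for (j in seq_len(nrow(adapters))) {
    aln <- smith_waterman(segment, adapters$seq[j], scheme = scheme,
                          subject_id = adapters$id[j])
    if (is.null(best) || aln$score > best$score) best <- aln
  }
  if (best$score <= 0) NULL else best
}

#' Cluster redundant contigs covering the same reference region
#'
#' Two contigs are linked when their alignment intervals on the same gene
#' overlap by strictly more than `min_overlap` bp; single-linkage connected
#' components of size >= 2 are reported as redundancy clusters. Large
#' clusters of near-identical contigs indicate under-merged assembly.
#'
#' @param hits Hit tibble with `contig_id`, `gene_id`, `g_start`, `g_end`.
#' @param min_overlap Strict overlap threshold, bp (default 30).
#' @return Tibble with one row per cluster member: `cluster_id` (integer,
#'   deterministic: clusters ordered by gene then leftmost span), `gene_id`,
#'   `contig_id`, `span_start`, `span_end` (the cluster's merged span on the
#'   gene). Singletons are excluded.
#' @export
redundancy_clusters <- function(hits, min_overlap = 30L) {
  empty <- tibble::tibble(cluster_id = integer(), gene_id = character(),
                          contig_id = character(), span_start = integer(),
                          span_end = integer())
  if (nrow(hits) == 0L) return(empty)
  clusters <- list()
  for (g in sort(unique(hits$gene_id))) {
    h <- hits[hits$gene_id == g, , drop = FALSE]
    h <- h[order(h$contig_id), , drop = FALSE]
    n <- nrow(h)
    if (n < 2L) next
    ov <- outer(h$g_end, h$g_end, pmin) - outer(h$g_start, h$g_start, pmax)
    pairs <- which(ov > min_overlap, arr.ind = TRUE)
    pairs <- pairs[pairs[, 1L] < pairs[, 2L], , drop = FALSE]
    if (nrow(pairs) == 0L) next
    gr <- igraph::graph_from_edgelist(
      cbind(h$contig_id[pairs[, 1L]], h$contig_id[pairs[, 2L]]),
      directed = FALSE
    )
    comp <- igraph::components(gr)
    for (cid in seq_len(comp$no)) {
      members <- names(comp$membership)[comp$membership == cid]
      hm <- h[h$contig_id %in% members, , drop = FALSE]
      clusters[[length(clusters) + 1L]] <- tibble::tibble(
        gene_id = g,
        contig_id = sort(unique(members)),
        span_start = min(hm$g_start),
        span_end = max(hm$g_end)
      )
    }
  }
  if (length(clusters) == 0L) return(empty)
  ord <- order(vapply(clusters, function(x) x$gene_id[1L], character(1L)),
               vapply(clusters, function(x) x$span_start[1L], integer(1L)))
  out <- dplyr::bind_rows(lapply(seq_along(ord), function(i) {
    dplyr::mutate(clusters[[ord[i]]], cluster_id = i)
  }))
  out[c("cluster_id", "gene_id", "contig_id", "span_start", "span_end")]
}
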