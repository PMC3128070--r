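#' Multi-assembly comparison report
#'
#' Runs the full quality-assessment battery over one or more contig sets and
#' collects every section into a single object: length statistics (all
#' contigs and the > `min_contig_length` bp class), hit counts and UniGen
#' counts at the moderate and stringent E-value cutoffs, the pairwise
#' shared-UniGen matrix (stringent cutoff, long contigs only), the direct
#' per-assembly assessment against the reference genes, pooled coverage,
#' defect flags (chimera outliers, unaligned-region/adapter flags,
#' redundancy clusters) and a microsatellite tally. When reads and their
#' alignments are supplied, a variant section (pileup classification and
#' SNP/error rates) is added.
#'
#' @param assemblies Named list of contig tibbles (`id`, `seq`).
#' @param genes Reference gene tibble (`id`, `seq`).
#' @param adapters Adapter tibble, or `NULL` to skip adapter matching.
#' @param reads Optional read tibble (see [simulate_reads()]); trimmed with
#'   [trim_reads()] before pileup.
#' @param read_alignments Optional gapless read-to-gene alignments matching
#'   `reads` (see [simulate_reads()] truth).
#' @param evalue_a,evalue_b Moderate and stringent E-value cutoffs.
#' @param min_contig_length Strict length threshold for the long-contig
#'   class, bp.
#' @param min_identity Strict identity threshold for the high-identity
#'   coverage table, percent.
#' @param chimera_max_ratio,chimera_max_evalue See
#'   [flag_chimera_outliers()].
#' @param cluster_min_overlap See [redundancy_clusters()].
#' @param scheme A [scoring_scheme()].
#' @return An `assembly_report`: a list of tibbles
#'   (`length_stats`, `hit_counts`, `shared_unigenes`, `assessment`,
#'   `per_gene_coverage`, `defects`, `clusters`, `repeats`, `variants`,
#'   `depth`), plus `pooled_coverage` (scalar) and `params`.
#' @export
run_report <- function(assemblies, genes, adapters = illumina_adapters(),
                       reads = NULL, read_alignments = NULL,
                       evalue_a = 1e-5, evalue_b = 1e-10,
                       min_contig_length = 200L, min_identity = 80,
                       chimera_max_ratio = 0.5, chimera_max_evalue = 1e-20,
                       cluster_min_overlap = 30L,
                       scheme = scoring_scheme()) {
  stopifnot(length(assemblies) >= 1L, !is.null(names(assemblies)),
            all(names(assemblies) != ""))
  names_a <- names(assemblies)

  length_stats_tbl <- purrr::map_dfr(names_a, function(a) {
    dplyr::bind_rows(
      dplyr::mutate(length_stats(assemblies[[a]]), class = "all"),
      dplyr::mutate(length_stats(assemblies[[a]], min_contig_length),
                    class = paste0(">", min_contig_length, "bp"))
    ) |>
      dplyr::mutate(assembly = a, .before = 1L)
  })

  assessments <- lapply(assemblies, assess_against_genes, genes = genes,
                        max_evalue = evalue_a, scheme = scheme)

  hit_counts <- purrr::map_dfr(names_a, function(a) {
    h <- assessments[[a]]$hits
    h_generic <- tibble::tibble(
      query_id = h$contig_id, subject_id = h$gene_id, evalue = h$evalue,
      bitscore = h$score, query_length = h$contig_length)
    count_block <- function(hits, cutoff) {
      kept <- filter_hits(hits, cutoff)
      kept_long <- filter_hits(hits, cutoff,
                               min_query_length = min_contig_length)
      tibble::tibble(
        max_evalue = cutoff,
        n_hits = nrow(kept),
        n_unigenes = nrow(unigene_reduce(kept)),
        n_unigenes_long = nrow(unigene_reduce(kept_long))
      )
    }
    dplyr::bind_rows(count_block(h_generic, evalue_a),
                     count_block(h_generic, evalue_b)) |>
      dplyr::mutate(assembly = a, .before = 1L)
  })

  shared <- purrr::map_dfr(names_a, function(a) {
    purrr::map_dfr(names_a, function(b) {
      ug <- function(x) {
        h <- assessments[[x]]$hits
        hg <- tibble::tibble(query_id = h$contig_id, subject_id = h$gene_id,
                             evalue = h$evalue, bitscore = h$score,
                             query_length = h$contig_length)
        unigene_reduce(filter_hits(hg, evalue_b,
                                   min_query_length = min_contig_length))
      }
      dplyr::mutate(shared_unigenes(ug(a), ug(b)),
                    assembly_a = a, assembly_b = b, .before = 1L)
    })
  })

  assessment_tbl <- purrr::map_dfr(names_a, function(a) {
    dplyr::mutate(glance(assessments[[a]]), assembly = a, .before = 1L)
  })

  coverage_tbl <- purrr::map_dfr(names_a, function(a) {
    dplyr::mutate(
      per_gene_coverage(assessments[[a]]$hits, genes,
                        min_identity = min_identity),
      assembly = a, .before = 1L)
  })

  pooled <- pooled_coverage(lapply(assessments, function(x) x$hits), genes)

  defects <- purrr::map_dfr(names_a, function(a) {
    hits <- assessments[[a]]$hits
    chim <- flag_chimera_outliers(hits, max_ratio = chimera_max_ratio,
                                  max_evalue = chimera_max_evalue)
    best <- hits |>
      dplyr::group_by(.data$contig_id) |>
      dplyr::slice_min(.data$evalue, n = 1L, with_ties = FALSE) |>
      dplyr::ungroup()
    seg <- classify_unaligned_regions(assemblies[[a]], best, adapters,
                                      scheme = scheme)
    dplyr::bind_rows(
      chim[c("contig_id", "kind", "gene_id", "evidence")],
      seg[c("contig_id", "kind", "gene_id", "evidence")]
    ) |>
      dplyr::mutate(assembly = a, .before = 1L)
  })

  clusters <- purrr::map_dfr(names_a, function(a) {
    dplyr::mutate(
      redundancy_clusters(assessments[[a]]$hits,
                          min_overlap = cluster_min_overlap),
      assembly = a, .before = 1L)
  })

  repeats_tbl <- purrr::map_dfr(names_a, function(a) {
    dplyr::mutate(find_microsatellites(assemblies[[a]]),
                  assembly = a, .before = 1L)
  })

  variants <- NULL
  depth <- NULL
  if (!is.null(reads) && !is.null(read_alignments)) {
    trimmed <- trim_reads(reads)
    aln <- trim_alignments(read_alignments, trimmed)
    pileup <- build_pileup(aln, genes)
    calls <- classify_sites(pileup)
    depth <- gene_depth_summary(pileup)
    variants <- variant_rates(calls, sum(depth$covered_bp))
  }

  structure(
    list(
      length_stats = length_stats_tbl,
      hit_counts = hit_counts,
      shared_unigenes = shared,
      assessment = assessment_tbl,
      per_gene_coverage = coverage_tbl,
      pooled_coverage = pooled,
      defects = defects,
      clusters = clusters,
      repeats = repeats_tbl,
      variants = variants,
      depth = depth,
      params = list(evalue_a = evalue_a, evalue_b = evalue_b,
                    min_contig_length = min_contig_length,
                    min_identity = min_identity,
                    chimera_max_ratio = chimera_max_ratio,
                    chimera_max_evalue = chimera_max_evalue,
                    cluster_min_overlap = cluster_min_overlap)
    ),
    class = "assembly_report"
  )
}

#' @export
print.assembly_report <- function(x, ...) {
  cat("<assembly_report>",
      length(unique(x$length_stats$assembly)), "assemblies\n")
  cat("\nLength statistics:\n")
  print(x$length_stats)
  cat("\nDirect assessment against reference genes:\n")
  print(x$assessment)
  cat(sprintf("\nPooled reference coverage: %.1f%%\n",
              100 * x$pooled_coverage))
  if (nrow(x$defects)) {
    cat("\nDefect flags:\n")
    print(dplyr::count(x$defects, .data$assembly, .data$kind))
  }
  if (!is.null(x$variants)) {
    cat("\nVariant rates:\n")
    print(x$variants)
  }
  invisible(x)
}

#' Write an assembly report to disk
#'
#' Each tabular section is written as a TSV and the whole report (minus
#' list-columns) as a single JSON document, the machine-readable record.
#'
#' @param report An `assembly_report` from [run_report()].
#' @param dir Output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "assembly_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sections <- c("length_stats", "hit_counts", "shared_unigenes",
                "assessment", "per_gene_coverage", "defects", "clusters",
                "repeats", "variants", "depth")
  paths <- character()
  json <- list(pooled_coverage = report$pooled_coverage,
               params = report$params)
  for (s in sections) {
    tbl <- report[[s]]
    if (is.null(tbl)) next
    p <- file.path(dir, paste0(s, ".tsv"))
    readr::write_tsv(tbl, p, progress = FALSE)
    paths <- c(paths, p)
    json[[s]] <- tbl
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(json, jp, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(paths, jp))
}
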