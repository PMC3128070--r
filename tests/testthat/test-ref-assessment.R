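make_genes <- function(...) {
  seqs <- c(...)
  tibble::tibble(id = sprintf("g%d", seq_along(seqs)), seq = seqs)
}

test_that("an exact gene copy yields one full-identity hit", {
  set.seed(41)
  genes <- make_genes(random_seq(400), random_seq(400))
  contigs <- tibble::tibble(id = "c1", seq = genes$seq[1])
  a <- assess_against_genes(contigs, genes)
  expect_equal(nrow(a$hits), 1L)
  expect_equal(a$hits$pident, 100)
  expect_equal(a$hits$ratio, 1)
  g <- glance(a)
  expect_equal(g$total_hits, 1L)
  expect_equal(g$n_identity_100, 1L)
  expect_equal(g$n_identity_gt80, 1L)
  expect_equal(g$avg_total_contig_length, 400)
})

test_that("contigs without passing alignments give a zeroed summary", {
  set.seed(42)
  genes <- make_genes(random_seq(300))
  contigs <- tibble::tibble(id = "c1", seq = random_seq(250))
  a <- assess_against_genes(contigs, genes)
  expect_equal(nrow(a$hits), 0L)
  expect_equal(glance(a)$total_hits, 0L)
  expect_equal(glance(a)$summed_aligned_coverage, 0L)
  b <- assess_against_genes(contigs[0, ], genes)
  expect_equal(glance(b)$total_hits, 0L)
})

test_that("per_gene_coverage merges overlapping intervals", {
  genes <- tibble::tibble(id = "g1", length = 100L)
  hits <- tibble::tibble(
    contig_id = c("a", "b"), gene_id = "g1",
    g_start = c(0L, 40L), g_end = c(50L, 90L), pident = c(95, 95)
  )
  cov <- per_gene_coverage(hits, genes)
  expect_equal(cov$covered_bp, 90L)
  expect_equal(cov$fraction_covered, 0.9)
  expect_equal(cov$contributing_contigs, 2L)

  none <- per_gene_coverage(hits[0, ], genes)
  expect_equal(none$covered_bp, 0L)
  expect_error(
    per_gene_coverage(dplyr::mutate(hits, g_end = 200L), genes),
    "bounds"
  )
})

test_that("per_gene_coverage equals a boolean-array oracle on random sets", {
  set.seed(43)
  for (i in 1:500) {
    glen <- sample(50:400, 1)
    n <- sample(0:12, 1)
    start <- integer(n); end <- integer(n)
    if (n > 0) {
      start <- sample(0:(glen - 1), n, replace = TRUE)
      end <- pmin(glen, start + sample(1:80, n, replace = TRUE))
    }
    hits <- tibble::tibble(contig_id = sprintf("c%d", seq_len(n)),
                           gene_id = "g1", g_start = start, g_end = end,
                           pident = 100)
    got <- per_gene_coverage(hits, tibble::tibble(id = "g1", length = glen))
    expect_equal(got$covered_bp, coverage_oracle(start, end, glen))
  }
})

test_that("identity filtering never increases coverage", {
  set.seed(44)
  glen <- 300L
  hits <- tibble::tibble(
    contig_id = sprintf("c%d", 1:20), gene_id = "g1",
    g_start = sample(0:250, 20, replace = TRUE),
    pident = runif(20, 60, 100)
  )
  hits$g_end <- pmin(glen, hits$g_start + sample(20:120, 20, replace = TRUE))
  genes <- tibble::tibble(id = "g1", length = glen)
  all_cov <- per_gene_coverage(hits, genes)$covered_bp
  hi_cov <- per_gene_coverage(hits, genes, min_identity = 80)$covered_bp
  expect_lte(hi_cov, all_cov)
})

test_that("pooled coverage unions assemblies and dominates each one", {
  genes <- tibble::tibble(id = "g1", length = 100L)
  left <- tibble::tibble(contig_id = "a", gene_id = "g1", g_start = 0L,
                         g_end = 50L, pident = 100)
  right <- tibble::tibble(contig_id = "b", gene_id = "g1", g_start = 50L,
                          g_end = 100L, pident = 100)
  expect_equal(pooled_coverage(list(left, right), genes), 1)
  # pooling a set with itself changes nothing
  expect_equal(pooled_coverage(list(left, left), genes),
               pooled_coverage(left, genes))

  set.seed(45)
  sets <- lapply(1:4, function(i) {
    n <- sample(3:10, 1)
    s <- sample(0:90, n, replace = TRUE)
    tibble::tibble(contig_id = sprintf("s%d_%d", i, seq_len(n)),
                   gene_id = "g1", g_start = s,
                   g_end = pmin(100L, s + sample(5:40, n, replace = TRUE)),
                   pident = 100)
  })
  pooled <- pooled_coverage(sets, genes)
  indiv <- vapply(sets, pooled_coverage, numeric(1), genes = genes)
  expect_gte(pooled, max(indiv))
  all_s <- unlist(lapply(sets, `[[`, "g_start"))
  all_e <- unlist(lapply(sets, `[[`, "g_end"))
  expect_equal(pooled, coverage_oracle(all_s, all_e, 100L) / 100)
})

test_that("chimera flagging requires both a short ratio and a strong E-value", {
  hits <- tibble::tibble(
    contig_id = c("good", "weak_short", "strong_short"),
    gene_id = "g1",
    ratio = c(1.0, 0.1, 0.45),
    evalue = c(1e-60, 1e-6, 1e-50)
  )
  flags <- flag_chimera_outliers(hits, max_ratio = 0.5, max_evalue = 1e-20)
  expect_equal(flags$contig_id, "strong_short")
  expect_equal(flags$kind, "chimera_outlier")
  # every flag satisfies both configured conditions exactly
  expect_true(all(flags$ratio <= 0.5 & flags$evalue <= 1e-20))
})

test_that("unaligned regions are classified by position and adapter content", {
  set.seed(46)
  gene <- random_seq(400)
  genes <- tibble::tibble(id = "g1", seq = gene)
  adapters <- illumina_adapters()
  contigs <- tibble::tibble(
    id = c("with_adapter", "full", "with_insert"),
    seq = c(paste0(substr(adapters$seq[1], 1, 25), gene),
            gene,
            paste0(substr(gene, 1, 200), random_seq(50),
                   substr(gene, 201, 400)))
  )
  a <- assess_against_genes(contigs, genes)
  flags <- classify_unaligned_regions(contigs, a$hits, adapters)
  ad <- flags[flags$contig_id == "with_adapter", ]
  expect_equal(ad$kind, "adapter_extension")
  expect_equal(ad$adapter_id, "illumina_pe_1")
  expect_equal(ad$start, 0L)
  expect_false("full" %in% flags$contig_id)
  ins <- flags[flags$contig_id == "with_insert", ]
  expect_equal(ins$kind, "internal_mismatch")
  expect_equal(ins$end - ins$start, 50L)
})

test_that("redundancy clustering is single-linkage with a strict overlap", {
  hits <- tibble::tibble(
    contig_id = c("a", "b", "c"), gene_id = "g1",
    g_start = c(0L, 50L, 100L), g_end = c(100L, 150L, 200L)
  )
  cl <- redundancy_clusters(hits, min_overlap = 30)
  expect_equal(sort(cl$contig_id), c("a", "b", "c"))
  expect_equal(unique(cl$cluster_id), 1L)
  expect_equal(unique(cl$span_start), 0L)
  expect_equal(unique(cl$span_end), 200L)

  # an overlap of exactly min_overlap does not link
  pair <- tibble::tibble(contig_id = c("a", "b"), gene_id = "g1",
                         g_start = c(0L, 70L), g_end = c(100L, 200L))
  expect_equal(nrow(redundancy_clusters(pair, min_overlap = 30)), 0L)
  expect_equal(nrow(redundancy_clusters(pair, min_overlap = 29)), 2L)
})

test_that("cluster membership is invariant under input order", {
  set.seed(47)
  hits <- tibble::tibble(
    contig_id = sprintf("c%02d", 1:30),
    gene_id = sample(c("g1", "g2"), 30, replace = TRUE),
    g_start = sample(0:500, 30, replace = TRUE)
  )
  hits$g_end <- hits$g_start + sample(40:150, 30, replace = TRUE)
  a <- redundancy_clusters(hits)
  b <- redundancy_clusters(hits[sample.int(30), ])
  expect_equal(a, b)
})

test_that("tidy and glance expose the assessment hits and summary", {
  sc <- default_scenario()
  a <- sc$assessment
  expect_s3_class(tidy(a), "tbl_df")
  expect_equal(nrow(glance(a)), 1L)
  expect_true(glance(a)$n_identity_100 <= glance(a)$n_identity_gt80)
  expect_true(glance(a)$n_identity_gt80 <= glance(a)$total_hits)
  # aligned span never exceeds the contig
  expect_true(all(tidy(a)$ratio > 0 & tidy(a)$ratio <= 1))
})
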