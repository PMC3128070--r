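test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 99, n_genes = 8L, n_mt_like = 5L,
                    n_ribosomal = 1L, n_redundancy_clusters = 1L,
                    n_chimeras = 1L, n_adapter_extensions = 1L,
                    mean_depth = 10)
  g1 <- make_transcriptome(cfg)
  g2 <- make_transcriptome(cfg)
  expect_identical(g1, g2)
  r1 <- simulate_reads(g1, cfg)
  r2 <- simulate_reads(g2, cfg)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth, r2$truth)
  a1 <- simulate_assembly(g1, cfg)
  a2 <- simulate_assembly(g1, cfg)
  expect_identical(a1, a2)
})

test_that("reference-subset flags cover the requested gene counts", {
  cfg <- sim_config(n_genes = 13L, n_mt_like = 13L, n_ribosomal = 0L)
  g <- make_transcriptome(cfg)
  expect_true(all(g$mt_like))
  cfg2 <- sim_config(n_genes = 20L, n_mt_like = 13L, n_ribosomal = 2L)
  g2 <- make_transcriptome(cfg2)
  expect_equal(sum(g2$mt_like), 13L)
  expect_equal(sum(g2$ribosomal), 2L)
  expect_false(any(g2$mt_like & g2$ribosomal))
})

test_that("base composition matches the configured GC content", {
  cfg <- sim_config(seed = 5, n_genes = 100L, n_mt_like = 10L,
                    gene_length_range = c(1000L, 1000L))
  g <- make_transcriptome(cfg)
  all_bases <- paste(g$seq, collapse = "")
  gc <- sum(strsplit(all_bases, "")[[1]] %in% c("G", "C")) /
    nchar(all_bases)
  expect_lt(abs(gc - 0.5), 0.01)
})

test_that("error-free reads are exact substrings of one haplotype", {
  cfg <- sim_config(seed = 6, n_genes = 4L, n_mt_like = 4L,
                    n_ribosomal = 0L, per_base_error = 0,
                    b_tail_prob = 0, adapter_readthrough_prob = 0,
                    mean_depth = 5)
  genes <- make_transcriptome(cfg)
  sim <- simulate_reads(genes, cfg)
  expect_equal(nrow(sim$truth$errors), 0L)
  hap2 <- genes$seq
  for (i in seq_len(nrow(genes))) {
    snp <- sim$truth$snps[sim$truth$snps$gene_id == genes$id[i], ]
    s <- strsplit(hap2[i], "")[[1]]
    s[snp$pos + 1] <- snp$alt
    hap2[i] <- paste(s, collapse = "")
  }
  aln <- sim$truth$alignments
  gene_seq <- stats::setNames(genes$seq, genes$id)
  hap2_seq <- stats::setNames(hap2, genes$id)
  ok <- vapply(seq_len(nrow(aln)), function(i) {
    ref1 <- substr(gene_seq[aln$gene_id[i]], aln$g_start[i] + 1,
                   aln$g_start[i] + aln$aligned_len[i])
    ref2 <- substr(hap2_seq[aln$gene_id[i]], aln$g_start[i] + 1,
                   aln$g_start[i] + aln$aligned_len[i])
    aln$bases[i] == ref1 || aln$bases[i] == ref2
  }, logical(1))
  expect_true(all(ok))
})

test_that("the observed substitution rate matches the configured rate", {
  cfg <- sim_config(seed = 8, n_genes = 10L, n_mt_like = 10L,
                    n_ribosomal = 0L, per_base_error = 0.002,
                    b_tail_prob = 0, adapter_readthrough_prob = 0,
                    mean_depth = 50)
  genes <- make_transcriptome(cfg)
  sim <- simulate_reads(genes, cfg)
  total_bases <- sum(sim$truth$alignments$aligned_len)
  expect_gt(total_bases, 4e5)
  n_err <- nrow(sim$truth$errors)
  expected <- total_bases * 0.002
  sd3 <- 3 * sqrt(total_bases * 0.002 * 0.998)
  expect_lt(abs(n_err - expected), sd3)
})

test_that("planted SNP positions never collide with injected errors", {
  sc <- default_scenario()
  snp_key <- paste(sc$sim$truth$snps$gene_id, sc$sim$truth$snps$pos)
  err_key <- paste(sc$sim$truth$errors$gene_id,
                   sc$sim$truth$errors$gene_pos)
  expect_length(intersect(snp_key, err_key), 0L)
})

test_that("truth labels partition the contig set", {
  sc <- default_scenario()
  expect_setequal(sc$truth$contig_id, sc$contigs$id)
  expect_equal(anyDuplicated(sc$truth$contig_id), 0L)
  chim <- sc$truth[sc$truth$label == "chimera", ]
  lens <- stats::setNames(nchar(sc$contigs$seq), sc$contigs$id)
  expect_true(all(chim$breakpoint > 0 &
                    chim$breakpoint < lens[chim$contig_id]))
  ext <- sc$truth[sc$truth$label == "adapter_extension", ]
  expect_true(all(ext$ext_length >= 20 & ext$ext_length <= 30))
})

test_that("a defect-free configuration reproduces the genes exactly", {
  cfg <- sim_config(seed = 9, n_genes = 6L, n_mt_like = 6L,
                    n_ribosomal = 0L, fragmentation_level = 0,
                    n_redundancy_clusters = 0L, n_chimeras = 0L,
                    n_adapter_extensions = 0L)
  genes <- make_transcriptome(cfg)
  asm <- simulate_assembly(genes, cfg)
  expect_equal(nrow(asm$contigs), 6L)
  expect_setequal(asm$contigs$seq, genes$seq)
  expect_true(all(asm$truth$label == "clean"))
})

test_that("defect demands beyond the gene budget are rejected", {
  cfg <- sim_config(n_genes = 5L, n_mt_like = 5L, n_ribosomal = 0L,
                    n_redundancy_clusters = 2L, n_chimeras = 2L,
                    n_adapter_extensions = 2L)
  genes <- make_transcriptome(cfg)
  expect_error(simulate_assembly(genes, cfg), "genes")
})

test_that("reads flagged with B tails are shortened by quality trimming", {
  sc <- default_scenario()
  tails <- sc$sim$truth$artifacts$read_id[
    sc$sim$truth$artifacts$artifact == "b_tail"]
  expect_gt(length(tails), 0L)
  trimmed <- trim_reads(sc$sim$reads)
  before <- stats::setNames(nchar(sc$sim$reads$seq), sc$sim$reads$id)
  after <- stats::setNames(nchar(trimmed$seq), trimmed$id)
  surviving <- intersect(tails, trimmed$id)
  expect_true(all(after[surviving] < before[surviving]))
})

test_that("trimming propagates to alignments on both strands", {
  aln <- tibble::tibble(
    read_id = c("fwd", "rev"),
    gene_id = "g1",
    g_start = c(10L, 10L),
    strand = c("+", "-"),
    bases = c("ACGTTGCAAT", "ACGTTGCAAT"),
    aligned_len = 10L,
    read_len = 10L
  )
  # both reads trimmed to 6 bases
  reads <- tibble::tibble(id = c("fwd", "rev"),
                          seq = c("ACGTTG", "ATTGCA"))
  out <- trim_alignments(aln, reads)
  fwd <- out[out$read_id == "fwd", ]
  expect_equal(fwd$bases, "ACGTTG")     # keeps the left end of the interval
  expect_equal(fwd$g_start, 10L)
  rev <- out[out$read_id == "rev", ]
  expect_equal(rev$bases, "TGCAAT")     # keeps the right end of the interval
  expect_equal(rev$g_start, 14L)
  # a discarded read drops out entirely
  out2 <- trim_alignments(aln, reads[1, ])
  expect_equal(out2$read_id, "fwd")
})
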