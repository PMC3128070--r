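#' Standard Illumina paired-end adapter sequences
#'
#' The two adapter read-through sequences searched for in contig ends.
#' Replace with your own tibble (`id`, `seq`) for other library chemistries.
#'
#' @return Adapter tibble (`id`, `seq`).
#' @export
illumina_adapters <- function() {
  tibble::tibble(
    id = c("illumina_pe_1", "illumina_pe_2"),
    seq = c("AGATCGGAAGAGCGGTTCAGCAGGAATGCCGAGACCG",
            "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTAGAT")
  )
}

#' Configuration for the synthetic data generator
#'
#' Bundles every knob of the simulated study: a small transcriptome with a
#' mitochondrial-like reference subset and ribosomal-flagged genes, 2x101 bp
#' paired-end reads from two pooled haplotypes with planted SNPs,
#' substitution sequencing errors, low-quality 'B' tails and occasional
#' adapter read-through, and an assembly with planted fragmentation,
#' redundancy clusters, chimeras and 5' adapter extensions. Defaults are
#' sized for desk-scale runs (a full pipeline pass in well under two
#' minutes) while keeping the study's rates: 6.3 SNPs/kb from pooled
#' haplotypes, a 0.6% per-reference-bp sequencing-error site rate, 20–30 bp
#' adapter extensions and redundancy clusters of 2–25 members.
#'
#' `per_base_error` is the per-read-base substitution probability. When
#' `NULL` (default) it is derived from `error_site_rate` and `mean_depth` by
#' inverting the probability that a site of that depth shows exactly one
#' deviating read — so the planted error process reproduces the configured
#' error-*site* rate, which is what the pileup classifier estimates. Set it
#' explicitly to control the raw per-base rate instead.
#'
#' @param seed Integer seed; all generator functions are deterministic given
#'   the config.
#' @param n_genes,gene_length_range,gc Transcriptome size and composition.
#' @param n_mt_like Genes flagged as the trusted mt-like reference subset.
#' @param n_ribosomal Genes flagged ribosomal (normalization check).
#' @param read_length,insert_min,insert_max Read geometry, bp; insert
#'   lengths are drawn strictly above `insert_min`.
#' @param mean_depth Target mean read depth over a gene.
#' @param error_site_rate Expected fraction of covered reference sites
#'   showing exactly one deviating read (the observable error rate).
#' @param per_base_error Per-base substitution probability, or `NULL` to
#'   derive it from `error_site_rate` (see above).
#' @param snp_rate_per_kb Planted SNP rate on the second haplotype.
#' @param b_tail_prob Per-read probability of a low-quality 'B' tail.
#' @param b_tail_error Substitution rate inside 'B' tails.
#' @param adapter_readthrough_prob Per-fragment probability that the insert
#'   is shorter than the read so the read runs into adapter.
#' @param fragmentation_level Probability that a non-defect gene is
#'   assembled as disjoint fragments rather than one full contig.
#' @param n_redundancy_clusters,redundancy_cluster_size_range,redundancy_divergence
#'   Planted redundancy clusters: count, member-count range, member
#'   substitution divergence.
#' @param n_chimeras,chimera_segment_range Planted chimeras: count and the
#'   length range of the shorter constituent segment, bp; the other segment
#'   is drawn 1.6–2.4 times longer so that the shorter side stays well below
#'   half the contig (the diagnostic chimera signature).
#' @param n_adapter_extensions,extension_length_range Planted 5' adapter
#'   extensions: count and length range, bp.
#' @param adapters Adapter tibble used for read-through and extensions.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 20L,
                       gene_length_range = c(800L, 1200L),
                       gc = 0.5,
                       n_mt_like = 13L,
                       n_ribosomal = 2L,
                       read_length = 101L,
                       insert_min = 181L,
                       insert_max = 300L,
                       mean_depth = 50,
                       error_site_rate = 0.006,
                       per_base_error = NULL,
                       snp_rate_per_kb = 6.3,
                       b_tail_prob = 0.03,
                       b_tail_error = 0.4,
                       adapter_readthrough_prob = 0.02,
                       fragmentation_level = 0.5,
                       n_redundancy_clusters = 3L,
                       redundancy_cluster_size_range = c(2L, 25L),
                       redundancy_divergence = 0.01,
                       n_chimeras = 3L,
                       chimera_segment_range = c(150L, 250L),
                       n_adapter_extensions = 5L,
                       extension_length_range = c(20L, 30L),
                       adapters = illumina_adapters()) {
  probs <- c(gc = gc, error_site_rate = error_site_rate,
             snp = snp_rate_per_kb / 1000, b_tail_prob = b_tail_prob,
             b_tail_error = b_tail_error,
             adapter_readthrough_prob = adapter_readthrough_prob,
             fragmentation_level = fragmentation_level,
             redundancy_divergence = redundancy_divergence)
  stopifnot(all(probs >= 0 & probs <= 1),
            gene_length_range[1L] <= gene_length_range[2L],
            redundancy_cluster_size_range[1L] >= 2L,
            redundancy_cluster_size_range[1L] <=
              redundancy_cluster_size_range[2L],
            extension_length_range[1L] <= extension_length_range[2L],
            chimera_segment_range[1L] <= chimera_segment_range[2L],
            n_mt_like + n_ribosomal <= n_genes,
            insert_min < insert_max, read_length >= 20L, mean_depth > 0)
  if (is.null(per_base_error)) {
    per_base_error <- derive_per_base_error(error_site_rate, mean_depth)
  }
  stopifnot(per_base_error >= 0, per_base_error <= 1)
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         gene_length_range = as.integer(gene_length_range), gc = gc,
         n_mt_like = as.integer(n_mt_like),
         n_ribosomal = as.integer(n_ribosomal),
         read_length = as.integer(read_length),
         insert_min = as.integer(insert_min),
         insert_max = as.integer(insert_max),
         mean_depth = mean_depth, error_site_rate = error_site_rate,
         per_base_error = per_base_error,
         snp_rate_per_kb = snp_rate_per_kb, b_tail_prob = b_tail_prob,
         b_tail_error = b_tail_error,
         adapter_readthrough_prob = adapter_readthrough_prob,
         fragmentation_level = fragmentation_level,
         n_redundancy_clusters = as.integer(n_redundancy_clusters),
         redundancy_cluster_size_range =
           as.integer(redundancy_cluster_size_range),
         redundancy_divergence = redundancy_divergence,
         n_chimeras = as.integer(n_chimeras),
         chimera_segment_range = as.integer(chimera_segment_range),
         n_adapter_extensions = as.integer(n_adapter_extensions),
         extension_length_range = as.integer(extension_length_range),
         adapters = adapters),
    class = "sim_config"
  )
}

# Per-base substitution rate e such that a site of depth d shows exactly one
# deviating read with probability `site_rate`: d*e*(1-e)^(d-1) = site_rate.
derive_per_base_error <- function(site_rate, depth) {
  if (site_rate == 0) return(0)
  f <- function(e) depth * e * (1 - e)^(depth - 1) - site_rate
  stats::uniroot(f, c(1e-12, 1 / depth), tol = 1e-12)$root
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic transcriptome with flagged reference subsets
#'
#' Uniform-random gene sequences of configured lengths. The first
#' `n_mt_like` genes are flagged as the trusted mt-like reference subset and
#' the following `n_ribosomal` genes as ribosomal. Deterministic under the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return Gene tibble: `id`, `desc`, `seq`, `mt_like`, `ribosomal`.
#' @export
make_transcriptome <- function(config) {
  withr::with_seed(config$seed, {
    lens <- sample(config$gene_length_range[1L]:config$gene_length_range[2L],
                   config$n_genes, replace = TRUE)
    seqs <- vapply(lens, random_dna, character(1L), gc = config$gc)
  })
  idx <- seq_len(config$n_genes)
  mt <- idx <= config$n_mt_like
  ribo <- !mt & idx <= config$n_mt_like + config$n_ribosomal
  tibble::tibble(
    id = sprintf("gene%02d", idx),
    desc = dplyr::case_when(mt ~ "mt-like", ribo ~ "ribosomal",
                            .default = "nuclear"),
    seq = seqs,
    mt_like = mt,
    ribosomal = ribo
  )
}

#' Simulate paired-end reads from two pooled haplotypes
#'
#' Fragments are drawn uniformly along each gene with insert length strictly
#' above `insert_min`; each fragment is sequenced from both ends
#' (`read_length` bp, mate 2 reverse-complemented). Two equifrequent
#' haplotypes mimic a pool of individuals: haplotype 2 carries SNPs planted
#' at `snp_rate_per_kb`. Substitution errors are injected at
#' `per_base_error` (never on a planted SNP site, keeping the truth labels
#' disjoint), a fraction of reads receive a low-quality 'B' tail with a
#' heavily elevated error rate, and occasionally the insert is shorter than
#' the read so the 3' end runs into adapter sequence.
#'
#' @param genes Gene tibble from [make_transcriptome()] (any subset).
#' @param config A [sim_config()].
#' @return A list:
#'   * `reads` — tibble `id`, `desc`, `seq`, `qual`, `mate`, `frag_id`;
#'   * `truth` — list of tibbles: `snps` (`gene_id`, `pos`, `ref`, `alt`),
#'     `errors` (`read_id`, `gene_id`, `gene_pos`, `read_pos`, `in_b_tail`),
#'     `alignments` (`read_id`, `gene_id`, `g_start`, `strand`, `bases`
#'     reference-oriented, `aligned_len`, `read_len`), and `artifacts`
#'     (`read_id`, `artifact` in `b_tail`/`adapter_readthrough`).
#' @export
simulate_reads <- function(genes, config) {
  long_enough <- nchar(genes$seq) > config$insert_min
  if (!all(long_enough)) {
    warning("skipping ", sum(!long_enough),
            " gene(s) shorter than the minimum insert length")
    genes <- genes[long_enough, , drop = FALSE]
  }
  stopifnot(nrow(genes) > 0L)
  withr::with_seed(config$seed + 1L, simulate_reads_impl(genes, config))
}

simulate_reads_impl <- function(genes, config) {
  rl <- config$read_length
  adapter1 <- config$adapters$seq[1L]
  adapter2 <- config$adapters$seq[min(2L, nrow(config$adapters))]

  # haplotype 2: plant SNPs
  snps <- list()
  hap2 <- genes$seq
  for (i in seq_len(nrow(genes))) {
    glen <- nchar(genes$seq[i])
    n_snp <- stats::rbinom(1L, glen, config$snp_rate_per_kb / 1000)
    if (n_snp == 0L) next
    pos <- sort(sample.int(glen, n_snp))  # 1-based
    ref <- substring(genes$seq[i], pos, pos)
    alt <- vapply(ref, substitute_base, character(1L))
    s <- strsplit(hap2[i], "", fixed = TRUE)[[1L]]
    s[pos] <- alt
    hap2[i] <- paste(s, collapse = "")
    snps[[length(snps) + 1L]] <- tibble::tibble(
      gene_id = genes$id[i], pos = pos - 1L, ref = ref, alt = unname(alt))
  }
  snps <- if (length(snps)) dplyr::bind_rows(snps) else
    tibble::tibble(gene_id = character(), pos = integer(),
                   ref = character(), alt = character())

  frag_rows <- list()
  for (i in seq_len(nrow(genes))) {
    glen <- nchar(genes$seq[i])
    n_frag <- max(1L, round(config$mean_depth * glen / (2 * rl)))
    rt <- stats::runif(n_frag) < config$adapter_readthrough_prob
    ins <- integer(n_frag)
    ins[rt] <- sample((rl - 30L):(rl - 10L), sum(rt), replace = TRUE)
    ins[!rt] <- sample((config$insert_min + 1L):min(config$insert_max, glen),
                       sum(!rt), replace = TRUE)
    frag_rows[[i]] <- tibble::tibble(
      gene_idx = i, insert = ins, readthrough = rt,
      start = vapply(ins, function(x) sample.int(glen - x + 1L, 1L) - 1L,
                     integer(1L)),
      hap = sample(1:2, n_frag, replace = TRUE)
    )
  }
  frags <- dplyr::bind_rows(frag_rows)
  frags$frag_id <- sprintf("frag%06d", seq_len(nrow(frags)))

  make_mate <- function(mate) {
    alen <- pmin(rl, frags$insert)
    template <- ifelse(frags$hap == 1L, genes$seq[frags$gene_idx],
                       hap2[frags$gene_idx])
    if (mate == 1L) {
      g_start <- frags$start
      bases <- substr(template, g_start + 1L, g_start + alen)
      read <- bases
      strand <- "+"
      adapter <- adapter1
    } else {
      g_start <- frags$start + frags$insert - alen
      bases <- substr(template, g_start + 1L, g_start + alen)
      read <- revcomp(bases)
      strand <- "-"
      adapter <- adapter2
    }
    fill <- rl - alen
    read <- ifelse(fill > 0L,
                   paste0(read, substr(adapter, 1L, fill)), read)
    tibble::tibble(
      read_id = paste0(frags$frag_id, "/", mate),
      frag_id = frags$frag_id, mate = mate,
      gene_id = genes$id[frags$gene_idx],
      g_start = g_start, strand = strand,
      aligned_len = alen, read = read
    )
  }
  reads <- dplyr::bind_rows(make_mate(1L), make_mate(2L))
  reads$read_len <- nchar(reads$read)

  # substitution errors in the aligned portion, avoiding planted SNP sites
  snp_key <- paste(snps$gene_id, snps$pos)
  err_n <- stats::rbinom(nrow(reads), reads$aligned_len,
                         config$per_base_error)
  errors <- list()
  for (i in which(err_n > 0L)) {
    rpos <- sample.int(reads$aligned_len[i], err_n[i])  # 1-based on read
    gpos <- error_gene_pos(reads[i, ], rpos)
    keep <- !(paste(reads$gene_id[i], gpos) %in% snp_key)
    rpos <- rpos[keep]; gpos <- gpos[keep]
    if (length(rpos) == 0L) next
    reads$read[i] <- mutate_positions(reads$read[i], rpos)
    errors[[length(errors) + 1L]] <- tibble::tibble(
      read_id = reads$read_id[i], gene_id = reads$gene_id[i],
      gene_pos = gpos, read_pos = rpos - 1L, in_b_tail = FALSE)
  }

  # 'B' tails: low-quality 3' ends with heavily elevated error rate
  reads$qual <- strrep("I", reads$read_len)
  tail_sel <- which(stats::runif(nrow(reads)) < config$b_tail_prob)
  for (i in tail_sel) {
    tl <- sample(5:40, 1L)
    tl <- min(tl, reads$read_len[i] - 1L)
    from <- reads$read_len[i] - tl + 1L
    reads$qual[i] <- paste0(strrep("I", from - 1L), strrep("B", tl))
    tail_pos <- from:reads$read_len[i]
    hit <- tail_pos[stats::runif(tl) < config$b_tail_error]
    hit <- hit[hit <= reads$aligned_len[i]]
    gpos <- error_gene_pos(reads[i, ], hit)
    keep <- !(paste(reads$gene_id[i], gpos) %in% snp_key)
    hit <- hit[keep]; gpos <- gpos[keep]
    if (length(hit) == 0L) next
    reads$read[i] <- mutate_positions(reads$read[i], hit)
    errors[[length(errors) + 1L]] <- tibble::tibble(
      read_id = reads$read_id[i], gene_id = reads$gene_id[i],
      gene_pos = gpos, read_pos = hit - 1L, in_b_tail = TRUE)
  }
  errors <- if (length(errors)) dplyr::bind_rows(errors) else
    tibble::tibble(read_id = character(), gene_id = character(),
                   gene_pos = integer(), read_pos = integer(),
                   in_b_tail = logical())

  aligned_bases <- ifelse(
    reads$strand == "+",
    substr(reads$read, 1L, reads$aligned_len),
    revcomp(substr(reads$read, 1L, reads$aligned_len))
  )
  artifacts <- dplyr::bind_rows(
    tibble::tibble(read_id = reads$read_id[tail_sel], artifact = "b_tail"),
    tibble::tibble(
      read_id = reads$read_id[reads$aligned_len < rl],
      artifact = "adapter_readthrough")
  )
  list(
    reads = tibble::tibble(
      id = reads$read_id, desc = "", seq = reads$read, qual = reads$qual,
      mate = reads$mate, frag_id = reads$frag_id),
    truth = list(
      snps = snps,
      errors = errors,
      alignments = tibble::tibble(
        read_id = reads$read_id, gene_id = reads$gene_id,
        g_start = reads$g_start, strand = reads$strand,
        bases = aligned_bases, aligned_len = reads$aligned_len,
        read_len = reads$read_len),
      artifacts = artifacts
    )
  )
}

# 0-based gene position of 1-based read positions in the aligned portion.
error_gene_pos <- function(read_row, rpos) {
  if (read_row$strand == "+") {
    read_row$g_start + rpos - 1L
  } else {
    read_row$g_start + read_row$aligned_len - rpos
  }
}

mutate_positions <- function(seq, pos1) {
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  s[pos1] <- vapply(s[pos1], substitute_base, character(1L))
  paste(s, collapse = "")
}

substitute_base <- function(ref) {
  sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
}

#' Propagate quality trimming to truth alignments
#'
#' After [trim_reads()], each read keeps only a 5' prefix. This helper
#' shortens the truth alignments accordingly: for forward reads the aligned
#' interval loses its right end, for reverse reads its left end. Reads
#' discarded by trimming (or trimmed into the adapter-only part) drop out.
#'
#' @param alignments Truth alignment tibble from [simulate_reads()].
#' @param reads Trimmed read tibble (columns `id`, `seq`).
#' @return The adjusted alignment tibble (same columns).
#' @export
trim_alignments <- function(alignments, reads) {
  new_len <- stats::setNames(nchar(reads$seq), reads$id)
  keep_read <- unname(new_len[alignments$read_id])
  keep_read[is.na(keep_read)] <- 0L
  k <- pmin(alignments$aligned_len, keep_read)
  out <- alignments[k > 0L, , drop = FALSE]
  k <- k[k > 0L]
  minus <- out$strand == "-"
  out$bases <- ifelse(
    minus,
    substr(out$bases, out$aligned_len - k + 1L, out$aligned_len),
    substr(out$bases, 1L, k)
  )
  out$g_start <- ifelse(minus, out$g_start + out$aligned_len - k,
                        out$g_start)
  out$aligned_len <- k
  out$read_len <- unname(new_len[out$read_id])
  out
}

#' Simulate a defective assembly with complete truth labels
#'
#' Builds a contig set from the gene set with a planted defect spectrum:
#' * **clean** contigs — exact full-length gene copies;
#' * **fragments** — genes split into disjoint sub-contigs (missed joins);
#' * **redundancy clusters** — 2–25 overlapping near-identical contigs of
#'   one gene, all sharing a common core so they mutually overlap well past
#'   the clustering threshold;
#' * **chimeras** — segments of two different genes joined at a recorded
#'   breakpoint;
#' * **adapter extensions** — full gene copies with a 20–30 bp adapter
#'   prefix attached at the 5' end.
#'
#' Defect categories are planted on disjoint genes so that every truth label
#' is unambiguous and recovery can be scored exactly.
#'
#' @param genes Gene tibble from [make_transcriptome()].
#' @param config A [sim_config()].
#' @return A list:
#'   * `contigs` — contig tibble (`id`, `desc`, `seq`);
#'   * `truth` — one row per contig: `contig_id`, `label` (`clean`,
#'     `fragment`, `redundancy_member`, `chimera`, `adapter_extension`),
#'     `gene_id`, `gene_b` (chimeras), `breakpoint` (chimeras: contig offset
#'     of the join), `cluster_id`, `adapter_id`, `ext_length`.
#' @export
simulate_assembly <- function(genes, config) {
  needed <- config$n_redundancy_clusters + 2L * config$n_chimeras +
    config$n_adapter_extensions + 1L
  if (nrow(genes) < needed) {
    stop("defect counts require at least ", needed, " genes but only ",
         nrow(genes), " are available")
  }
  withr::with_seed(config$seed + 2L, simulate_assembly_impl(genes, config))
}

simulate_assembly_impl <- function(genes, config) {
  n <- nrow(genes)
  roles <- rep("plain", n)
  pool <- sample.int(n)  # random but seed-deterministic gene roles
  take <- function(k) {
    if (k == 0L) return(integer())
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  cluster_genes <- take(config$n_redundancy_clusters)
  chimera_genes <- matrix(take(2L * config$n_chimeras), ncol = 2L)
  adapter_genes <- take(config$n_adapter_extensions)

  contigs <- list()
  truth <- list()
  emit <- function(seq, label, gene_id = NA_character_,
                   gene_b = NA_character_, breakpoint = NA_integer_,
                   cluster_id = NA_integer_, adapter_id = NA_character_,
                   ext_length = NA_integer_, desc = "") {
    id <- sprintf("ctg%04d", length(contigs) + 1L)
    contigs[[length(contigs) + 1L]] <<- tibble::tibble(
      id = id, desc = desc, seq = seq)
    truth[[length(truth) + 1L]] <<- tibble::tibble(
      contig_id = id, label = label, gene_id = gene_id, gene_b = gene_b,
      breakpoint = breakpoint, cluster_id = cluster_id,
      adapter_id = adapter_id, ext_length = ext_length)
  }

  # redundancy clusters: members all contain a shared 50 bp core
  size_rng <- config$redundancy_cluster_size_range
  for (ci in seq_along(cluster_genes)) {
    gi <- cluster_genes[ci]
    glen <- nchar(genes$seq[gi])
    core_lo <- glen %/% 2L - 25L
    core_hi <- glen %/% 2L + 25L
    m <- sample(size_rng[1L]:size_rng[2L], 1L)
    for (j in seq_len(m)) {
      a <- sample(max(0L, core_lo - 300L):core_lo, 1L)
      b <- sample(core_hi:min(glen, core_hi + 300L), 1L)
      member <- substr(genes$seq[gi], a + 1L, b)
      n_mut <- stats::rbinom(1L, nchar(member), config$redundancy_divergence)
      if (n_mut > 0L) {
        member <- mutate_positions(member,
                                   sample.int(nchar(member), n_mut))
      }
      emit(member, "redundancy_member", gene_id = genes$id[gi],
           cluster_id = ci, desc = sprintf("cluster %d member", ci))
    }
  }

  # chimeras: one segment from each of two reserved genes. The shorter
  # segment is kept well under half the contig so planted chimeras show the
  # diagnostic signature (strong hit, distinctly short aligned fraction)
  # rather than sitting on the detector's ratio boundary.
  seg_rng <- config$chimera_segment_range
  for (ci in seq_len(config$n_chimeras)) {
    ga <- chimera_genes[ci, 1L]
    gb <- chimera_genes[ci, 2L]
    la <- sample(seg_rng[1L]:seg_rng[2L], 1L)
    lb <- round(la * stats::runif(1L, 1.6, 2.4))
    if (stats::runif(1L) < 0.5) {
      tmp <- la; la <- lb; lb <- tmp
    }
    sa <- sample.int(nchar(genes$seq[ga]) - la + 1L, 1L) - 1L
    sb <- sample.int(nchar(genes$seq[gb]) - lb + 1L, 1L) - 1L
    emit(paste0(substr(genes$seq[ga], sa + 1L, sa + la),
                substr(genes$seq[gb], sb + 1L, sb + lb)),
         "chimera", gene_id = genes$id[ga], gene_b = genes$id[gb],
         breakpoint = la, desc = "chimeric join")
  }

  # adapter extensions: adapter prefix glued to a full gene copy
  ext_rng <- config$extension_length_range
  for (gi in adapter_genes) {
    ai <- sample.int(nrow(config$adapters), 1L)
    el <- sample(ext_rng[1L]:ext_rng[2L], 1L)
    el <- min(el, nchar(config$adapters$seq[ai]))
    emit(paste0(substr(config$adapters$seq[ai], 1L, el), genes$seq[gi]),
         "adapter_extension", gene_id = genes$id[gi],
         adapter_id = config$adapters$id[ai], ext_length = el,
         desc = "5' adapter extension")
  }

  # remaining genes: clean copies or disjoint fragments
  for (gi in pool) {
    glen <- nchar(genes$seq[gi])
    if (stats::runif(1L) < config$fragmentation_level && glen >= 300L) {
      nf <- sample(2:4, 1L)
      cuts <- sort(sample(seq(100L, glen - 100L, by = 10L), nf - 1L))
      bounds <- cbind(c(0L, cuts + 5L), c(cuts - 5L, glen))
      for (f in seq_len(nf)) {
        emit(substr(genes$seq[gi], bounds[f, 1L] + 1L, bounds[f, 2L]),
             "fragment", gene_id = genes$id[gi], desc = "gene fragment")
      }
    } else {
      emit(genes$seq[gi], "clean", gene_id = genes$id[gi],
           desc = "full-length copy")
    }
  }

  list(contigs = dplyr::bind_rows(contigs), truth = dplyr::bind_rows(truth))
}
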