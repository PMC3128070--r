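---
title: "Assessing de novo transcriptome assemblies without a reference genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing de novo transcriptome assemblies without a reference genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contigqc)
library(dplyr)
```

## The problem

When a transcriptome is assembled de novo from short reads — a non-model
organism with no reference genome — there is no ground truth to compare the
contigs against. Yet assemblers differ wildly: one may emit hundreds of
thousands of short, redundant contigs while another produces fewer, longer
ones, and the downstream annotation depends entirely on which contig set is
trusted. `contigqc` implements a two-pronged evaluation protocol for exactly
this situation, plus a truth-labelled simulator so that every stage of the
protocol is testable end to end.

**Indirect assessment** exploits external sequence databases. Because mapping
accuracy rises with contig length and alignment stringency, the number of
homology hits is compared at a moderate E-value cutoff (1e-5) against a
stringent one (1e-10), optionally restricted to contigs longer than 200 bp.
Counting raw hits rewards fragmented assemblies (many fragments of one gene
each hit the same subject), so redundant hits to the same subject are
collapsed to unique gene hits — *UniGens* — keeping only the best hit per
subject ([unigene_reduce()]). Concordance of UniGen sets between independent
assemblers ([shared_unigenes()]) is itself a quality signal: a gene found by
two different algorithms is unlikely to be an artifact.

**Direct assessment** uses a small trusted reference — typically the 13
protein-coding mitochondrial genes, which are highly expressed and reliably
known. Every contig is locally aligned against every reference gene
([assess_against_genes()]); hits below the cutoff are summarised as hit
counts, average total and aligned contig lengths, identity-threshold counts,
and per-gene coverage by merged alignment intervals
([per_gene_coverage()]). Pooling hit sets from several assemblies
([pooled_coverage()]) shows how much reference sequence is recovered by at
least one assembler — pooled coverage can exceed every individual assembly's
because each one misses regions the others find.

## Defect diagnosis

Three recurrent assembly pathologies leave recognisable signatures in the
direct assessment:

* **Chimeric contigs** — two unrelated sequences joined at assembly time —
  produce a hit with a *strong* E-value but an aligned span that is only a
  small fraction of the contig. [flag_chimera_outliers()] flags hits with
  `ratio <= 0.5` and `evalue <= 1e-20` (both conditions required; the
  E-value bound is far stricter than the 1e-5 inclusion cutoff, so weak
  chance matches with small ratios are not flagged).
* **Adapter extensions** — residual sequencing adapter attached to a contig
  end, typically 20–30 bp at the 5' end. [classify_unaligned_regions()]
  takes the contig sequence not covered by the alignment, splits it into
  maximal segments of at least 15 bp, labels them `end_mismatch` or
  `internal_mismatch` by position, and upgrades an end segment to
  `adapter_extension` when it aligns to a known adapter at >= 90% identity
  over >= 15 bp.
* **Redundancy clusters** — many near-identical contigs covering the same
  reference region, the signature of an assembler failing to merge
  overlapping fragments (often caused by SNP variation in pooled samples).
  [redundancy_clusters()] links contigs whose gene intervals overlap by
  strictly more than 30 bp and reports single-linkage components of two or
  more members.

The 0.5 / 1e-20 / 15 bp / 90% thresholds deserve a note: the original
protocol scored these defects by visual inspection, so there are no
published numeric values to inherit. The defaults are deliberate,
config-exposed choices: 0.5 because a contig more than half-explained by the
reference is better described as a partial match than a chimera; 1e-20
because a true chimera's aligned half is long enough to score far below any
chance alignment; 15 bp / 90% because shorter or weaker matches to a ~35 bp
adapter are indistinguishable from noise.

## The internal aligner and E-values

The pipeline can import externally computed 12-column hit tables
([read_hit_table()]), but to stay self-contained it also computes local
alignments internally. [smith_waterman()] wraps an exact affine-gap local
alignment (match +1, mismatch -3, gap open -5, gap extend -2; a gap of
length L scores `gap_open + L * gap_extend`). Scores are converted to
E-values with the Karlin–Altschul form `E = K m n exp(-lambda S)`, using the
published ungapped parameters for +1/-3 (`lambda = 1.374`, `K = 0.711`) and
the summed reference length as the database size `n`. Applying ungapped
parameters to gapped scores makes these E-values approximate — slightly
conservative for gapped alignments — but they preserve what the cutoffs are
used for: a strictly monotone ranking of hits on which the 1e-5 / 1e-10
thresholds act. All E-value comparisons are strict (`<`), and E-values are
computed in log space so long perfect matches underflow cleanly to zero.
The whole scheme is swappable via [scoring_scheme()].

## SNP versus sequencing error

Pooling RNA from many individuals puts real polymorphism into the reads, and
distinguishing it from sequencing error matters because both disrupt
assembly. From gapless read-to-reference alignments, [build_pileup()]
tallies bases per reference position, and [classify_sites()] applies two
rules in order:

* **SNP**: depth >= 5 and variant frequency >= 0.2, where the variant
  frequency counts only the most frequent non-reference base;
* **sequencing error**: depth >= 10 and *exactly one* deviating read
  observation at the site.

"One single deviating nucleotide" is read as one deviating read observation
(count == 1), not one deviating base type: this is the reading under which
the two rules are provably disjoint (one deviating read at depth >= 10 caps
the variant frequency at 0.1 < 0.2). Sites with depth 5–9 and a single
deviating read satisfy neither rule and are classified `none`. Indel columns
are outside the model entirely — the pileup is substitution-only.

[variant_rates()] reports SNPs per kb and the error rate as a percentage.
The denominator is not dictated by the protocol; the package uses the number
of reference positions covered by at least one read, and the argument is
exposed so any other convention can be substituted.

**A calibration point that is easy to get wrong.** The "sequencing error
rate" this estimator produces is a *per-reference-site* rate: the fraction
of covered positions showing exactly one deviating read. It is not the
per-read-base error probability, and the two diverge sharply at high depth —
at 50x, a per-base error of 0.6% would make roughly a fifth of all sites
single-deviation sites. The generator therefore treats the observable
site rate as the primary parameter (`error_site_rate`, default 0.006) and
derives the per-base substitution probability from it and the configured
mean depth by inverting `P(exactly one deviating read) = d e (1-e)^(d-1)`
(about 1.2e-4 per base at 50x). Setting `per_base_error` explicitly
overrides the derivation.

## Other conventions worth stating

* **Coordinates**: external formats keep their native 1-based inclusive
  coordinates; everything internal is 0-based half-open. The conversion
  happens exactly once, at the I/O boundary.
* **"> 200 bp" is strict**: a 200 bp contig is excluded from the long class.
  Likewise "> 80% identity" is strict and "100% identity" is exact.
* **The 5x normalization boundary is pass-inclusive** ("does not exceed"):
  a ribosomal-to-other ratio of exactly 5 passes.
* **Quality trimming** matches the literal symbol `B` (the low-quality tail
  convention of Illumina pipelines 1.3–1.5), not a phred threshold: a run of
  five or more `B`s truncates the read immediately before the run's first
  base.
* **UniGen tie-breaks**: equal E-values are resolved by higher bit score,
  then lexicographic query id, making the reduction deterministic.
* **Microsatellites**: "minimum repeat length of six" is read as six repeat
  *units* (the standard SSR convention), detection is perfect-repeat only,
  motifs of 2–5 nt, and a region whose motif is a power of a shorter motif
  (including homopolymers) is reported once at the shortest unit length.
  Spans are full-unit maximal, so `end - start = unit_length * n_units`
  always holds. Because imperfect repeats are not scored, counts are not
  comparable to tools that allow mismatches.
* **Table semantics**: the assessment's `total_hits` counts (contig, gene)
  pairs passing the cutoff, while the identity-threshold rows count distinct
  contigs; `avg_fraction_per_gene` is the unweighted mean over genes.

## What the simulator emulates — and what it does not

The generator ([sim_config()], [make_transcriptome()], [simulate_reads()],
[simulate_assembly()]) reproduces the data-generating process the protocol
was designed for, at desk scale: about 20 genes of ~1 kb (13 flagged as the
mt-like reference subset, 2 ribosomal), 2x101 bp paired-end reads with
inserts strictly above 181 bp at ~50x depth, two equifrequent haplotypes
with SNPs planted at 6.3/kb, substitution errors calibrated to a 0.6%
error-site rate, occasional low-quality `B` tails (with heavily elevated
error inside the tail, which is what makes trimming consequential) and
adapter read-through. The assembly defects are planted on disjoint genes —
clusters of 2–25 overlapping members diverged by <= 1%, chimeras joining
segments of two genes, 20–30 bp 5' adapter extensions, and fragmentation
into disjoint sub-contigs — so every contig carries exactly one truth label
and recovery can be scored exactly. One deliberate asymmetry: a chimera's
shorter segment is kept well under half the contig (the longer side is
drawn 1.6–2.4x the shorter). A 50:50 join sits exactly on the detector's
ratio boundary, where a one-base difference in alignment end decides the
call; the defect being modelled is a strong hit with a *distinctly* short
aligned fraction.

Every output is bit-reproducible given the config seed. All problem sizes
were chosen so the full battery — alignment of every contig against every
gene, read simulation, trimming, pileup and classification — completes in
about a minute on one core; the acceptance script
(`scripts/acceptance.R`) runs exactly this scenario.

The simulator intentionally does **not** model: realistic expression-level
variation (reads are uniform per bp, so normalization always looks
successful), indels (the variant model is substitution-only), quality-score
profiles beyond the `B`-tail artifact, true assembler behaviour (contigs are
constructed, not assembled from the reads — fragment/chimera/cluster
structure is planted, not emergent), or protein-space (translated) homology
search. Passing the recovery tests therefore demonstrates that the
*measurement* machinery is correct and calibrated, not that any particular
assembler will behave this way on real data; on real data the indirect
measures also depend on database completeness and evolutionary distance,
which the synthetic transcriptome cannot represent.

## Degenerate inputs and numerical corners

Zero-length alignments (no positive-scoring cell) are returned as score 0
with empty spans rather than an error. An empty contig set yields a zeroed
assessment summary. Genes shorter than the minimum insert are skipped with a
warning by the read simulator. Reads trimmed to nothing are dropped, and
trimming propagates to truth alignments on both strands (forward reads lose
the right end of their reference interval, reverse reads the left).
Interval arithmetic is closed under empty input: coverage of a gene with no
hits is 0, and the pooled coverage of duplicated hit sets equals that of one
copy.
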