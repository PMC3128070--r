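# The default synthetic scenario, computed once per test run and reused by
# every file that needs it (the contig-vs-gene alignment pass dominates the
# cost).
default_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 20260101)
      genes <- make_transcriptome(cfg)
      asm <- simulate_assembly(genes, cfg)
      assessment <- assess_against_genes(asm$contigs, genes,
                                         max_evalue = 1e-5)
      sim <- simulate_reads(genes, cfg)
      cache <<- list(cfg = cfg, genes = genes, contigs = asm$contigs,
                     truth = asm$truth, assessment = assessment,
                     sim = sim)
    }
    cache
  }
})
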