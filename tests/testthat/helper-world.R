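# A small shared synthetic world for module tests: 25 kb genome, 16 genes,
# every gene with a planted motif, light CG background. Built once per test
# session. 30x coverage keeps per-strand informative depth (~15x) far from
# the min_cov = 5 floor so the fixture's truth is reliably callable.
small_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g0 <- generate_genome(25000, 0.70, seed = 11)
    ann <- generate_annotation(g0, 16, c(400, 800), 100, seed = 12)
    pl <- plant_methylome(g0, ann, genes_with_motif_fraction = 1,
                          background_rates = c(CG = 0.002), seed = 13)
    reads <- simulate_reads(pl$genome, pl$truth, coverage = 30,
                            read_length = 80, seed = 14)
    idx <- build_index(pl$genome, 16)
    aln <- map_reads(idx, reads)
    counts <- pileup(aln, pl$genome)
    calls <- call_methylation(counts, pl$genome)
    cache <<- list(genome = pl$genome, annotation = ann, truth = pl$truth,
                   planted = pl$planted, reads = reads, index = idx,
                   alignments = aln, counts = counts, calls = calls)
    cache
  }
})
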