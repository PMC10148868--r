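test_that("generate_genome composition, determinism and errors", {
  g <- generate_genome(1000, gc_fraction = 1.0, seed = 1)
  expect_false(grepl("[^GC]", g$seq))

  g1 <- generate_genome(5000, 0.7, seed = 42)
  g2 <- generate_genome(5000, 0.7, seed = 42)
  expect_identical(g1$seq, g2$seq)
  expect_false(identical(g1$seq, generate_genome(5000, 0.7, seed = 43)$seq))

  # observed GC within +-0.005 of target at 1 Mbp
  big <- generate_genome(1e6, 0.70, seed = 7)
  expect_lt(abs(gc_fraction(big) - 0.70), 0.005)

  expect_error(generate_genome(0, 0.5), "length")
  expect_error(generate_genome(100, 1.5), "gc_fraction")
})

test_that("generate_annotation places disjoint genes with consistent starts", {
  g <- generate_genome(50000, 0.7, seed = 2)
  expect_identical(nrow(generate_annotation(g, 0)), 0L)

  ann <- generate_annotation(g, 40, c(300, 900), min_gap = 50, seed = 3)
  expect_identical(nrow(ann), 40L)
  expect_true(all(ann$start >= 0 & ann$start < ann$end &
                    ann$end <= genome_length(g)))
  expect_true(intervals_ok(ann$start, ann$end, min_gap = 50))
  expect_identical(ann$translation_start,
                   as.integer(ifelse(ann$strand == "+", ann$start,
                                     ann$end - 1L)))

  # strand counts within 3 sigma of Binomial(200, 1/2)
  big <- generate_annotation(generate_genome(1e6, 0.7, seed = 4), 200,
                             seed = 5)
  expect_lt(abs(sum(big$strand == "+") - 100), 3 * sqrt(200 * 0.25))

  # infeasible packing is an explicit error
  expect_error(generate_annotation(generate_genome(1000, 0.5, seed = 1),
                                   10, c(200, 200), min_gap = 50),
               "cannot place")
})

test_that("plant_methylome writes motifs into upstream regions with truth", {
  g <- generate_genome(30000, 0.7, seed = 21)
  ann <- generate_annotation(g, 20, c(400, 800), 100, seed = 22)

  # nothing requested, nothing planted
  pl0 <- plant_methylome(g, ann, genes_with_motif_fraction = 0,
                         background_rates = c(CG = 0), seed = 23)
  expect_identical(nrow(pl0$truth), 0L)
  expect_identical(pl0$genome$seq, g$seq)

  pl <- plant_methylome(g, ann, motifs = list(motif_spec("GGCCGG", 4)),
                        genes_with_motif_fraction = 0.5,
                        background_rates = c(CG = 0), seed = 24)
  expect_identical(nrow(pl$planted), 10L) # round(0.5 * 20) genes selected
  expect_identical(nrow(pl$truth), 10L)

  regions <- upstream_regions(ann, genome_length = genome_length(g))
  chars <- strsplit(pl$genome$seq, "")[[1]]
  for (i in seq_len(nrow(pl$planted))) {
    p <- pl$planted[i, ]
    word <- substr(pl$genome$seq, p$start0 + 1, p$start0 + 6)
    expect_identical(word, if (p$strand == "+") "GGCCGG" else
      revcomp("GGCCGG"))
    reg <- regions[regions$gene_id == p$gene_id, ]
    expect_true(p$start0 >= reg$start && p$start0 + 6 <= reg$end)
  }
  plus <- pl$planted[pl$planted$strand == "+", ]
  anchors <- plus$start0 + 3L
  expect_true(all(paste(anchors, "+") %in%
                    paste(pl$truth$pos0, pl$truth$strand)))

  # truth consistency: the base under every site is C on its strand
  ref <- chars[pl$truth$pos0 + 1L]
  expect_true(all(ref[pl$truth$strand == "+"] == "C"))
  expect_true(all(ref[pl$truth$strand == "-"] == "G"))

  # planted motifs are findable by exhaustive string search
  n_fwd <- length(gregexpr("GGCCGG", pl$genome$seq, fixed = TRUE)[[1]])
  n_rev <- length(gregexpr(revcomp("GGCCGG"), pl$genome$seq,
                           fixed = TRUE)[[1]])
  expect_gte(n_fwd + n_rev, nrow(pl$planted))
})

test_that("background methylation respects contexts and exclusions", {
  g <- generate_genome(20000, 0.7, seed = 31)
  ann <- generate_annotation(g, 5, c(400, 600), 100, seed = 32)
  pl <- plant_methylome(g, ann, genes_with_motif_fraction = 0,
                        background_rates = c(CG = 0.01, CHH = 0.005),
                        seed = 33)
  expect_true(all(pl$truth$provenance == "background"))
  ctx <- classify_context(pl$genome, pl$truth$pos0, pl$truth$strand)
  expect_true(all(ctx %in% c("CG", "CHH")))
  expect_error(plant_methylome(g, ann, background_rates = c(XX = 0.1)),
               "unknown background context")
})

test_that("simulate_reads honors protection, conversion and read count", {
  g <- generate_genome(3000, 0.7, seed = 41)
  chars <- strsplit(g$seq, "")[[1]]

  # all cytosines methylated at 1.0, no errors: OT reads are exact genome
  # substrings, OB reads exact substrings of the reverse complement
  all_meth <- rbind(
    data.frame(chrom = g$name, pos0 = which(chars == "C") - 1L,
               strand = "+", fraction = 1, provenance = "x"),
    data.frame(chrom = g$name, pos0 = which(chars == "G") - 1L,
               strand = "-", fraction = 1, provenance = "x"))
  rd <- simulate_reads(g, all_meth, coverage = 3, read_length = 60,
                       conversion_rate = 1, error_rate = 0, seed = 42)
  ot <- rd[rd$origin_frame == "OT", ]
  expect_true(all(ot$bases ==
                    substring(g$seq, ot$origin_pos + 1, ot$origin_pos + 60)))
  ob <- rd[rd$origin_frame == "OB", ]
  expect_true(all(ob$bases ==
                    revcomp(substring(g$seq, ob$origin_pos + 1,
                                      ob$origin_pos + 60))))

  # empty truth + full conversion: no C survives at reference-C positions
  empty <- all_meth[0, ]
  rd2 <- simulate_reads(g, empty, coverage = 3, read_length = 60,
                        conversion_rate = 1, error_rate = 0, seed = 43)
  ot2 <- rd2[rd2$origin_frame == "OT", ]
  for (i in head(seq_len(nrow(ot2)), 50)) {
    win <- chars[ot2$origin_pos[i] + seq_len(60)]
    rb <- strsplit(ot2$bases[i], "")[[1]]
    expect_true(all(rb[win == "C"] == "T"))
    expect_identical(rb[win != "C"], win[win != "C"])
  }

  # read count = ceiling(coverage * L / read_length)
  expect_identical(nrow(rd), as.integer(ceiling(3 * 3000 / 60)))

  expect_error(simulate_reads(g, empty, coverage = 1, read_length = 5000),
               "read_length")
})

test_that("partial conversion matches its binomial expectation", {
  g <- generate_genome(5000, 0.7, seed = 51)
  empty <- data.frame(chrom = character(0), pos0 = integer(0),
                      strand = character(0), fraction = numeric(0),
                      provenance = character(0))
  conv <- 0.95
  rd <- simulate_reads(g, empty, coverage = 10, read_length = 80,
                       conversion_rate = conv, error_rate = 0, seed = 52)
  ot <- rd[rd$origin_frame == "OT", ]
  chars <- strsplit(g$seq, "")[[1]]
  n_c <- 0; n_tot <- 0
  for (i in seq_len(nrow(ot))) {
    win <- chars[ot$origin_pos[i] + seq_len(80)]
    rb <- strsplit(ot$bases[i], "")[[1]]
    n_c <- n_c + sum(rb[win == "C"] == "C")
    n_tot <- n_tot + sum(win == "C")
  }
  phat <- n_c / n_tot # unconverted fraction estimates 1 - conversion_rate
  expect_lt(abs(phat - (1 - conv)),
            3 * sqrt((1 - conv) * conv / n_tot))
})

test_that("simulation outputs are byte-identical under a fixed seed", {
  w <- small_world()
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  rd1 <- simulate_reads(w$genome, w$truth, coverage = 2, read_length = 70,
                        seed = 99)
  rd2 <- simulate_reads(w$genome, w$truth, coverage = 2, read_length = 70,
                        seed = 99)
  write_fastq(rd1, f1); write_fastq(rd2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  t1 <- tempfile(); t2 <- tempfile()
  write_truth(w$truth, t1); write_truth(w$truth, t2)
  expect_identical(readLines(t1), readLines(t2))
  expect_identical(read_truth(t1)$pos0, w$truth$pos0)
})

test_that("FASTA and GFF3 round-trip through Biostrings/rtracklayer", {
  w <- small_world()
  fa <- tempfile(fileext = ".fa")
  write_fasta(w$genome, fa)
  expect_identical(read_fasta(fa)$seq, w$genome$seq)

  gff <- tempfile(fileext = ".gff3")
  write_gff3(w$annotation, w$genome, gff)
  back <- read_gff3(gff)
  expect_identical(back$start, w$annotation$start)
  expect_identical(back$end, w$annotation$end)
  expect_identical(back$strand, w$annotation$strand)
  expect_identical(back$translation_start, w$annotation$translation_start)
})
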