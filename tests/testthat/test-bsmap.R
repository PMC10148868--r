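test_that("index stores both converted frames", {
  idx <- build_index(bs_genome("g", "ACCG"), k = 4)
  # C->T conversion of ACCG is ATTG (OT frame)
  expect_identical(index_query(idx, "ATTG", "OT"), 0L)
  # G->A conversion of ACCG is ACCA (OB frame)
  expect_identical(index_query(idx, "ACCA", "OB"), 0L)
  expect_length(index_query(idx, "AAAA", "OT"), 0)
  expect_error(build_index(bs_genome("g", "ACCG"), k = 3), "k")
  expect_error(build_index(bs_genome("g", "ACCG"), k = 40), "k")
})

test_that("every converted-reference k-mer is indexed at its offset", {
  g <- generate_genome(2000, 0.7, seed = 61)
  k <- 8L
  idx <- build_index(g, k = k)
  ct <- chartr("C", "T", g$seq)
  ga <- chartr("G", "A", g$seq)
  for (off in seq(0, 2000 - k, by = 7)) { # stride keeps the loop quick
    expect_true(off %in% index_query(idx, substr(ct, off + 1, off + k), "OT"))
    expect_true(off %in% index_query(idx, substr(ga, off + 1, off + k), "OB"))
  }
})

test_that("reads map to their origin with bisulfite-aware scoring", {
  g <- generate_genome(4000, 0.7, seed = 62)
  idx <- build_index(g, 16)

  # fully converted OT substring maps back exactly
  p <- 1234L
  read <- chartr("C", "T", substr(g$seq, p + 1, p + 100))
  a <- map_read(idx, read)
  expect_identical(a$status, "unique")
  expect_identical(a$pos, p)
  expect_identical(a$strand, "OT")
  expect_identical(a$mismatches, 0L)

  # unconverted (methylated) Cs are not mismatches either
  raw <- substr(g$seq, p + 1, p + 100)
  a2 <- map_read(idx, raw)
  expect_identical(a2$mismatches, 0L)
  expect_identical(a2$pos, p)

  # an OB read: reverse complement with bottom-strand C->T conversion
  ob <- chartr("C", "T", revcomp(substr(g$seq, p + 1, p + 100)))
  a3 <- map_read(idx, ob)
  expect_identical(a3$status, "unique")
  expect_identical(a3$pos, p)
  expect_identical(a3$strand, "OB")

  # reads shorter than k are unmapped with reason
  expect_identical(map_read(idx, "ACGTACGT")$status, "unmapped")
})

test_that("bisulfite scoring is asymmetric", {
  g <- generate_genome(3000, 0.7, seed = 63)
  idx <- build_index(g, 16)
  p <- 500L
  win <- substr(g$seq, p + 1, p + 100)
  ch <- strsplit(win, "")[[1]]
  # read T over reference C: free
  tc <- which(ch == "C" & seq_along(ch) > 20 & seq_along(ch) < 80)[1]
  r1 <- win; substr(r1, tc, tc) <- "T"
  expect_identical(map_read(idx, r1)$mismatches, 0L)
  # read C over reference T: costs one mismatch
  ct <- which(ch == "T" & seq_along(ch) > 20 & seq_along(ch) < 80)[1]
  r2 <- win; substr(r2, ct, ct) <- "C"
  a <- map_read(idx, r2)
  expect_identical(a$mismatches, 1L)
  expect_identical(a$pos, p)
})

test_that("reads inside a long tandem repeat are ambiguous", {
  unit <- generate_genome(150, 0.7, seed = 64)$seq
  flank1 <- generate_genome(300, 0.7, seed = 65)$seq
  flank2 <- generate_genome(300, 0.7, seed = 66)$seq
  g <- bs_genome("rep", paste0(flank1, unit, unit, flank2))
  idx <- build_index(g, 16)
  read <- chartr("C", "T", substr(unit, 11, 110))
  expect_identical(map_read(idx, read)$status, "ambiguous")
})

test_that("mapper agrees with the exhaustive scan oracle", {
  g <- generate_genome(1200, 0.7, seed = 67)
  idx <- build_index(g, 16)
  rd <- simulate_reads(g, data.frame(chrom = character(0), pos0 = integer(0),
                                     strand = character(0),
                                     fraction = numeric(0),
                                     provenance = character(0)),
                       coverage = 8, read_length = 100,
                       conversion_rate = 0.99, error_rate = 0, seed = 68)
  # add constructed reads with interior mutations (outside both seeds)
  mut <- vapply(1:20, function(i) {
    p <- 50L * i
    r <- chartr("C", "T", substr(g$seq, p + 1, p + 100))
    substr(r, 40, 40) <- c("A", "C", "G", "T")[(i %% 4) + 1]
    r
  }, character(1))
  all_reads <- c(rd$bases, mut)
  aln <- map_reads(idx, all_reads, max_mismatch = 2)
  oracle <- make_scan_oracle(g$seq, 100L)
  for (i in seq_along(all_reads)) {
    o <- oracle(all_reads[i], 2)
    expect_identical(aln$status[i], o$status)
    if (o$status == "unique") {
      expect_identical(aln$pos[i], as.integer(o$pos))
      expect_identical(aln$strand[i], o$frame)
    }
  }
})

test_that("error-free reads from a 1 Mbp genome map back at >= 99%", {
  g <- generate_genome(1e6, 0.7, seed = 69)
  empty <- data.frame(chrom = character(0), pos0 = integer(0),
                      strand = character(0), fraction = numeric(0),
                      provenance = character(0))
  rd <- simulate_reads(g, empty, coverage = 1, read_length = 100,
                       conversion_rate = 1, error_rate = 0, seed = 70)
  rd <- rd[seq_len(10000), ]
  idx <- build_index(g, 16)
  aln <- map_reads(idx, rd, max_mismatch = 0)
  ok <- aln$status == "unique"
  expect_gte(mean(ok), 0.99)
  expect_true(all(aln$pos[ok] == rd$origin_pos[ok]))
  expect_true(all(aln$strand[ok] == rd$origin_frame[ok]))
})

test_that("SAM round-trips alignments including frames and failures", {
  w <- small_world()
  aln <- w$alignments[seq_len(500), ]
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, w$genome, sam)
  back <- read_sam(sam)
  expect_identical(nrow(back), nrow(aln))
  expect_identical(back$read_id, aln$read_id)
  expect_identical(back$status, aln$status)
  u <- aln$status == "unique"
  expect_identical(back$pos[u], aln$pos[u])
  expect_identical(back$strand[u], aln$strand[u])
  expect_identical(back$bases[u], aln$bases[u]) # as-sequenced orientation
})
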