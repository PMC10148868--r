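test_that("classify_context matches the stated definitions", {
  expect_identical(classify_context("ACGA", 1, "+"), "CG")
  expect_identical(classify_context("ACAGA", 1, "+"), "CHG")
  expect_identical(classify_context("ACAAT", 1, "+"), "CHH")
  # bottom-strand C under the G of TCGA: downstream bases are the
  # complements of positions 1, 0 = G, A -> CG
  expect_identical(classify_context("TCGA", 2, "-"), "CG")
  # edges and Ns give undefined, never a fabricated context
  expect_identical(classify_context("AACG", 2, "+"), "undefined")
  expect_identical(classify_context("ACNGA", 1, "+"), "undefined")
  expect_identical(classify_context("CGAA", 1, "-"), "undefined")
  expect_error(classify_context("ACGA", 0, "+"), "not a cytosine")
})

test_that("classify_context agrees with the reverse-complement oracle", {
  g <- generate_genome(3000, 0.7, seed = 71)
  chars <- strsplit(g$seq, "")[[1]]
  pos <- c(which(chars == "C") - 1L, which(chars == "G") - 1L)
  strand <- rep(c("+", "-"), c(sum(chars == "C"), sum(chars == "G")))
  expect_identical(classify_context(g, pos, strand),
                   oracle_context(g$seq, pos, strand))
})

test_that("pileup counts C as methylated, T as converted, else ignored", {
  g <- bs_genome("g", "AACGTACGTACGTACGTTTT")
  mk <- function(bases, pos, strand) {
    data.frame(read_id = "r1", chrom = "g", pos = pos, strand = strand,
               mismatches = 0L, status = "unique", bases = bases,
               stringsAsFactors = FALSE)
  }
  # OT read with C over the reference C at pos 2
  p1 <- pileup(mk("ACGT", 1L, "OT"), g)
  expect_identical(p1$n_meth[p1$pos == 2], 1L)
  expect_identical(p1$n_total[p1$pos == 2], 1L)
  expect_identical(p1$strand[p1$pos == 2], "+")
  # T over the same site: converted
  p2 <- pileup(mk("ATGT", 1L, "OT"), g)
  expect_identical(p2$n_meth[p2$pos == 2], 0L)
  expect_identical(p2$n_total[p2$pos == 2], 1L)
  # G over the site (sequencing error): site absent
  p3 <- pileup(mk("AGGT", 1L, "OT"), g)
  expect_false(2 %in% p3$pos)
  # OB read: bottom-strand C under the reference G at pos 3;
  # as-sequenced bottom read with G in reference orientation means base C
  ob <- revcomp("ACGT") # bottom 5'->3' of the window at pos 1..4
  p4 <- pileup(mk(ob, 1L, "OB"), g)
  expect_identical(p4$strand[p4$pos == 3], "-")
  expect_identical(p4$n_meth[p4$pos == 3], 1L)
  # ambiguous/unmapped reads contribute nothing
  amb <- mk("ACGT", 1L, "OT"); amb$status <- "ambiguous"
  expect_identical(nrow(pileup(amb, g)), 0L)
  # out-of-bounds alignment is a corrupt-input error
  expect_error(pileup(mk("ACGT", 18L, "OT"), g), "bounds")
})

test_that("binomial calling matches closed forms and the tail-sum oracle", {
  # closed forms: P(X >= 0) = 1, P(X >= n) = eps^n
  expect_identical(binom_tail_p(0, 10, 0.005), 1)
  expect_equal(binom_tail_p(20, 20, 0.005), 0.005^20, tolerance = 1e-12)
  # tail-sum oracle on a grid
  for (n in c(5, 10, 17)) {
    for (m in 0:n) {
      for (eps in c(0.005, 0.05)) {
        expect_equal(binom_tail_p(m, n, eps), oracle_binom_tail(m, n, eps),
                     tolerance = 1e-12)
      }
    }
  }
  # monotonicity: p non-increasing in n_meth at fixed n_total
  p <- binom_tail_p(0:30, 30, 0.01)
  expect_true(all(diff(p) <= 0))
})

test_that("call_methylation applies coverage, FDR and level rules", {
  g <- bs_genome("g", strrep("ACGT", 50))
  counts <- data.frame(
    chrom = "g",
    pos = c(1L, 5L, 9L, 13L, 17L),
    strand = "+",
    n_meth = c(10L, 0L, 2L, 10L, 3L),
    n_total = c(10L, 10L, 10L, 10L, 4L))
  calls <- call_methylation(counts, g, epsilon = 0.005, alpha = 0.05,
                            min_cov = 5, min_level = 0.5)
  expect_true(calls$called[1])            # 10/10 unconverted
  expect_false(calls$called[2])           # p = 1
  expect_false(calls$called[3])           # beta 0.2 < min_level
  expect_true(is.na(calls$q[5]))          # under min_cov: untested
  expect_false(calls$called[5])
  # the called invariant
  with(calls[calls$called, ], {
    expect_true(all(q <= 0.05 & n_total >= 5 & beta >= 0.5))
  })
  expect_identical(nrow(call_methylation(counts[0, ], g)), 0L)
})

test_that("epsilon estimation pools unconverted residues", {
  w <- small_world()
  est <- estimate_epsilon(w$counts)
  # the simulation ran at conversion 0.995 -> epsilon 0.005
  expect_gt(est, 0.002)
  expect_lt(est, 0.010)
  expect_gte(estimate_epsilon(w$counts[0, ]), 1e-4)
})

test_that("context summary partitions called sites; CG collapse works", {
  w <- small_world()
  cs <- context_summary(w$calls)
  expect_identical(sum(cs), sum(w$calls$called))
  expect_identical(context_summary(w$calls[0, ]),
                   stats::setNames(integer(4),
                                   c("CG", "CHG", "CHH", "undefined")))
  # constructed symmetric CG pair collapses to one record
  g <- bs_genome("g", "AACGTT")
  calls <- data.frame(chrom = "g", pos = c(2L, 3L), strand = c("+", "-"),
                      n_meth = c(8L, 6L), n_total = c(8L, 7L),
                      context = "CG", beta = c(1, 6 / 7), p = 0, q = 0,
                      called = TRUE, stringsAsFactors = FALSE)
  col <- collapse_cg_pairs(calls)
  expect_identical(nrow(col), 1L)
  expect_identical(col$n_meth, 14L)
  expect_identical(col$n_total, 15L)
})

test_that("cytosine report and bedGraph round-trip", {
  w <- small_world()
  tsv <- tempfile(fileext = ".tsv")
  write_cytosine_report(w$calls, tsv)
  back <- read_cytosine_report(tsv)
  expect_identical(back$pos, w$calls$pos)
  expect_identical(back$strand, w$calls$strand)
  expect_identical(back$n_meth, w$calls$n_meth)
  expect_identical(back$n_total, w$calls$n_total)
  expect_identical(back$called, w$calls$called)
  bg <- tempfile(fileext = ".bedGraph")
  write_bedgraph(w$calls, bg)
  expect_identical(length(readLines(bg)) - 1L, sum(w$calls$called))
})
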