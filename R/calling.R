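#' Classify the sequence context of a cytosine
#'
#' Reads the two bases 3' of the cytosine on its own strand (for a - strand
#' site these are the complements of the two preceding top-strand bases):
#' next base G gives CG, else next-next base G gives CHG, else CHH, where H
#' is A, T or C. Sites with fewer than two downstream bases on their strand,
#' or any N among them, are `undefined` (no context is fabricated at edges).
#'
#' @param genome a [bs_genome()] (or sequence string); may contain N if
#'   parsed from a file.
#' @param pos integer vector of 0-based positions.
#' @param strand character vector, `"+"` or `"-"`, recycled to match `pos`.
#' @return character vector over `{CG, CHG, CHH, undefined}`.
#' @export
#' @examples
#' classify_context("ACGA", 1, "+")   # "CG"
#' classify_context("ACAGA", 1, "+")  # "CHG"
#' classify_context("TCGA", 2, "-")   # "CG" (bottom-strand C under the G)
classify_context <- function(genome, pos, strand) {
  genome <- as_genome(genome)
  s <- genome$seq
  L <- nchar(s)
  n <- length(pos)
  strand <- rep_len(strand, n)
  at <- function(p) { # 0-based char lookup, "" when out of range
    out <- rep("", length(p))
    ok <- which(p >= 0L & p < L)
    if (length(ok)) out[ok] <- substring(s, p[ok] + 1L, p[ok] + 1L)
    out
  }
  ref <- at(pos)
  plus <- strand == "+"
  if (any(ref[plus] != "C") || any(ref[!plus] != "G"))
    stop("reference base at (pos, strand) is not a cytosine", call. = FALSE)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  b1 <- b2 <- character(n)
  b1[plus] <- at(pos[plus] + 1L)
  b2[plus] <- at(pos[plus] + 2L)
  m1 <- at(pos[!plus] - 1L); m2 <- at(pos[!plus] - 2L)
  b1[!plus] <- ifelse(m1 == "", "", comp[m1])
  b2[!plus] <- ifelse(m2 == "", "", comp[m2])
  out <- rep("undefined", n)
  known <- b1 %in% c("A", "C", "G", "T") & b2 %in% c("A", "C", "G", "T")
  out[known & b1 == "G"] <- "CG"
  out[known & b1 != "G" & b2 == "G"] <- "CHG"
  out[known & b1 != "G" & b2 != "G"] <- "CHH"
  out
}

#' Pile up bisulfite evidence per cytosine
#'
#' Only uniquely mapped reads contribute. An OT read interrogates top-strand
#' cytosines: read base C is unconverted evidence (`n_meth`), T is converted
#' evidence, anything else (a sequencing error) is ignored. An OB read
#' mirrors this on bottom-strand cytosines (top-strand Gs). Sites with no
#' informative read are omitted.
#'
#' @param alignments a `bs_alignments` data.frame from [map_reads()] or
#'   [read_sam()]; must carry read `bases` (join them from a reads table via
#'   the `reads` argument if absent).
#' @param genome the reference [bs_genome()].
#' @param reads optional `bs_reads`/FASTQ data.frame used to fill in
#'   `alignments$bases` by `read_id`.
#' @return data.frame of class `site_counts`: `chrom`, `pos` (0-based),
#'   `strand` (`+`/`-`), `n_meth`, `n_total`.
#' @export
pileup <- function(alignments, genome, reads = NULL) {
  genome <- as_genome(genome)
  L <- genome_length(genome)
  if (is.null(alignments$bases) || anyNA(alignments$bases)) {
    if (is.null(reads))
      stop("alignments carry no read bases; supply `reads`", call. = FALSE)
    alignments$bases <- reads$bases[match(alignments$read_id, reads$read_id)]
  }
  aln <- alignments[alignments$status == "unique", , drop = FALSE]
  if (nrow(aln) && any(aln$pos < 0 | aln$pos + nchar(aln$bases) > L))
    stop("alignment out of genome bounds", call. = FALSE)
  res <- cpp_pileup(genome$seq, as.integer(aln$pos),
                    as.integer(aln$strand == "OB"), aln$bases)
  build <- function(meth, tot, strand) {
    keep <- which(tot > 0L)
    data.frame(chrom = rep(genome$name, length(keep)), pos = keep - 1L,
               strand = rep(strand, length(keep)),
               n_meth = meth[keep], n_total = tot[keep],
               stringsAsFactors = FALSE)
  }
  out <- rbind(build(res$meth_plus, res$tot_plus, "+"),
               build(res$meth_minus, res$tot_minus, "-"))
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("site_counts", "data.frame")
  out
}

#' Exact binomial non-conversion p-values
#'
#' Upper-tail probability `P(X >= n_meth | n_total, epsilon)` of observing at
#' least the seen number of unconverted reads if the site were unmethylated
#' and residual non-conversion happened at rate `epsilon`.
#'
#' @param n_meth,n_total integer vectors.
#' @param epsilon non-conversion rate in (0, 1).
#' @return numeric vector of p-values (`p = 1` whenever `n_meth = 0`).
#' @export
binom_tail_p <- function(n_meth, n_total, epsilon) {
  pbinom(n_meth - 1, n_total, epsilon, lower.tail = FALSE)
}

#' Call methylated cytosines
#'
#' Per site, an exact binomial upper-tail test of the unconverted read count
#' against the non-conversion rate `epsilon`; Benjamini-Hochberg correction
#' across all tested sites (those with `n_total >= min_cov`); a site is
#' called when `q <= alpha` and its methylation level `beta = n_meth /
#' n_total` is at least `min_level`. Sequence context is attached via
#' [classify_context()].
#'
#' @param counts a `site_counts` data.frame from [pileup()].
#' @param genome the reference [bs_genome()] (for context classification).
#' @param epsilon non-conversion rate in (0, 1); see [estimate_epsilon()].
#' @param alpha FDR level.
#' @param min_cov minimum informative reads for a site to be tested.
#' @param min_level minimum beta for a call.
#' @return data.frame of class `methyl_calls`: the count columns plus
#'   `context`, `beta`, `p`, `q` (NA for untested sites) and `called`.
#' @export
call_methylation <- function(counts, genome, epsilon = 0.005, alpha = 0.05,
                             min_cov = 5L, min_level = 0.5) {
  assert_scalar_number(epsilon, "epsilon", lo = 1e-12, hi = 1 - 1e-12)
  assert_scalar_number(alpha, "alpha", lo = 0, hi = 1)
  assert_scalar_number(min_cov, "min_cov", lo = 1)
  assert_scalar_number(min_level, "min_level", lo = 0, hi = 1)
  genome <- as_genome(genome)
  out <- as.data.frame(counts)
  if (nrow(out) == 0L) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), n_meth = integer(0),
                      n_total = integer(0))
  }
  out$context <- if (nrow(out)) classify_context(genome, out$pos, out$strand)
                 else character(0)
  out$beta <- ifelse(out$n_total > 0, out$n_meth / out$n_total, NA_real_)
  out$p <- binom_tail_p(out$n_meth, out$n_total, epsilon)
  tested <- out$n_total >= min_cov
  out$q <- rep(NA_real_, nrow(out))
  out$q[tested] <- p.adjust(out$p[tested], method = "BH")
  out$called <- tested & !is.na(out$q) & out$q <= alpha & out$beta >= min_level
  attr(out, "params") <- list(epsilon = epsilon, alpha = alpha,
                              min_cov = as.integer(min_cov),
                              min_level = min_level)
  class(out) <- c("methyl_calls", "data.frame")
  out
}

#' Estimate the bisulfite non-conversion rate from the data
#'
#' Proxy estimate without an unmethylated spike-in control: over sites that
#' are clearly unmethylated (`beta < max_beta`, `n_total >= min_cov`), the
#' unconverted fraction estimates `epsilon`. The default pools reads
#' (`sum(n_meth) / sum(n_total)`), which remains informative when most
#' individual sites show zero unconverted reads; `method = "median"` takes
#' the per-site median instead (often exactly 0 at moderate coverage, hence
#' not the default).
#'
#' @param counts a `site_counts` data.frame.
#' @param max_beta upper beta bound defining "clearly unmethylated".
#' @param min_cov minimum coverage for a site to enter the estimate.
#' @param method `"pooled"` (default) or `"median"`.
#' @param floor lower bound applied to the estimate so the binomial test
#'   stays proper.
#' @return estimated epsilon (scalar).
#' @export
estimate_epsilon <- function(counts, max_beta = 0.1, min_cov = 5L,
                             method = c("pooled", "median"), floor = 1e-4) {
  method <- match.arg(method)
  sel <- counts$n_total >= min_cov &
    (counts$n_meth / counts$n_total) < max_beta
  x <- counts[sel, , drop = FALSE]
  if (nrow(x) == 0L) return(floor)
  est <- switch(method,
                pooled = sum(x$n_meth) / sum(x$n_total),
                median = median(x$n_meth / x$n_total))
  max(est, floor)
}

#' Summarize called sites per sequence context
#'
#' @param calls a `methyl_calls` data.frame.
#' @param called_only count only called sites (default) or all rows.
#' @return named integer vector with elements `CG`, `CHG`, `CHH`,
#'   `undefined`; the three context counts plus `undefined` always sum to
#'   the number of (called) sites.
#' @export
context_summary <- function(calls, called_only = TRUE) {
  x <- if (called_only && !is.null(calls$called))
    calls[calls$called, , drop = FALSE] else calls
  lv <- c("CG", "CHG", "CHH", "undefined")
  out <- table(factor(x$context, levels = lv))
  stats::setNames(as.integer(out), lv)
}

#' Collapse symmetric CG pairs
#'
#' Whether genome-wide m5C counts treat the two strands of a CG dinucleotide
#' separately or as one unit is a reporting convention; this package reports
#' strands separately and offers this collapse. A called + strand CG site at
#' `pos` and a called - strand CG site at `pos + 1` merge into one record
#' (the + coordinate, summed evidence).
#'
#' @param calls a `methyl_calls` data.frame.
#' @return data.frame with merged CG pairs; non-CG and unpaired sites pass
#'   through unchanged.
#' @export
collapse_cg_pairs <- function(calls) {
  x <- calls[calls$called, , drop = FALSE]
  cg_p <- x$context == "CG" & x$strand == "+"
  cg_m <- x$context == "CG" & x$strand == "-"
  partner <- match(x$pos[cg_p] + 1L, x$pos[cg_m])
  merged <- which(cg_p)[!is.na(partner)]
  mate <- which(cg_m)[partner[!is.na(partner)]]
  if (length(merged)) {
    x$n_meth[merged] <- x$n_meth[merged] + x$n_meth[mate]
    x$n_total[merged] <- x$n_total[merged] + x$n_total[mate]
    x$beta[merged] <- x$n_meth[merged] / x$n_total[merged]
    x$strand[merged] <- "*"
    x <- x[-mate, , drop = FALSE]
  }
  rownames(x) <- NULL
  x
}

#' Write / read a Bismark-style cytosine report
#'
#' TSV `chrom pos1 strand n_meth n_unmeth context p q called` with 1-based
#' positions (stated in a header comment); the package's in-memory tables
#' stay 0-based.
#'
#' @param calls a `methyl_calls` data.frame.
#' @param path file path.
#' @export
write_cytosine_report <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# bsmethyl cytosine report; pos1 is 1-based", con)
  df <- data.frame(chrom = calls$chrom, pos1 = calls$pos + 1L,
                   strand = calls$strand, n_meth = calls$n_meth,
                   n_unmeth = calls$n_total - calls$n_meth,
                   context = calls$context,
                   p = signif(calls$p, 8), q = signif(calls$q, 8),
                   called = calls$called)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_cytosine_report
#' @export
read_cytosine_report <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  out <- data.frame(chrom = df$chrom, pos = df$pos1 - 1L, strand = df$strand,
                    n_meth = df$n_meth, n_total = df$n_meth + df$n_unmeth,
                    context = df$context, stringsAsFactors = FALSE)
  out$beta <- ifelse(out$n_total > 0, out$n_meth / out$n_total, NA_real_)
  out$p <- df$p
  out$q <- df$q
  out$called <- df$called
  class(out) <- c("methyl_calls", "data.frame")
  out
}

#' Write called sites as bedGraph (percent methylation)
#'
#' One line `chrom pos0 pos0+1 100*beta` per called site (bedGraph is
#' 0-based half-open).
#'
#' @param calls a `methyl_calls` data.frame.
#' @param path file path.
#' @export
write_bedgraph <- function(calls, path) {
  x <- calls[calls$called, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('track type=bedGraph name="methylation"', con)
  if (nrow(x))
    writeLines(sprintf("%s\t%d\t%d\t%.6g", x$chrom, x$pos, x$pos + 1L,
                       100 * x$beta), con)
  invisible(path)
}
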