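#' Simulate directional bisulfite-converted reads
#'
#' Fragments are drawn uniformly over the linear genome (no wraparound) and
#' assigned with equal probability to the original-top (OT) or
#' original-bottom (OB) strand of a directional bisulfite library. On the
#' molecule's strand, every unmethylated cytosine deaminates to T with
#' probability `conversion_rate`; a methylated cytosine (Bernoulli draw per
#' molecule at the site's methylation fraction) never converts and can only
#' read as non-C through a sequencing error. I.i.d. substitution errors at
#' `error_rate` are applied after conversion. OB reads are reported as
#' sequenced, i.e. in bottom-strand 5'->3' orientation.
#'
#' @param genome a [bs_genome()].
#' @param truth methylation-truth data.frame (`pos0`, `strand`, `fraction`),
#'   e.g. from [plant_methylome()]; may have zero rows.
#' @param coverage mean fold-coverage; the number of reads emitted is
#'   `ceiling(coverage * genome_length / read_length)`.
#' @param read_length read length in bp (must not exceed the genome length).
#' @param conversion_rate bisulfite conversion efficiency of unmethylated
#'   cytosines.
#' @param error_rate per-base substitution error rate.
#' @param seed integer seed (`NULL` = current stream).
#' @param quality_char constant FASTQ quality symbol; default `"?"`
#'   (Phred 30). Callers in this package do not use base qualities.
#' @return a data.frame of class `bs_reads` with columns `read_id`, `bases`,
#'   `qual`, `origin_pos` (0-based leftmost genome coordinate of the
#'   fragment) and `origin_frame` (`OT`/`OB`) — the truth sidecar.
#' @export
simulate_reads <- function(genome, truth, coverage = 30, read_length = 100L,
                           conversion_rate = 0.995, error_rate = 0.001,
                           seed = NULL, quality_char = "?") {
  genome <- as_genome(genome)
  L <- genome_length(genome)
  assert_scalar_number(coverage, "coverage", lo = .Machine$double.eps)
  assert_scalar_number(read_length, "read_length", lo = 1)
  assert_scalar_number(conversion_rate, "conversion_rate", lo = 0, hi = 1)
  assert_scalar_number(error_rate, "error_rate", lo = 0, hi = 1)
  if (read_length > L)
    stop("read_length exceeds genome length", call. = FALSE)

  fplus <- numeric(L); fminus <- numeric(L)
  if (nrow(truth)) {
    chars <- strsplit(genome$seq, "", fixed = TRUE)[[1]]
    plus <- truth$strand == "+"
    refp <- chars[truth$pos0[plus] + 1L]
    refm <- chars[truth$pos0[!plus] + 1L]
    if (any(refp != "C") || any(refm != "G"))
      stop("truth site whose reference base is not C on its strand",
           call. = FALSE)
    if (any(truth$fraction <= 0 | truth$fraction > 1))
      stop("truth fractions must be in (0, 1]", call. = FALSE)
    fplus[truth$pos0[plus] + 1L] <- truth$fraction[plus]
    fminus[truth$pos0[!plus] + 1L] <- truth$fraction[!plus]
  }

  n_reads <- as.integer(ceiling(coverage * L / read_length))
  sim <- with_seed(seed, {
    cpp_simulate_reads(genome$seq, fplus, fminus, n_reads,
                       as.integer(read_length), conversion_rate, error_rate)
  })
  out <- data.frame(
    read_id = sprintf("r%07d", seq_len(n_reads)),
    bases = as.character(sim$bases),
    qual = strrep(quality_char, read_length),
    origin_pos = sim$pos,
    origin_frame = c("OT", "OB")[sim$frame + 1L],
    stringsAsFactors = FALSE
  )
  class(out) <- c("bs_reads", "data.frame")
  out
}

#' Read / write FASTQ and the read-origin truth sidecar
#'
#' @param reads a `bs_reads` data.frame (or any data.frame with `read_id`,
#'   `bases`, `qual`).
#' @param path file path.
#' @return `read_fastq()` returns a data.frame with `read_id` and `bases`
#'   (qualities are not used downstream); writers return `path` invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$read_id
  q <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = q)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             bases = as.character(x), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' @rdname write_fastq
#' @export
write_read_origins <- function(reads, path) {
  write.table(reads[, c("read_id", "origin_pos", "origin_frame")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_read_origins <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
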