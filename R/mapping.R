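#' Build a reduced-alphabet bisulfite index
#'
#' Indexes every genomic k-mer of the two bisulfite-converted frames of the
#' top strand: the C->T-converted sequence (OT frame, where sequenced reads
#' from the original top strand live after conversion) and the
#' G->A-converted sequence (OB frame, mirroring conversion of the bottom
#' strand as seen in top-strand coordinates).
#'
#' @param genome a [bs_genome()] (or sequence string).
#' @param k seed length, 4..32 (default 16; two 16-mer seeds per 100 bp read
#'   tolerate interior mismatches cheaply).
#' @return an object of class `bs_index` holding the genome and an external
#'   pointer to the compiled index. The pointer is session-local: rebuild the
#'   index rather than serializing it.
#' @export
build_index <- function(genome, k = 16L) {
  genome <- as_genome(genome)
  assert_scalar_number(k, "k", lo = 4, hi = 32)
  structure(list(genome = genome, k = as.integer(k),
                 ptr = cpp_build_index(genome$seq, as.integer(k))),
            class = "bs_index")
}

#' @export
print.bs_index <- function(x, ...) {
  cat(sprintf("<bs_index> %s (%d bp), k = %d, frames: OT (C>T), OB (G>A)\n",
              x$genome$name, genome_length(x$genome), x$k))
  invisible(x)
}

#' Query an index k-mer (diagnostic)
#'
#' Returns the 0-based positions at which `kmer` occurs in the requested
#' converted frame of the reference. Mainly useful for tests and debugging.
#'
#' @param index a [build_index()] result.
#' @param kmer string of length `k` over A/C/G/T.
#' @param frame `"OT"` (C->T frame) or `"OB"` (G->A frame).
#' @return integer vector of 0-based positions (possibly empty).
#' @export
index_query <- function(index, kmer, frame = c("OT", "OB")) {
  frame <- match.arg(frame)
  as.integer(cpp_index_query(index$ptr, toupper(kmer), frame)$pos)
}

#' Map bisulfite reads by seeded, ungapped, bisulfite-aware alignment
#'
#' Each read is tried in both frames. For OT the read's C->T conversion is
#' seeded (first and last k-mer) into the C->T reference frame and scored
#' against the unconverted reference with the asymmetric bisulfite rule:
#' reference C with read T is free, but reference T with read C costs a
#' mismatch. For OB the reverse complement of the read is seeded into the
#' G->A frame and scored with reference G / read A free. The unique
#' candidate achieving the minimal mismatch count (and not exceeding
#' `max_mismatch`) wins; two or more candidates tied at the minimum give
#' `ambiguous` (never an arbitrary tie-break — ambiguous placements would
#' fabricate methylation evidence); no candidate within the budget gives
#' `unmapped`. Reads shorter than `k` are unmapped.
#'
#' @param index a [build_index()] result.
#' @param reads a `bs_reads` data.frame (columns `read_id`, `bases`), or a
#'   character vector of read sequences.
#' @param max_mismatch maximum bisulfite-aware mismatches; `NULL` (default)
#'   scales as `ceiling(0.02 * read_length)`, i.e. 2 per 100 bp.
#' @return data.frame of class `bs_alignments`: `read_id`, `chrom`, `pos`
#'   (0-based leftmost, NA unless unique), `strand` (`OT`/`OB`),
#'   `mismatches`, `status` (`unique`/`ambiguous`/`unmapped`), `bases`.
#' @export
map_reads <- function(index, reads, max_mismatch = NULL) {
  stopifnot(inherits(index, "bs_index"))
  if (is.character(reads))
    reads <- data.frame(read_id = sprintf("r%07d", seq_along(reads)),
                        bases = reads, stringsAsFactors = FALSE)
  bases <- toupper(reads$bases)
  n <- length(bases)
  lens <- nchar(bases)
  res <- data.frame(pos = rep(NA_integer_, n), frame = NA_integer_,
                    mismatches = NA_integer_, status = NA_integer_)
  for (len in unique(lens)) {
    sel <- which(lens == len)
    mm <- if (is.null(max_mismatch)) as.integer(ceiling(0.02 * len)) else
      as.integer(max_mismatch)
    res[sel, ] <- cpp_map_reads(index$ptr, bases[sel], mm)
  }
  out <- data.frame(
    read_id = reads$read_id,
    chrom = index$genome$name,
    pos = res$pos,
    strand = c("OT", "OB")[res$frame + 1L],
    mismatches = res$mismatches,
    status = c("unique", "ambiguous", "unmapped")[res$status + 1L],
    bases = bases,
    stringsAsFactors = FALSE
  )
  class(out) <- c("bs_alignments", "data.frame")
  out
}

#' @rdname map_reads
#' @param read a single read sequence (string).
#' @export
map_read <- function(index, read, max_mismatch = NULL) {
  map_reads(index, c(read), max_mismatch = max_mismatch)
}

#' Write / read minimal SAM
#'
#' Writes a minimal single-reference SAM: `@HD`/`@SQ` header, the 11
#' mandatory columns with CIGAR `<len>M`, plus tags `XG:Z:OT|OB` (bisulfite
#' frame) and `XT:Z:unique|ambiguous|unmapped`. SEQ is stored in reference
#' orientation (OB reads are reverse-complemented, FLAG 16), per SAM
#' convention; `read_sam()` restores the as-sequenced orientation.
#' Non-unique reads are emitted with FLAG 4 and no position so that the
#' record count matches the input read count.
#'
#' @param alignments a `bs_alignments` data.frame (with `bases`).
#' @param genome the reference [bs_genome()] (for the `@SQ` header).
#' @param path file path.
#' @return `read_sam()` returns a `bs_alignments` data.frame; `write_sam()`
#'   returns `path` invisibly.
#' @export
write_sam <- function(alignments, genome, path) {
  genome <- as_genome(genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", genome$name,
                       genome_length(genome))), con)
  uniq <- alignments$status == "unique"
  flag <- ifelse(!uniq, 4L, ifelse(alignments$strand == "OB", 16L, 0L))
  seqs <- alignments$bases
  ob <- uniq & alignments$strand == "OB"
  seqs[ob] <- revcomp(seqs[ob])
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tXG:Z:%s\tXT:Z:%s",
                   alignments$read_id, flag,
                   ifelse(uniq, genome$name, "*"),
                   ifelse(uniq, alignments$pos + 1L, 0L),
                   ifelse(uniq, 60L, 0L),
                   ifelse(uniq, sprintf("%dM", nchar(seqs)), "*"),
                   seqs,
                   ifelse(uniq, alignments$strand, "*"),
                   alignments$status)
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  tag <- function(prefix) {
    vapply(f, function(x) {
      hit <- x[startsWith(x, prefix)]
      if (length(hit)) sub(prefix, "", hit[1]) else NA_character_
    }, character(1))
  }
  flag <- as.integer(get(2))
  uniq <- !bitwAnd(flag, 4L)
  status <- tag("XT:Z:")
  status[is.na(status)] <- ifelse(uniq[is.na(status)], "unique", "unmapped")
  strand <- tag("XG:Z:")
  strand[strand == "*"] <- NA_character_
  strand[is.na(strand) & uniq] <- ifelse(bitwAnd(flag, 16L)[is.na(strand) & uniq] > 0,
                                         "OB", "OT")
  bases <- get(10)
  ob <- uniq & !is.na(strand) & strand == "OB"
  bases[ob] <- revcomp(bases[ob])
  out <- data.frame(
    read_id = get(1),
    chrom = ifelse(uniq, get(3), NA_character_),
    pos = ifelse(uniq, as.integer(get(4)) - 1L, NA_integer_),
    strand = strand,
    mismatches = NA_integer_,
    status = status,
    bases = bases,
    stringsAsFactors = FALSE
  )
  class(out) <- c("bs_alignments", "data.frame")
  out
}
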