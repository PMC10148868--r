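#' Genome container
#'
#' A minimal container for a single linear chromosome: a name and a sequence
#' over A/C/G/T (parsed genomes may additionally contain N). Streptomyces
#' chromosomes are linear, so no wraparound semantics exist anywhere in the
#' package.
#'
#' @param name chromosome identifier.
#' @param sequence DNA sequence as a single string.
#' @return an object of class `bs_genome` with fields `name`, `seq` and
#'   `topology` (always `"linear"`).
#' @export
bs_genome <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop("genome length must be >= 1", call. = FALSE)
  if (grepl("[^ACGTN]", sequence))
    stop("genome sequence contains characters outside {A,C,G,T,N}",
         call. = FALSE)
  structure(list(name = name, seq = sequence, topology = "linear"),
            class = "bs_genome")
}

#' @export
print.bs_genome <- function(x, ...) {
  cat(sprintf("<bs_genome> %s: %s bp (linear)\n", x$name,
              format(nchar(x$seq), big.mark = ",")))
  invisible(x)
}

#' @rdname bs_genome
#' @param genome a `bs_genome`.
#' @export
genome_length <- function(genome) nchar(as_genome(genome)$seq)

# Accept a bs_genome or a bare sequence string.
as_genome <- function(genome, name = "chr") {
  if (inherits(genome, "bs_genome")) genome else bs_genome(name, genome)
}

#' Generate a random genome with a target GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = `gc_fraction`/2 and
#' P(A) = P(T) = (1 - `gc_fraction`)/2. The default GC content of 0.70
#' matches the GC-rich chromosomes of streptomycetes.
#'
#' @param length genome length in bp (>= 1).
#' @param gc_fraction target GC fraction in `[0, 1]`.
#' @param seed integer seed; identical inputs and seed give byte-identical
#'   sequences. `NULL` uses the current RNG stream.
#' @param name chromosome name.
#' @return a [bs_genome()].
#' @export
#' @examples
#' g <- generate_genome(1000, gc_fraction = 0.7, seed = 1)
#' genome_length(g)
generate_genome <- function(length, gc_fraction = 0.70, seed = NULL,
                            name = "chr") {
  assert_scalar_number(length, "length", lo = 1)
  assert_scalar_number(gc_fraction, "gc_fraction", lo = 0, hi = 1)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq <- with_seed(seed, {
    paste(sample(names(p), size = length, replace = TRUE, prob = p),
          collapse = "")
  })
  bs_genome(name, seq)
}

#' Read / write a single-record FASTA genome
#'
#' Thin wrappers over Biostrings I/O restricted to the single linear
#' chromosome this package works with.
#'
#' @param genome a [bs_genome()].
#' @param path file path.
#' @return `read_fasta()` returns a [bs_genome()]; `write_fasta()` returns
#'   `path` invisibly.
#' @export
write_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  x <- Biostrings::DNAStringSet(genome$seq)
  names(x) <- genome$name
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1L)
    stop("expected a single-record FASTA, found ", length(x), " records",
         call. = FALSE)
  nm <- sub("\\s.*$", "", names(x)[1])
  bs_genome(nm, as.character(x[[1]]))
}

#' Observed GC fraction of a genome
#' @param genome a [bs_genome()] or sequence string.
#' @return numeric in `[0, 1]`.
#' @export
gc_fraction <- function(genome) {
  s <- as_genome(genome)$seq
  n <- nchar(s)
  gc <- nchar(gsub("[^GC]", "", s))
  gc / n
}
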