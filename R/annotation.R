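#' Generate a random non-overlapping gene annotation
#'
#' Places `n_genes` pairwise non-overlapping genes on the chromosome with at
#' least `min_gap` bp between consecutive genes, strands assigned at random.
#' The translation start is the first base of the start codon: the gene's
#' `start` on the + strand, `end - 1` on the - strand (0-based).
#'
#' @param genome a [bs_genome()] (or sequence string).
#' @param n_genes number of genes to place.
#' @param gene_length length-2 vector `(min, max)` of gene lengths in bp.
#' @param min_gap minimum gap between consecutive genes in bp.
#' @param seed integer seed (`NULL` = current RNG stream).
#' @return a data.frame with columns `gene_id`, `start` (0-based inclusive),
#'   `end` (0-based exclusive), `strand`, `translation_start` (0-based).
#'   Genes are returned in coordinate order.
#' @details Placement draws gene lengths uniformly, then distributes the
#'   remaining slack multinomially over the n+1 gaps (including the two
#'   chromosome ends). An infeasible packing (total gene length plus minimum
#'   gaps exceeding the genome) is an explicit error, never a silent
#'   truncation.
#' @export
generate_annotation <- function(genome, n_genes, gene_length = c(600L, 1800L),
                                min_gap = 200L, seed = NULL) {
  L <- genome_length(as_genome(genome))
  assert_scalar_number(n_genes, "n_genes", lo = 0)
  stopifnot(length(gene_length) == 2L, gene_length[1] <= gene_length[2],
            gene_length[1] >= 1)
  assert_scalar_number(min_gap, "min_gap", lo = 0)
  n_genes <- as.integer(n_genes)
  empty <- data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      translation_start = integer(0),
                      stringsAsFactors = FALSE)
  if (n_genes == 0L) return(empty)

  with_seed(seed, {
    lens <- sample(seq.int(gene_length[1], gene_length[2]), n_genes,
                   replace = TRUE)
    slack <- L - sum(lens) - (n_genes - 1L) * min_gap
    if (slack < 0)
      stop(sprintf(paste0("cannot place %d genes of %d-%d bp with min_gap ",
                          "%d in a %d bp genome"),
                   n_genes, gene_length[1], gene_length[2], min_gap, L),
           call. = FALSE)
    extra <- as.vector(rmultinom(1L, slack, rep(1, n_genes + 1L)))
    gaps <- c(extra[1L], extra[-1L][-n_genes] + min_gap)
    if (n_genes == 1L) gaps <- extra[1L]
    starts <- cumsum(gaps + c(0L, lens[-n_genes])) # start of each gene
    ends <- starts + lens
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    data.frame(
      gene_id = sprintf("gene_%04d", seq_len(n_genes)),
      start = as.integer(starts),
      end = as.integer(ends),
      strand = strand,
      translation_start = as.integer(ifelse(strand == "+", starts, ends - 1L)),
      stringsAsFactors = FALSE
    )
  })
}

#' Read / write gene annotations as GFF3
#'
#' `write_gff3()` exports `gene` features with `ID` attributes (1-based
#' inclusive coordinates, per GFF3). `read_gff3()` imports them back into the
#' package's 0-based representation and reconstructs the translation start
#' from the strand.
#'
#' @param annotation a data.frame as from [generate_annotation()].
#' @param genome a [bs_genome()] providing the seqname and length.
#' @param path file path.
#' @return `read_gff3()` returns the annotation data.frame; `write_gff3()`
#'   returns `path` invisibly.
#' @export
write_gff3 <- function(annotation, genome, path) {
  genome <- as_genome(genome)
  gr <- GenomicRanges::GRanges(
    seqnames = genome$name,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    strand = annotation$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- annotation$gene_id
  GenomeInfoDb::seqlengths(gr) <- genome_length(genome)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  strand <- as.character(BiocGenerics::strand(gr))
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids)) ids <- sprintf("gene_%04d", seq_along(gr))
  out <- data.frame(
    gene_id = as.character(ids),
    start = start0,
    end = end0,
    strand = strand,
    translation_start = as.integer(ifelse(strand == "+", start0, end0 - 1L)),
    stringsAsFactors = FALSE
  )
  out[order(out$start), , drop = FALSE]
}
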