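#' Anchored methylation motif specification
#'
#' A motif is a short DNA word with a designated anchor: the 1-based offset
#' of the methylated cytosine within the word. The package defaults model
#' the two consensus sequences recovered from the S. coelicolor upstream
#' methylome, GGCmCGG (word GGCCGG, anchor 4) and GCCmCG (word GCCCG,
#' anchor 4).
#'
#' @param sequence DNA word over A/C/G/T.
#' @param anchor 1-based offset of the methylated C; `sequence[anchor]` must
#'   be C.
#' @param fraction per-molecule methylation fraction planted at each
#'   instance's anchor, in `(0, 1]`.
#' @return an object of class `motif_spec`.
#' @export
#' @examples
#' motif_spec("GGCCGG", 4)
motif_spec <- function(sequence, anchor, fraction = 1.0) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("motif sequence must be over {A,C,G,T}", call. = FALSE)
  assert_scalar_number(anchor, "anchor", lo = 1, hi = nchar(sequence))
  anchor <- as.integer(anchor)
  if (substr(sequence, anchor, anchor) != "C")
    stop("motif anchor base must be C", call. = FALSE)
  assert_scalar_number(fraction, "fraction", lo = 0, hi = 1)
  if (fraction <= 0) stop("motif fraction must be in (0, 1]", call. = FALSE)
  structure(list(sequence = sequence, anchor = anchor, fraction = fraction),
            class = "motif_spec")
}

#' @rdname motif_spec
#' @export
default_motifs <- function() {
  list(motif_spec("GGCCGG", 4L), motif_spec("GCCCG", 4L))
}

#' @export
print.motif_spec <- function(x, ...) {
  m <- paste0(substr(x$sequence, 1, x$anchor - 1), "m",
              substr(x$sequence, x$anchor, nchar(x$sequence)))
  cat(sprintf("<motif_spec> %s (anchor %d, fraction %.2f)\n", m, x$anchor,
              x$fraction))
  invisible(x)
}

#' Plant a motif-anchored methylome into a genome
#'
#' For a random subset of genes (`genes_with_motif_fraction` of them), one
#' motif instance is written into the genome inside that gene's upstream
#' region (`up` bp before to `down` bp after the translation start,
#' strand-aware, replacing the existing bases), and the anchor cytosine is
#' recorded as a methylation-truth site on the gene's strand. Motifs are
#' assigned to selected genes in rotation, so the planted counts per motif
#' are as equal as possible. Background methylation then marks a random
#' subset of the remaining cytosines per CG/CHG/CHH context at the stated
#' rates.
#'
#' For a motif that is its own reverse complement the anchor cytosine on the
#' opposite strand is planted too (set `palindrome_both_strands = FALSE` to
#' disable). Neither default motif is palindromic — revcomp(GGCCGG) is
#' CCGGCC — so this only matters for user-supplied motifs.
#'
#' @param genome a [bs_genome()].
#' @param annotation data.frame from [generate_annotation()] / [read_gff3()].
#' @param motifs list of [motif_spec()]s; default [default_motifs()].
#' @param genes_with_motif_fraction fraction of genes receiving a planted
#'   motif instance.
#' @param background_rates named numeric: per-context fraction of (non-motif)
#'   cytosines methylated in the background, names among CG/CHG/CHH.
#' @param background_level per-molecule methylation fraction of background
#'   sites (default 1.0: constitutively methylated).
#' @param up,down upstream-region extent around the translation start, bp.
#' @param seed integer seed (`NULL` = current stream).
#' @param palindrome_both_strands plant the opposite-strand anchor of
#'   self-reverse-complementary motifs.
#' @return a list with elements
#'   \describe{
#'     \item{genome}{the edited [bs_genome()]}
#'     \item{truth}{data.frame `chrom, pos0, strand, fraction, provenance`
#'       (`motif-planted` or `background`), 0-based positions}
#'     \item{planted}{data.frame `gene_id, motif, anchor, start0, strand` of
#'       written motif instances (`start0` = leftmost genome coordinate)}
#'   }
#' @export
plant_methylome <- function(genome, annotation, motifs = default_motifs(),
                            genes_with_motif_fraction = 0.5,
                            background_rates = c(CG = 0.001, CHG = 0, CHH = 0),
                            background_level = 1.0, up = 500L, down = 100L,
                            seed = NULL, palindrome_both_strands = TRUE) {
  genome <- as_genome(genome)
  L <- genome_length(genome)
  assert_scalar_number(genes_with_motif_fraction, "genes_with_motif_fraction",
                       lo = 0, hi = 1)
  assert_scalar_number(background_level, "background_level", lo = 0, hi = 1)
  if (is.list(motifs) && inherits(motifs, "motif_spec")) motifs <- list(motifs)
  stopifnot(all(vapply(motifs, inherits, logical(1), "motif_spec")))
  bad <- setdiff(names(background_rates), c("CG", "CHG", "CHH"))
  if (length(bad))
    stop("unknown background context(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  with_seed(seed, {
    seq <- genome$seq
    truth <- list()
    planted <- list()
    occupied <- matrix(numeric(0), ncol = 2) # planted intervals [start, end)

    n_sel <- round(genes_with_motif_fraction * nrow(annotation))
    sel <- if (n_sel > 0) sample(nrow(annotation), n_sel) else integer(0)
    motif_of <- rep_len(seq_along(motifs), length(sel))

    for (i in seq_along(sel)) {
      gene <- annotation[sel[i], ]
      m <- motifs[[motif_of[i]]]
      len <- nchar(m$sequence)
      reg <- upstream_region(gene, up = up, down = down, genome_length = L)
      if (reg$end - reg$start < len)
        stop(sprintf("motif %s longer than upstream region of %s",
                     m$sequence, gene$gene_id), call. = FALSE)
      starts <- seq.int(reg$start, reg$end - len) # candidate leftmost starts
      if (nrow(occupied)) {
        free <- vapply(starts, function(s)
          all(s + len <= occupied[, 1] | s >= occupied[, 2]), logical(1))
        starts <- starts[free]
      }
      if (!length(starts)) {
        warning("no collision-free slot for a motif in upstream region of ",
                gene$gene_id, "; gene skipped")
        next
      }
      s <- if (length(starts) == 1L) starts else sample(starts, 1L)
      word <- if (gene$strand == "+") m$sequence else revcomp(m$sequence)
      substr(seq, s + 1L, s + len) <- word
      anchor0 <- if (gene$strand == "+") s + m$anchor - 1L else s + len - m$anchor
      truth[[length(truth) + 1L]] <- data.frame(
        pos0 = anchor0, strand = gene$strand, fraction = m$fraction,
        provenance = "motif-planted", stringsAsFactors = FALSE)
      if (palindrome_both_strands && m$sequence == revcomp(m$sequence)) {
        # opposite-strand anchor of a self-reverse-complementary motif:
        # mirror position within the planted word, opposite strand
        opp_pos <- if (gene$strand == "+") s + len - m$anchor else
          s + m$anchor - 1L
        truth[[length(truth) + 1L]] <- data.frame(
          pos0 = opp_pos, strand = if (gene$strand == "+") "-" else "+",
          fraction = m$fraction, provenance = "motif-planted",
          stringsAsFactors = FALSE)
      }
      planted[[length(planted) + 1L]] <- data.frame(
        gene_id = gene$gene_id, motif = m$sequence, anchor = m$anchor,
        start0 = s, strand = gene$strand, stringsAsFactors = FALSE)
      occupied <- rbind(occupied, c(s, s + len))
    }

    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(pos0 = integer(0), strand = character(0),
                 fraction = numeric(0), provenance = character(0),
                 stringsAsFactors = FALSE)

    # background methylation on the *edited* genome, per context
    edited <- bs_genome(genome$name, seq)
    rates <- background_rates[background_rates > 0]
    if (length(rates)) {
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      cand <- rbind(
        data.frame(pos0 = which(chars == "C") - 1L, strand = "+",
                   stringsAsFactors = FALSE),
        data.frame(pos0 = which(chars == "G") - 1L, strand = "-",
                   stringsAsFactors = FALSE))
      taken <- paste(truth$pos0, truth$strand)
      cand <- cand[!(paste(cand$pos0, cand$strand) %in% taken), , drop = FALSE]
      ctx <- classify_context(edited, cand$pos0, cand$strand)
      for (cx in names(rates)) {
        pool <- which(ctx == cx)
        n_bg <- round(rates[[cx]] * length(pool))
        if (n_bg < 1) next
        pick <- sample(pool, n_bg)
        truth <- rbind(truth, data.frame(
          pos0 = cand$pos0[pick], strand = cand$strand[pick],
          fraction = background_level, provenance = "background",
          stringsAsFactors = FALSE))
      }
    }

    truth <- truth[order(truth$pos0, truth$strand), , drop = FALSE]
    rownames(truth) <- NULL
    truth <- cbind(chrom = rep(genome$name, nrow(truth)), truth,
                   stringsAsFactors = FALSE)
    planted <- if (length(planted)) do.call(rbind, planted) else
      data.frame(gene_id = character(0), motif = character(0),
                 anchor = integer(0), start0 = integer(0),
                 strand = character(0), stringsAsFactors = FALSE)
    list(genome = edited, truth = truth, planted = planted)
  })
}

#' Read / write methylation ground truth
#'
#' TSV with header `chrom pos0 strand fraction provenance` (0-based
#' positions).
#'
#' @param truth truth data.frame (see [plant_methylome()]).
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  write.table(truth[, c("chrom", "pos0", "strand", "fraction", "provenance")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c("character", "integer", "character", "numeric",
                            "character"))
}
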