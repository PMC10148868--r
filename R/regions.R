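#' Strand-aware upstream region around a translation start
#'
#' The scanned window runs from `up` bp upstream of the putative translation
#' start site to `down` bp downstream of it (the translation-start base
#' counts as the first downstream base). With `p` the 0-based translation
#' start, a + strand gene gives `[p - up, p + down)` and a - strand gene the
#' mirrored `[p - down + 1, p + up + 1)` on forward coordinates. Regions are
#' clipped to the genome and flagged when clipping occurred.
#'
#' @param gene one annotation row (data.frame or list with `gene_id`,
#'   `strand`, `translation_start`).
#' @param up,down extent upstream/downstream of the translation start, bp.
#' @param genome_length chromosome length, bp.
#' @return one-row data.frame: `gene_id`, `start`, `end` (0-based half-open,
#'   forward coordinates), `strand`, `clipped`.
#' @export
#' @examples
#' # + strand gene whose start codon begins at 1-based position 1000:
#' upstream_region(list(gene_id = "g", strand = "+", translation_start = 999),
#'                 genome_length = 2000)  # [499, 1099)
upstream_region <- function(gene, up = 500L, down = 100L, genome_length) {
  p <- as.integer(gene$translation_start)
  if (gene$strand == "+") {
    start <- p - up; end <- p + down
  } else {
    start <- p - down + 1L; end <- p + up + 1L
  }
  cs <- max(start, 0L); ce <- min(end, as.integer(genome_length))
  data.frame(gene_id = gene$gene_id, start = as.integer(cs),
             end = as.integer(ce), strand = gene$strand,
             clipped = (cs != start || ce != end), stringsAsFactors = FALSE)
}

#' @rdname upstream_region
#' @param annotation full annotation data.frame.
#' @export
upstream_regions <- function(annotation, up = 500L, down = 100L,
                             genome_length) {
  if (nrow(annotation) == 0L)
    return(data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      clipped = logical(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(nrow(annotation)), function(i)
    upstream_region(annotation[i, ], up = up, down = down,
                    genome_length = genome_length)))
  rownames(out) <- NULL
  out
}

#' Genes with methylated cytosines in their upstream regions
#'
#' A gene is reported iff at least one called site (either strand) lies in
#' its upstream region; a site falling in two overlapping regions is
#' credited to both genes. With `motifs` supplied (a `motif_results` table
#' from [anchored_motif_discovery()] or a list of [motif_spec()]s), only
#' called sites whose strand-local anchored word matches one of the motifs
#' count — the consensus-sharing gene set, which is how a motif-defined gene
#' list is assembled from a methylome.
#'
#' @param calls a `methyl_calls` data.frame.
#' @param regions data.frame from [upstream_regions()].
#' @param motifs optional motif filter (see above).
#' @param genome required when `motifs` is given: the [bs_genome()] used to
#'   read each site's local sequence.
#' @return data.frame: `gene_id`, `n_sites`, `sites` (comma-separated
#'   `pos:strand`, 0-based).
#' @export
genes_with_methylated_upstream <- function(calls, regions, motifs = NULL,
                                           genome = NULL) {
  x <- calls[calls$called, , drop = FALSE]
  if (!is.null(motifs)) {
    if (is.null(genome))
      stop("`genome` is required for motif-filtered gene reporting",
           call. = FALSE)
    x <- x[site_matches_motif(x, genome, motifs), , drop = FALSE]
  }
  empty <- data.frame(gene_id = character(0), n_sites = integer(0),
                      sites = character(0), stringsAsFactors = FALSE)
  if (nrow(x) == 0L || nrow(regions) == 0L) return(empty)
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = x$pos + 1L, width = 1L),
    IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  if (length(hits) == 0L) return(empty)
  site_lab <- paste0(x$pos, ":", x$strand)[S4Vectors::queryHits(hits)]
  gene <- regions$gene_id[S4Vectors::subjectHits(hits)]
  agg <- split(site_lab, gene)
  out <- data.frame(gene_id = names(agg),
                    n_sites = unname(vapply(agg, length, integer(1))),
                    sites = unname(vapply(agg, paste, character(1),
                                          collapse = ",")),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Does each called site's strand-local sequence carry one of the motifs at
# its anchor? `motifs` is a motif_results data.frame (consensus/anchor) or a
# list of motif_spec.
site_matches_motif <- function(calls, genome, motifs) {
  genome <- as_genome(genome)
  if (is.data.frame(motifs)) {
    specs <- Map(function(s, a) list(sequence = s, anchor = a),
                 motifs$consensus, motifs$anchor)
  } else {
    if (inherits(motifs, "motif_spec")) motifs <- list(motifs)
    specs <- motifs
  }
  if (length(specs) == 0L) return(rep(FALSE, nrow(calls)))
  hit <- rep(FALSE, nrow(calls))
  for (m in specs) {
    k <- nchar(m$sequence); a <- m$anchor
    w <- site_words(genome, calls$pos, calls$strand, k, a)
    hit <- hit | (!is.na(w) & w == m$sequence)
  }
  hit
}

# The k-word on each site's own strand with the site at 1-based offset
# `anchor`; NA where the window leaves the genome.
site_words <- function(genome, pos, strand, k, anchor) {
  s <- as_genome(genome)$seq
  L <- nchar(s)
  from <- ifelse(strand == "+", pos - (anchor - 1L), pos - (k - anchor))
  ok <- from >= 0L & from + k <= L
  w <- rep(NA_character_, length(pos))
  w[ok] <- substring(s, from[ok] + 1L, from[ok] + k)
  minus <- ok & strand == "-"
  w[minus] <- revcomp(w[minus])
  w
}

#' Anchored consensus-motif discovery around called methylcytosines
#'
#' For every called site the local sequence is read on the site's own strand
#' (- strand sites are reverse-complemented, so motifs are reported in the
#' 5'->3' frame the methyltransferase sees). For each word length in
#' `k_values` and each anchor offset, the anchored k-word at the site is
#' tallied; its expected count is the number of usable sites times the
#' genome-wide frequency of that anchored word among cytosine positions
#' (both strands). Each candidate gets an exact binomial upper-tail p-value
#' and a BH q-value across all candidates.
#'
#' With the default `null = "context"`, the background word frequency is
#' conditioned on the CG/CHG/CHH context mix of the called sites: the
#' frequency is a mixture over per-context genome-wide frequencies weighted
#' by the observed context proportions. This matters whenever the methylome
#' is context-biased — against an unconditional all-cytosine null, any word
#' merely containing the favoured context (e.g. any `..CG..` word in a
#' CG-dominated methylome) shows spurious enrichment. For sites drawn
#' uniformly over all cytosines the two nulls coincide;
#' `null = "all_cytosines"` forces the unconditional version.
#'
#' Reported motifs are then chosen by greedy sequential masking, the
#' standard guard against the same planted sites resurfacing as shifted or
#' extended word variants: the most significant candidate passing the
#' filters (`q <= q_max`, support >= `min_support` among unexplained sites)
#' is reported, its supporting sites are removed, supports are recomputed,
#' and the cycle repeats. The final list is ranked by enrichment.
#'
#' @param calls a `methyl_calls` data.frame.
#' @param genome the [bs_genome()] the calls refer to.
#' @param k_values word lengths to scan (default 5 and 6).
#' @param flank bp of genomic context required on each side of a site; sites
#'   closer than `flank` to a chromosome end are skipped.
#' @param min_support minimum number of supporting sites for a reported
#'   motif.
#' @param q_max BH q-value cutoff.
#' @param null background model: `"context"` (default, context-matched) or
#'   `"all_cytosines"` (unconditional).
#' @return data.frame of class `motif_results`, ranked by enrichment:
#'   `consensus`, `anchor` (1-based offset of the methylated C), `k`,
#'   `support`, `expected`, `enrichment`, `p`, `q`.
#' @export
anchored_motif_discovery <- function(calls, genome, k_values = c(5L, 6L),
                                     flank = 10L, min_support = 5L,
                                     q_max = 0.05,
                                     null = c("context", "all_cytosines")) {
  null <- match.arg(null)
  genome <- as_genome(genome)
  L <- genome_length(genome)
  empty <- data.frame(consensus = character(0), anchor = integer(0),
                      k = integer(0), support = integer(0),
                      expected = numeric(0), enrichment = numeric(0),
                      p = numeric(0), q = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("motif_results", "data.frame")
  x <- calls[calls$called, , drop = FALSE]
  x <- x[x$pos >= flank & x$pos <= L - 1L - flank, , drop = FALSE]
  n_sites <- nrow(x)
  if (n_sites == 0L) return(empty)
  stopifnot(max(k_values) <= flank + 1L)

  # context mixture weights of the sites being explained
  ctx_levels <- c("CG", "CHG", "CHH", "undefined")
  site_ctx <- if (!is.null(x$context)) x$context else
    classify_context(genome, x$pos, x$strand)
  pi_ctx <- as.numeric(table(factor(site_ctx, levels = ctx_levels))) / n_sites

  # candidate table: one row per (word, anchor) observed at >= 1 site,
  # with the list of supporting site indices
  cand <- list()
  for (k in k_values) {
    for (a in seq_len(k)) {
      w <- site_words(genome, x$pos, x$strand, k, a)
      by_word <- split(seq_len(n_sites), w)
      bg <- cpp_anchored_kmer_counts(genome$seq, as.integer(k),
                                     as.integer(a))
      totals <- attr(bg, "totals")
      codes <- vapply(names(by_word), kmer_code, numeric(1))
      rows <- bg[codes + 1L, , drop = FALSE] # NA codes give NA rows
      if (null == "all_cytosines") {
        freq <- rowSums(rows) / sum(totals)
      } else {
        per_ctx <- sweep(rows, 2, pmax(totals, 1), "/")
        per_ctx[, totals == 0] <- 0
        freq <- as.numeric(per_ctx %*% pi_ctx)
        freq[is.na(rowSums(rows))] <- NA_real_
      }
      cand[[length(cand) + 1L]] <- list(
        words = names(by_word), k = k, anchor = a, sites = by_word,
        freq = freq)
    }
  }
  words <- unlist(lapply(cand, `[[`, "words"), use.names = FALSE)
  ks <- unlist(lapply(cand, function(cc) rep(cc$k, length(cc$words))))
  anchors <- unlist(lapply(cand, function(cc) rep(cc$anchor, length(cc$words))))
  freqs <- unlist(lapply(cand, `[[`, "freq"), use.names = FALSE)
  sites <- unlist(lapply(cand, `[[`, "sites"), recursive = FALSE,
                  use.names = FALSE)
  keep <- !is.na(freqs) # words with N (parsed genomes) are not testable
  words <- words[keep]; ks <- ks[keep]; anchors <- anchors[keep]
  freqs <- freqs[keep]; sites <- sites[keep]
  if (!length(words)) return(empty)
  support0 <- vapply(sites, length, integer(1))
  p0 <- binom_tail_p(support0, n_sites, pmin(freqs, 1))
  # BH across the full family of valid anchored words (anchor base C fixed,
  # so 4^(k-1) words per anchor), not merely the observed ones: conditioning
  # the family on support >= 1 makes the correction anticonservative
  m_family <- sum(vapply(k_values, function(k) k * 4^(k - 1), numeric(1)))
  q0 <- p.adjust(p0, method = "BH", n = max(m_family, length(p0)))

  # greedy sequential masking over sites
  active <- rep(TRUE, n_sites)
  eligible <- q0 <= q_max
  picked <- list()
  repeat {
    n_active <- sum(active)
    if (n_active == 0L) break
    supp <- vapply(sites, function(s) sum(active[s]), integer(1))
    ok <- eligible & supp >= min_support
    p_now <- rep(1, length(supp))
    p_now[ok] <- binom_tail_p(supp[ok], n_active, pmin(freqs[ok], 1))
    # a candidate must stay significant on the still-unexplained sites
    # (otherwise its initial significance was borrowed from already-reported
    # motifs' sites), and family-corrected: each round re-tests the whole
    # anchored-word family on the masked site set
    ok <- ok & p_now <= q_max / m_family
    if (!any(ok)) break
    best <- which(ok)[order(p_now[ok], -supp[ok], words[ok])[1L]]
    expected <- n_active * freqs[best]
    picked[[length(picked) + 1L]] <- data.frame(
      consensus = words[best], anchor = anchors[best], k = ks[best],
      support = supp[best], expected = expected,
      enrichment = if (expected > 0) supp[best] / expected else Inf,
      p = p_now[best], q = q0[best], stringsAsFactors = FALSE)
    active[sites[[best]]] <- FALSE
    eligible[best] <- FALSE
  }
  if (!length(picked)) return(empty)
  out <- do.call(rbind, picked)
  out <- out[order(-out$enrichment, out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motif_results", "data.frame")
  out
}

# 2-bit integer code of a DNA word (A=0 C=1 G=2 T=3, first base most
# significant); NA-safe for words containing other characters.
kmer_code <- function(w) {
  v <- match(strsplit(w, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1
  if (anyNA(v)) return(NA_real_)
  sum(v * 4^(rev(seq_along(v)) - 1))
}

#' Write regions/genes/motif tables as TSV
#'
#' Plain TSV writers for the regions-module outputs (stated 0-based
#' half-open coordinates for regions).
#'
#' @param x the table to write.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
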