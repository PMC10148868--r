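#' Fixed-window methylation profile along the chromosome
#'
#' Tiles `[0, genome_length)` with non-overlapping windows of `window` bp
#' (the last window may be short) and assigns each called site at position
#' `p` to window `floor(p / window)`. Both a count (`n_called`) and a level
#' (`mean_beta` over called sites, NA where none) are reported, since a
#' "methylation level per window" can mean either.
#'
#' @param calls a `methyl_calls` data.frame (rows with `called == TRUE` are
#'   profiled; a table without a `called` column is used as-is).
#' @param genome_length chromosome length in bp.
#' @param window window width in bp (default 250 kbp).
#' @return data.frame of class `window_profile` with `start`, `end` (0-based
#'   half-open), `n_called`, `mean_beta`; attributes `window` and
#'   `genome_length`.
#' @export
window_profile <- function(calls, genome_length, window = 250000L) {
  assert_scalar_number(window, "window", lo = 1)
  assert_scalar_number(genome_length, "genome_length", lo = 1)
  x <- if (!is.null(calls$called)) calls[calls$called, , drop = FALSE]
       else calls
  if (nrow(x) && any(x$pos >= genome_length | x$pos < 0))
    stop("call position outside [0, genome_length)", call. = FALSE)
  n_win <- as.integer(ceiling(genome_length / window))
  starts <- as.numeric(window) * (seq_len(n_win) - 1)
  ends <- pmin(starts + window, genome_length)
  idx <- floor(x$pos / window) + 1L
  n_called <- tabulate(idx, nbins = n_win)
  mean_beta <- rep(NA_real_, n_win)
  if (nrow(x)) {
    sums <- tapply(x$beta, factor(idx, levels = seq_len(n_win)), mean)
    mean_beta <- as.numeric(sums)
  }
  out <- data.frame(start = starts, end = ends, n_called = n_called,
                    mean_beta = mean_beta)
  attr(out, "window") <- window
  attr(out, "genome_length") <- genome_length
  class(out) <- c("window_profile", "data.frame")
  out
}

#' Compare two window profiles (e.g. two timepoints)
#'
#' Per-window differences between two samples profiled on the identical
#' window grid, with an optional overlaid two-track plot (both samples'
#' per-window called-site counts along the chromosome).
#'
#' @param profile_a,profile_b `window_profile` objects on the same grid.
#' @param labels length-2 character, track labels for the plot.
#' @param plot_file optional PDF path for the overlay figure.
#' @return data.frame `start`, `end`, `d_n_called` (A - B), `d_mean_beta`
#'   (A - B; NA-propagating).
#' @export
compare_samples <- function(profile_a, profile_b,
                            labels = c("sample A", "sample B"),
                            plot_file = NULL) {
  if (!identical(profile_a$start, profile_b$start) ||
      !identical(profile_a$end, profile_b$end))
    stop("window grids differ between the two profiles", call. = FALSE)
  out <- data.frame(
    start = profile_a$start, end = profile_a$end,
    d_n_called = profile_a$n_called - profile_b$n_called,
    d_mean_beta = profile_a$mean_beta - profile_b$mean_beta
  )
  if (!is.null(plot_file)) {
    pdf(plot_file, width = 9, height = 4)
    on.exit(dev.off())
    mid <- (profile_a$start + profile_a$end) / 2 / 1e6
    ylim <- range(c(profile_a$n_called, profile_b$n_called))
    plot(mid, profile_a$n_called, type = "l", col = "red3", ylim = ylim,
         xlab = "chromosome position (Mbp)", ylab = "called mC per window",
         main = sprintf("methylation along the chromosome (%g kbp windows)",
                        attr(profile_a, "window") / 1000))
    lines(mid, profile_b$n_called, col = "green4")
    legend("topright", legend = labels, col = c("red3", "green4"), lty = 1,
           bty = "n")
  }
  out
}

#' Per-site track of called cytosines
#'
#' Writes called sites as BED6 (0-based half-open, strand in column 6, score
#' = round(100 * beta), name = context) and optionally draws a
#' genome-coordinate scatter of the sites.
#'
#' @param calls a `methyl_calls` data.frame.
#' @param bed_file optional BED output path.
#' @param plot_file optional PDF path for the position scatter.
#' @return invisibly, the called subset as a data.frame (`chrom`, `pos`,
#'   `strand`, `beta`, `context`).
#' @export
site_track <- function(calls, bed_file = NULL, plot_file = NULL) {
  x <- calls[calls$called, , drop = FALSE]
  if (!is.null(bed_file)) {
    if (nrow(x)) {
      gr <- GenomicRanges::GRanges(
        seqnames = x$chrom,
        ranges = IRanges::IRanges(start = x$pos + 1L, width = 1L),
        strand = x$strand)
      S4Vectors::mcols(gr)$name <- x$context
      S4Vectors::mcols(gr)$score <- round(100 * x$beta)
      rtracklayer::export(gr, bed_file, format = "bed")
    } else {
      file.create(bed_file)
    }
  }
  if (!is.null(plot_file)) {
    pdf(plot_file, width = 9, height = 2.5)
    plot(x$pos / 1e6, rep(1, nrow(x)), pch = "|", cex = 0.8, yaxt = "n",
         ylab = "", xlab = "chromosome position (Mbp)",
         main = "called methylated cytosines")
    dev.off()
  }
  invisible(x[, c("chrom", "pos", "strand", "beta", "context")])
}

#' Read a BED6 site track back into positions/strands
#' @param path BED file path.
#' @return data.frame `chrom`, `pos` (0-based), `strand`.
#' @export
read_site_track <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             pos = BiocGenerics::start(gr) - 1L,
             strand = as.character(BiocGenerics::strand(gr)),
             stringsAsFactors = FALSE)
}
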