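# Independent brute-force oracles. These deliberately avoid the package's
# compiled code paths: reverse complements go through Biostrings, searches
# are exhaustive scans, tail probabilities are direct summations.

# context of (pos, strand) by explicit 3-mer extraction + reverse complement
oracle_context <- function(seq, pos, strand) {
  L <- nchar(seq)
  vapply(seq_along(pos), function(i) {
    p <- pos[i]
    trimer <- if (strand[i] == "+") {
      if (p + 2 > L - 1) return("undefined")
      substr(seq, p + 1, p + 3)
    } else {
      if (p - 2 < 0) return("undefined")
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(seq, p - 1, p + 1))))
    }
    ch <- strsplit(trimer, "")[[1]]
    if (any(!ch %in% c("A", "C", "G", "T"))) return("undefined")
    if (ch[2] == "G") "CG" else if (ch[3] == "G") "CHG" else "CHH"
  }, character(1))
}

# exhaustive position x frame scan mapper; returns a closure over a genome
# so the per-genome window matrices are built once
make_scan_oracle <- function(seq, read_len) {
  L <- nchar(seq)
  gch <- strsplit(seq, "")[[1]]
  npos <- L - read_len + 1L
  G <- vapply(seq_len(read_len),
              function(j) gch[seq_len(npos) + j - 1L], character(npos))
  isC <- G == "C"
  isG <- G == "G"
  function(read, max_mm) {
    r <- strsplit(read, "")[[1]]
    Rm <- matrix(r, nrow = npos, ncol = read_len, byrow = TRUE)
    mm_ot <- rowSums(!(G == Rm | (isC & Rm == "T")))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(read)))
    Cm <- matrix(strsplit(rc, "")[[1]], nrow = npos, ncol = read_len,
                 byrow = TRUE)
    mm_ob <- rowSums(!(G == Cm | (isG & Cm == "A")))
    best <- min(mm_ot, mm_ob)
    if (best > max_mm)
      return(list(status = "unmapped", pos = NA, frame = NA))
    n_best <- sum(mm_ot == best) + sum(mm_ob == best)
    if (n_best > 1L)
      return(list(status = "ambiguous", pos = NA, frame = NA))
    if (any(mm_ot == best))
      list(status = "unique", pos = which(mm_ot == best) - 1L, frame = "OT")
    else
      list(status = "unique", pos = which(mm_ob == best) - 1L, frame = "OB")
  }
}

# direct binomial upper-tail summation P(X >= m | n, eps)
oracle_binom_tail <- function(m, n, eps) {
  if (m <= 0) return(1)
  k <- m:n
  sum(choose(n, k) * eps^k * (1 - eps)^(n - k))
}

# pairwise interval-overlap / gap checker (0-based half-open intervals)
intervals_ok <- function(start, end, min_gap = 0) {
  o <- order(start)
  s <- start[o]; e <- end[o]
  n <- length(s)
  if (n < 2L) return(TRUE)
  all(s[-1] - e[-n] >= min_gap)
}
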