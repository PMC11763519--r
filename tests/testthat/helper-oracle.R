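# Independent oracles used across the suite.  They deliberately avoid the
# package's vectorized code paths: the distance is recomputed from a local
# copy of the 1974 property table and the screen is a literal pairwise
# enumeration.

oracle_props <- list(
  S = c(1.42, 9.2, 32),    R = c(0.65, 10.5, 124), L = c(0, 4.9, 111),
  P = c(0.39, 8.0, 32.5),  T = c(0.71, 8.6, 61),   A = c(0, 8.1, 31),
  V = c(0, 5.9, 84),       G = c(0.74, 9.0, 3),    I = c(0, 5.2, 111),
  F = c(0, 5.2, 132),      Y = c(0.20, 6.2, 136),  C = c(2.75, 5.5, 55),
  H = c(0.58, 10.4, 96),   Q = c(0.89, 10.5, 85),  N = c(1.33, 11.6, 56),
  K = c(0.33, 11.3, 119),  D = c(1.38, 13.0, 54),  E = c(0.92, 12.3, 83),
  M = c(0, 5.7, 105),      W = c(0.13, 5.4, 170))

oracle_dist <- function(a, b) {
  pa <- oracle_props[[a]]
  pb <- oracle_props[[b]]
  50.723 * sqrt(1.833 * (pa[1] - pb[1])^2 + 0.1018 * (pa[2] - pb[2])^2 +
                  0.000399 * (pa[3] - pb[3])^2)
}

# literal per-site enumeration of foreground/background mean pairwise
# distances over the usable (non-gap, non-X) residues of a character matrix
brute_site_means <- function(M, column, fg, bg) {
  usable <- function(ids) {
    ch <- M[ids, column]
    ch[!ch %in% c("-", "X")]
  }
  enum <- function(res) {
    n <- length(res)
    if (n < 2) {
      return(numeric(0))
    }
    d <- c()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- c(d, oracle_dist(res[i], res[j]))
      }
    }
    d
  }
  fgd <- enum(usable(fg))
  bgd <- enum(usable(bg))
  list(fgMean = if (length(fgd)) mean(fgd) else NA_real_,
       bgMean = if (length(bgd)) mean(bgd) else NA_real_,
       nFgPairs = length(fgd), nBgPairs = length(bgd))
}

# random small alignment over the full alphabet incl. gaps, as a named
# character vector of aligned strings
random_small_alignment <- function(nseq, width, gapProb = 0.1) {
  letters20 <- names(oracle_props)
  chars <- sample(c(letters20, "-"), nseq * width, replace = TRUE,
                  prob = c(rep((1 - gapProb) / 20, 20), gapProb))
  M <- matrix(chars, nrow = nseq)
  M[1, M[1, ] == "-"] <- "A"  # keep the reference record gap-free
  stats::setNames(apply(M, 1, paste0, collapse = ""),
                  c("REF", paste0("S", seq_len(nseq - 1))))
}
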