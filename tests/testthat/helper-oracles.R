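# Independent oracles used across the suite. Kept deliberately naive:
# direct enumeration and position-by-position arithmetic, never calls into
# the code paths they check.

# brute-force one-sided enrichment p-value: enumerate all ways of drawing
# n_fg region labels from the pooled population of k successes and
# N - k failures, and sum the probability of seeing >= k_fg successes
# in the foreground draw
brute_force_enrichment_p <- function(k_fg, n_fg, k_ctrl, n_ctrl) {
  K <- k_fg + k_ctrl
  N <- n_fg + n_ctrl
  total <- choose(N, n_fg)
  num <- 0
  for (j in seq(k_fg, min(K, n_fg))) {
    num <- num + choose(K, j) * choose(N - K, n_fg - j)
  }
  num / total
}

# position-by-position log-odds sum, floored like the implementation
brute_force_log_odds <- function(mat, background, site, eps = 1e-4) {
  bases <- strsplit(site, "")[[1]]
  total <- 0
  for (i in seq_along(bases)) {
    p <- max(mat[bases[i], i], eps)
    total <- total + log2(p / background[bases[i]])
  }
  unname(total)
}

# naive exact-match scan of a consensus on both strands (0-based starts)
naive_consensus_scan <- function(seq, consensus) {
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                 collapse = ""))
  L <- nchar(consensus)
  hits <- list()
  for (i in seq_len(nchar(seq) - L + 1)) {
    w <- substring(seq, i, i + L - 1)
    if (w == consensus)
      hits[[length(hits) + 1L]] <- data.frame(start = i - 1L, strand = "+")
    if (w == rc(consensus))
      hits[[length(hits) + 1L]] <- data.frame(start = i - 1L, strand = "-")
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(0), strand = character(0)))
  do.call(rbind, hits)
}

revcomp_str <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent bisection for the mass-balance root, to high precision
bisect_pfree <- function(K, omega, ptot, dtot, iter = 300) {
  frac_bound <- function(p) {
    q <- K * p
    Z <- 1 + 2 * q + omega * q^2
    (2 * q + 2 * omega * q^2) / Z
  }
  g <- function(p) p + dtot * frac_bound(p) - ptot
  lo <- 0; hi <- ptot
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# small TRANSFAC fixture: two records, one with a trailing consensus column
transfac_fixture <- function() {
  c("ID motif_acgt",
    "P0 A C G T",
    "01 10 0 0 0",
    "02 0 10 0 0",
    "03 0 0 10 0",
    "04 0 0 0 10",
    "//",
    "ID sox_half",
    "XX",
    "P0 A C G T",
    "01 8 1 1 0 A",
    "02 0 9 0 1 C",
    "03 9 0 1 0 A",
    "04 10 0 0 0 A",
    "05 1 0 0 9 T",
    "06 0 0 10 0 G",
    "//")
}
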