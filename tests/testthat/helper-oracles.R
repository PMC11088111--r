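# Independent oracles. These deliberately avoid the package's vectorised
# frequency-count path: diversity is computed by comparing haplotype pairs,
# FST from a scalar per-site transcription of the Weir & Cockerham (1984)
# two-population estimator, and the hypergeometric tail by explicit
# choose() sums.

# sites x (2N) haplotype allele matrix (NA = missing), pop-ordered columns
hap_matrix <- function(x, sample_idx) {
  S <- length(x$pos0)
  h <- matrix(NA_integer_, S, 2L * length(sample_idx))
  h[, seq(1L, ncol(h), 2L)] <- x$gt1[, sample_idx, drop = FALSE]
  h[, seq(2L, ncol(h), 2L)] <- x$gt2[, sample_idx, drop = FALSE]
  h
}

# per-site usable flag replicated from first principles: invariant or
# single-base biallelic SNP
oracle_usable <- function(x) {
  nchar(x$ref) == 1L & (x$alt == "" | (nchar(x$alt) == 1L))
}

# all-pairs within-population mismatch and comparison counts per window
oracle_pi <- function(x, sample_idx, win_of) {
  h <- hap_matrix(x, sample_idx)
  use <- oracle_usable(x)
  nw <- max(win_of, na.rm = TRUE)
  num <- den <- numeric(nw)
  for (a in seq_len(ncol(h) - 1L)) for (b in (a + 1L):ncol(h)) {
    ok <- use & !is.na(h[, a]) & !is.na(h[, b]) & !is.na(win_of)
    if (!any(ok)) next
    d <- (h[ok, a] != h[ok, b])
    num <- num + tabulate(win_of[ok][d], nw)
    den <- den + tabulate(win_of[ok], nw)
  }
  list(num = num, den = den, pi = ifelse(den > 0, num / den, NA_real_))
}

# all cross-population haplotype pairs
oracle_dxy <- function(x, idx1, idx2, win_of) {
  h1 <- hap_matrix(x, idx1); h2 <- hap_matrix(x, idx2)
  use <- oracle_usable(x)
  nw <- max(win_of, na.rm = TRUE)
  num <- den <- numeric(nw)
  for (a in seq_len(ncol(h1))) for (b in seq_len(ncol(h2))) {
    ok <- use & !is.na(h1[, a]) & !is.na(h2[, b]) & !is.na(win_of)
    if (!any(ok)) next
    d <- (h1[ok, a] != h2[ok, b])
    num <- num + tabulate(win_of[ok][d], nw)
    den <- den + tabulate(win_of[ok], nw)
  }
  list(num = num, den = den, dxy = ifelse(den > 0, num / den, NA_real_))
}

# scalar Weir & Cockerham (1984) a, b, c for one biallelic site, two pops;
# g1_*, g2_* are the two allele vectors of each population's genotypes
oracle_wc_site <- function(g1_p1, g2_p1, g1_p2, g2_p2) {
  called1 <- !is.na(g1_p1); called2 <- !is.na(g1_p2)
  n1 <- sum(called1); n2 <- sum(called2)
  if (n1 < 2 || n2 < 2) return(c(a = 0, b = 0, c = 0))
  p1 <- sum(g1_p1[called1] == 1) + sum(g2_p1[called1] == 1)
  p2 <- sum(g1_p2[called2] == 1) + sum(g2_p2[called2] == 1)
  p1 <- p1 / (2 * n1); p2 <- p2 / (2 * n2)
  h1 <- sum(g1_p1[called1] != g2_p1[called1]) / n1
  h2 <- sum(g1_p2[called2] != g2_p2[called2]) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a = a, b = b, c = hbar / 2)
}

oracle_fst_window <- function(x, idx1, idx2, win_of) {
  use <- oracle_usable(x) & x$alt != ""
  nw <- max(win_of, na.rm = TRUE)
  A <- ABC <- numeric(nw)
  for (s in which(use & !is.na(win_of))) {
    abc <- oracle_wc_site(x$gt1[s, idx1], x$gt2[s, idx1],
                          x$gt1[s, idx2], x$gt2[s, idx2])
    A[win_of[s]] <- A[win_of[s]] + abc["a"]
    ABC[win_of[s]] <- ABC[win_of[s]] + sum(abc)
  }
  ifelse(ABC != 0, A / ABC, NA_real_)
}

# explicit hypergeometric upper tail by choose() sums
oracle_hyper_tail <- function(k, n, K, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# explicit double-loop mean pairwise p-distance
oracle_pdist <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow(m))
  n <- nrow(m); tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- ok[i, ] & ok[j, ]
    tot <- tot + sum(m[i, both] != m[j, both]) / sum(both)
    np <- np + 1
  }
  tot / np
}
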