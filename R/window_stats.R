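#' Tile contigs with fixed nonoverlapping windows
#'
#' @param contig_lengths named numeric vector of contig lengths (bp).
#' @param size window size in bp (the genome scans here use 5000).
#' @return data.table with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `label`; the last window of each contig is truncated at
#'   the contig end.
#' @export
make_windows <- function(contig_lengths, size = 5000L) {
  if (length(size) != 1L || !is.finite(size) || size < 1)
    stop("window size must be a positive integer")
  size <- as.integer(size)
  out <- rbindlist(lapply(names(contig_lengths), function(ch) {
    len <- as.integer(contig_lengths[[ch]])
    if (len < 1L) return(NULL)
    s <- seq.int(0L, len - 1L, by = size)
    data.table(chrom = ch, start = s, end = pmin(s + size, len))
  }))
  out[, label := sprintf("%s:%d-%d", chrom, start, end)]
  out[]
}

# Per-population allele and genotype tallies for every site.
# Returns, per population: n (called alleles), c_alt, n_ind (called diploids),
# het (observed heterozygote count). Multiallelic and indel sites yield zero
# everywhere (they are excluded from all statistics, with a count attribute).
pop_site_tallies <- function(x, idx) {
  g1 <- x$gt1[, idx, drop = FALSE]
  g2 <- x$gt2[, idx, drop = FALSE]
  called <- !is.na(g1)
  n_ind <- rowSums(called)
  c_alt <- rowSums(g1 == 1L, na.rm = TRUE) + rowSums(g2 == 1L, na.rm = TRUE)
  het <- rowSums(g1 != g2, na.rm = TRUE)
  list(n = 2 * n_ind, c_alt = c_alt, n_ind = n_ind, het = het)
}

usable_site_mask <- function(x) {
  nchar(x$ref) == 1L & (x$alt == "" | nchar(x$alt) == 1L)
}

#' Per-site building blocks of pi, dxy and Weir-Cockerham FST
#'
#' For each site and each of exactly two populations, computes the
#' missing-data-aware numerators and denominators of nucleotide diversity
#' (within-population mismatch pairs over called-allele pairs), divergence
#' (between-population mismatch pairs over cross pairs), and the diploid
#' two-population Weir & Cockerham (1984) variance components a, b, c.
#' Sites that are neither biallelic SNPs nor invariant (multiallelic, indel)
#' contribute zero everywhere; sites where a population has fewer than 2
#' called alleles contribute nothing to that population's pi; dxy requires
#' at least 1 called allele on each side; the WC components require at least
#' 2 called diploid genotypes in both populations.
#'
#' @param x an [allsites()] object.
#' @param popmap a [population_map()] with exactly two populations whose
#'   samples all appear in `x`.
#' @return data.table, one row per site, with columns `chrom`, `pos0`,
#'   `pi_num_<pop>`, `pi_den_<pop>`, `dxy_num`, `dxy_den`, `wc_a`, `wc_abc`,
#'   `usable`; attribute `n_excluded` counts multiallelic/indel sites.
#' @export
site_counts <- function(x, popmap) {
  stopifnot(inherits(x, "allsites"), inherits(popmap, "popmap"))
  pops <- attr(popmap, "pops")
  if (length(pops) != 2L)
    stop("site_counts requires exactly two populations, got ",
         length(pops))
  missing_s <- setdiff(names(popmap), x$samples)
  if (length(missing_s))
    stop("popmap samples absent from data: ",
         paste(missing_s, collapse = ", "))
  p1 <- names(pops)[1]; p2 <- names(pops)[2]
  i1 <- match(pops[[1]], x$samples)
  i2 <- match(pops[[2]], x$samples)

  ok <- usable_site_mask(x)
  t1 <- pop_site_tallies(x, i1)
  t2 <- pop_site_tallies(x, i2)

  z <- function(v, cond) { v[!cond] <- 0; v }
  pi_parts <- function(t) {
    use <- ok & t$n >= 2
    num <- z((t$n - t$c_alt) * t$c_alt, use)
    den <- z(t$n * (t$n - 1) / 2, use)
    list(num = num, den = den)
  }
  w1 <- pi_parts(t1); w2 <- pi_parts(t2)

  use_d <- ok & t1$n >= 1 & t2$n >= 1
  dxy_num <- z((t1$n - t1$c_alt) * t2$c_alt +
                 t1$c_alt * (t2$n - t2$c_alt), use_d)
  dxy_den <- z(t1$n * t2$n, use_d)

  # Weir & Cockerham (1984) diploid two-population components
  use_w <- ok & t1$n_ind >= 2 & t2$n_ind >= 2
  n1 <- t1$n_ind; n2 <- t2$n_ind
  pf1 <- ifelse(t1$n > 0, t1$c_alt / t1$n, 0)
  pf2 <- ifelse(t2$n > 0, t2$c_alt / t2$n, 0)
  h1 <- ifelse(n1 > 0, t1$het / n1, 0)
  h2 <- ifelse(n2 > 0, t2$het / n2, 0)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * pf1 + n2 * pf2) / (r * nbar)
  s2 <- (n1 * (pf1 - pbar)^2 + n2 * (pf2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a <- z(a, use_w); b <- z(b, use_w); cc <- z(cc, use_w)
  a[!is.finite(a)] <- 0; b[!is.finite(b)] <- 0; cc[!is.finite(cc)] <- 0

  out <- data.table(chrom = x$chrom, pos0 = x$pos0,
                    pi_num_1 = w1$num, pi_den_1 = w1$den,
                    pi_num_2 = w2$num, pi_den_2 = w2$den,
                    dxy_num = dxy_num, dxy_den = dxy_den,
                    wc_a = a, wc_abc = a + b + cc,
                    usable = ok)
  setnames(out,
           c("pi_num_1", "pi_den_1", "pi_num_2", "pi_den_2"),
           c(paste0("pi_num_", p1), paste0("pi_den_", p1),
             paste0("pi_num_", p2), paste0("pi_den_", p2)))
  attr(out, "pops") <- c(p1, p2)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

# Assign each site to the window containing it (windows assumed disjoint).
assign_windows <- function(chrom, pos0, windows) {
  q <- IRanges::IRanges(pos0 + 1L, pos0 + 1L)
  s <- IRanges::IRanges(windows$start + 1L, windows$end)
  win <- rep(NA_integer_, length(pos0))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    si <- which(chrom == ch)
    if (!length(si)) next
    ov <- IRanges::findOverlaps(q[si], s[wi], select = "first")
    win[si] <- wi[ov]
  }
  win
}

#' Windowed pi, dxy and Weir-Cockerham FST (ratio of sums)
#'
#' Aggregates [site_counts()] over windows: each statistic is the sum of
#' per-site numerators divided by the sum of per-site denominators
#' ("ratio of sums"), which keeps the estimators unbiased under arbitrary
#' per-genotype missingness because invariant and partially-called sites
#' still contribute their comparison counts to the denominator. FST is
#' `sum(a) / sum(a + b + c)` over the Weir-Cockerham per-site components and
#' may be negative; it is reported unclipped. A statistic whose denominator
#' is zero is `NA`, and such windows carry `any_missing = TRUE` so callers
#' can drop them (windowed scans exclude windows missing any parameter).
#'
#' @param x an [allsites()] object, (chrom, pos) sorted.
#' @param windows data.table from [make_windows()] (or any disjoint interval
#'   set with `chrom`, `start`, `end`).
#' @param popmap two-population [population_map()].
#' @return data.table with one row per window: coordinates, `fst`,
#'   `pi_<pop1>`, `pi_<pop2>`, `dxy`, `n_sites` (sites contributing to any
#'   denominator), the raw sums that produced each ratio, and `any_missing`.
#' @export
window_summaries <- function(x, windows, popmap) {
  o <- order(x$chrom, x$pos0)
  if (!identical(o, seq_along(o))) stop("sites must be sorted by (chrom, pos)")
  sc <- site_counts(x, popmap)
  pops <- attr(sc, "pops")
  sc[, win := assign_windows(chrom, pos0, windows)]
  pn1 <- paste0("pi_num_", pops[1]); pd1 <- paste0("pi_den_", pops[1])
  pn2 <- paste0("pi_num_", pops[2]); pd2 <- paste0("pi_den_", pops[2])
  agg <- sc[!is.na(win), .(
    pi_num_1 = sum(.SD[[pn1]]), pi_den_1 = sum(.SD[[pd1]]),
    pi_num_2 = sum(.SD[[pn2]]), pi_den_2 = sum(.SD[[pd2]]),
    dxy_num = sum(dxy_num), dxy_den = sum(dxy_den),
    wc_a = sum(wc_a), wc_abc = sum(wc_abc),
    n_sites = sum(.SD[[pd1]] > 0 | .SD[[pd2]] > 0 | dxy_den > 0)
  ), by = win]

  out <- data.table(chrom = windows$chrom, start = windows$start,
                    end = windows$end)
  out[, label := sprintf("%s:%d-%d", chrom, start, end)]
  m <- match(seq_len(nrow(out)), agg$win)
  for (cn in setdiff(names(agg), "win")) {
    v <- agg[[cn]][m]
    v[is.na(v)] <- 0
    data.table::set(out, j = cn, value = v)
  }
  rat <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out[, fst := rat(wc_a, wc_abc)]
  data.table::set(out, j = paste0("pi_", pops[1]),
                  value = rat(out$pi_num_1, out$pi_den_1))
  data.table::set(out, j = paste0("pi_", pops[2]),
                  value = rat(out$pi_num_2, out$pi_den_2))
  out[, dxy := rat(dxy_num, dxy_den)]
  out[, any_missing := is.na(fst) | is.na(.SD[[paste0("pi_", pops[1])]]) |
        is.na(.SD[[paste0("pi_", pops[2])]]) | is.na(dxy)]
  data.table::setattr(out, "pops", pops)
  data.table::setattr(out, "n_excluded_sites", attr(sc, "n_excluded"))
  out[]
}

#' Pooled nucleotide diversity over arbitrary intervals
#'
#' The same ratio-of-sums estimator as [window_summaries()], restricted to a
#' chosen sample set and to possibly non-tiling intervals (e.g. the CDS
#' exons of a gene). Intervals sharing a `label` are pooled: the result for a
#' label is the summed mismatch count over all its intervals divided by the
#' summed comparison count, so splitting an interval in two never changes
#' the estimate.
#'
#' @param x an [allsites()] object.
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `label` (default: one label per row).
#'   Intervals pooled under one label must not overlap each other.
#' @param samples character vector of samples to pool as one population
#'   (default: all samples in `x`).
#' @return data.table with `label`, `pi` (`NA` where no called pairs),
#'   `num`, `den`, `n_sites`.
#' @export
region_pi <- function(x, intervals, samples = NULL) {
  intervals <- as.data.table(intervals)
  if (nrow(intervals) == 0L) stop("empty interval set")
  if (!"label" %in% names(intervals))
    intervals[, label := sprintf("%s:%d-%d", chrom, start, end)]
  if (is.null(samples)) samples <- x$samples
  idx <- match(samples, x$samples)
  if (anyNA(idx))
    stop("samples absent from data: ",
         paste(samples[is.na(idx)], collapse = ", "))
  ok <- usable_site_mask(x)
  t1 <- pop_site_tallies(x, idx)
  use <- ok & t1$n >= 2
  num <- ifelse(use, (t1$n - t1$c_alt) * t1$c_alt, 0)
  den <- ifelse(use, t1$n * (t1$n - 1) / 2, 0)

  q <- IRanges::IRanges(x$pos0 + 1L, x$pos0 + 1L)
  res <- rbindlist(lapply(seq_len(nrow(intervals)), function(i) {
    si <- which(x$chrom == intervals$chrom[i])
    hit <- si[IRanges::overlapsAny(
      q[si], IRanges::IRanges(intervals$start[i] + 1L, intervals$end[i]))]
    data.table(label = intervals$label[i],
               num = sum(num[hit]), den = sum(den[hit]),
               n_sites = sum(den[hit] > 0))
  }))
  out <- res[, .(num = sum(num), den = sum(den), n_sites = sum(n_sites)),
             by = label]
  out[, pi := ifelse(den > 0, num / den, NA_real_)]
  out[, .(label, pi, num, den, n_sites)]
}

#' Pearson correlation between two per-window tracks
#'
#' Pairs with a missing value in either track are dropped; the two-sided p
#' comes from `t = r * sqrt((k - 2) / (1 - r^2))` on k - 2 degrees of
#' freedom (k = complete pairs).
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p`, and `n` (complete pairs used).
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  k <- length(x)
  if (k < 3L) stop("need at least 3 complete pairs, got ", k)
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance in one of the tracks")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((k - 2) / (1 - r^2))
    p <- 2 * pt(abs(tstat), df = k - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = k)
}
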