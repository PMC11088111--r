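test_that("make_windows tiles, truncates and validates", {
  w <- make_windows(c(c6 = 12000), 5000)
  expect_equal(w$start, c(0L, 5000L, 10000L))
  expect_equal(w$end, c(5000L, 10000L, 12000L))
  expect_equal(nrow(make_windows(c(x = 5000), 5000)), 1L)
  w1 <- make_windows(c(x = 1), 5000)
  expect_equal(c(w1$start, w1$end), c(0L, 1L))
  expect_error(make_windows(c(x = 100), 0), "positive")
})

test_that("per-site counts match hand enumeration", {
  samples <- sprintf("s%d", 1:4)
  pm <- population_map(samples, c("p1", "p1", "p2", "p2"))
  # pop1 alleles {A,A,T,T}: 4 mismatching pairs of 6; pop2 fixed ref
  x <- sites_from_rows(
    list(list(pos = 0L, ref = "A", alt = "T", gt = "0/0 1/1 0/0 0/0")),
    samples)
  sc <- site_counts(x, pm)
  expect_equal(sc$pi_num_p1, 4)
  expect_equal(sc$pi_den_p1, 6)
  expect_equal(sc$pi_num_p1 / sc$pi_den_p1, 2 / 3)

  # fixed difference: dxy = 1, single-site window FST = 1
  xf <- sites_from_rows(
    list(list(pos = 0L, ref = "A", alt = "T", gt = "0/0 0/0 1/1 1/1")),
    samples)
  scf <- site_counts(xf, pm)
  expect_equal(scf$dxy_num, 16)
  expect_equal(scf$dxy_den, 16)
  expect_equal(scf$wc_a / scf$wc_abc, 1)

  # invariant site, 3 called diploids per pop
  samples6 <- sprintf("s%d", 1:6)
  pm6 <- population_map(samples6, rep(c("p1", "p2"), each = 3))
  xi <- sites_from_rows(
    list(list(pos = 0L, ref = "G", alt = "",
              gt = "0/0 0/0 0/0 0/0 0/0 0/0")), samples6)
  sci <- site_counts(xi, pm6)
  expect_equal(sci$pi_num_p1, 0)
  expect_equal(sci$pi_den_p1, 15)
  expect_equal(sci$pi_den_p2, 15)
  expect_equal(sci$dxy_den, 36)
  expect_equal(sci$wc_abc, 0)
})

test_that("window summaries: invariant windows, fixed-difference arithmetic", {
  samples <- sprintf("s%d", 1:4)
  pm <- population_map(samples, c("p1", "p1", "p2", "p2"))
  rows <- c(
    list(list(pos = 0L, ref = "A", alt = "T", gt = "0/0 0/0 1/1 1/1")),
    lapply(1:99, function(i)
      list(pos = as.integer(i), ref = "C", alt = "", gt = "0/0 0/0 0/0 0/0")))
  x <- sites_from_rows(rows, samples, contig_len = 100L)
  ws <- window_summaries(x, make_windows(c(chrT = 100), 100), pm)
  expect_equal(ws$dxy, 16 / 1600)
  expect_equal(ws$fst, 1)
  expect_equal(ws$pi_p1, 0)
  expect_false(ws$any_missing)

  # all-invariant window: pi = dxy = 0, FST undefined, flagged
  xi <- sites_from_rows(
    lapply(0:99, function(i)
      list(pos = as.integer(i), ref = "C", alt = "", gt = "0/0 0/0 0/0 0/0")),
    samples, contig_len = 100L)
  wsi <- window_summaries(xi, make_windows(c(chrT = 100), 100), pm)
  expect_equal(wsi$pi_p1, 0)
  expect_equal(wsi$dxy, 0)
  expect_true(is.na(wsi$fst))
  expect_true(wsi$any_missing)
})

test_that("unsorted input errors", {
  samples <- c("a", "b")
  pm <- population_map(samples, c("p1", "p2"))
  x <- sites_from_rows(list(
    list(pos = 5L, ref = "A", alt = "", gt = "0/0 0/0"),
    list(pos = 1L, ref = "A", alt = "", gt = "0/0 0/0")), samples)
  expect_error(window_summaries(x, make_windows(c(chrT = 10), 10), pm),
               "sorted")
})

test_that("random masking leaves pi unbiased (denominator awareness)", {
  x <- random_sites(n_samples = 8, n_sites = 400, p_variant = 0.3,
                    miss = 0, seed = 11)
  pm <- population_map(x$samples, rep(c("p1", "p2"), each = 4))
  wins <- make_windows(c(chrT = 400), 400)
  full <- window_summaries(x, wins, pm)
  est <- replicate(40, {
    xm <- inject_missingness(x, 0.3, seed = sample.int(1e6, 1))
    window_summaries(xm, wins, pm)$pi_p1
  })
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - full$pi_p1), 3 * se + 1e-12)
})

test_that("ratio of sums, not mean of per-site ratios", {
  # two sites with different denominators: site 1 has 2 diploids called,
  # site 2 has 4; mean-of-ratios and ratio-of-sums disagree
  samples <- sprintf("s%d", 1:4)
  pm <- population_map(samples, c("p1", "p1", "p2", "p2"))
  x <- sites_from_rows(list(
    list(pos = 0L, ref = "A", alt = "T", gt = "0/1 ./. 0/0 0/0"),
    list(pos = 1L, ref = "A", alt = "T", gt = "0/1 0/1 0/0 0/0")),
    samples, contig_len = 2L)
  ws <- window_summaries(x, make_windows(c(chrT = 2), 2), pm)
  # site 1: num 1, den 1; site 2: num 4, den 6
  ratio_of_sums <- (1 + 4) / (1 + 6)
  mean_of_ratios <- mean(c(1 / 1, 4 / 6))
  expect_equal(ws$pi_p1, ratio_of_sums)
  expect_false(isTRUE(all.equal(ws$pi_p1, mean_of_ratios)))
})

test_that("pi/dxy/FST equal the independent oracles on random cohorts", {
  for (seed in 1:12) {
    ns <- sample(4:10, 1)
    x <- random_sites(n_samples = ns, n_sites = 300, p_variant = 0.25,
                      miss = 0.25, seed = seed)
    pm <- two_pop_map(x)
    wins <- make_windows(c(chrT = 300), 100)
    ws <- window_summaries(x, wins, pm)
    win_of <- findInterval(x$pos0, wins$start)
    i1 <- match(attr(pm, "pops")[[1]], x$samples)
    i2 <- match(attr(pm, "pops")[[2]], x$samples)
    expect_equal(ws$pi_pop1, oracle_pi(x, i1, win_of)$pi, tolerance = 1e-12)
    expect_equal(ws$pi_pop2, oracle_pi(x, i2, win_of)$pi, tolerance = 1e-12)
    expect_equal(ws$dxy, oracle_dxy(x, i1, i2, win_of)$dxy,
                 tolerance = 1e-12)
    expect_equal(ws$fst, oracle_fst_window(x, i1, i2, win_of),
                 tolerance = 1e-10)
  }
})

test_that("region_pi reproduces pooled-interval arithmetic", {
  samples <- c("a", "b")
  # 738 bp CDS, 2 diploids, 3 segregating sites balanced 2/2
  rows <- lapply(0:737, function(i) {
    if (i %in% c(10L, 300L, 600L))
      list(pos = as.integer(i), ref = "A", alt = "T", gt = "0/1 0/1")
    else list(pos = as.integer(i), ref = "A", alt = "", gt = "0/0 0/0")
  })
  x <- sites_from_rows(rows, samples, contig_len = 738L)
  r <- region_pi(x, data.frame(chrom = "chrT", start = 0L, end = 738L,
                               label = "cds"))
  expect_equal(r$pi, (3 * 4) / (738 * 6))
  expect_equal(r$pi, 0.00271, tolerance = 1e-3)

  # splitting the interval changes nothing (pooled ratio of sums)
  r2 <- region_pi(x, data.frame(chrom = "chrT",
                                start = c(0L, 400L), end = c(400L, 738L),
                                label = "cds"))
  expect_equal(r2$pi, r$pi)

  # interval with no called sites -> NA
  xq <- sites_from_rows(list(
    list(pos = 0L, ref = "A", alt = "", gt = "./. ./.")), samples)
  rq <- region_pi(xq, data.frame(chrom = "chrT", start = 0L, end = 1L))
  expect_true(is.na(rq$pi))
  expect_error(region_pi(x, data.frame()[0, ]), "empty")
})

test_that("pearson correlation matches closed form and cor.test", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  set.seed(3)
  a <- rnorm(10); b <- rnorm(10)
  got <- pearson_correlation(a, b)
  ct <- stats::cor.test(a, b)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)
  # NA entries dropped pairwise
  a2 <- c(a, NA); b2 <- c(b, 5)
  expect_equal(pearson_correlation(a2, b2)$n, 10)
  expect_error(pearson_correlation(1:2, 2:3), "3 complete pairs")
  expect_error(pearson_correlation(rep(1, 5), 1:5), "variance")
})
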