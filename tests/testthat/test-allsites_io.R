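test_that("AllSites VCF reading handles invariant, missing and ordered records", {
  p <- write_vcf_text(vcf_3line_fixture())
  x <- read_allsites_vcf(p)
  expect_s3_class(x, "allsites")
  expect_equal(length(x$pos0), 3L)
  expect_equal(x$pos0, c(9L, 19L, 29L))          # 1-based -> 0-based
  # invariant site: empty alt, both genotypes (0,0)
  expect_equal(x$alt[1], "")
  expect_equal(unname(x$gt1[1, ]), c(0L, 0L))
  expect_equal(unname(x$gt2[1, ]), c(0L, 0L))
  # ./. preserved as missing
  expect_true(is.na(x$gt1[2, 2]) && is.na(x$gt2[2, 2]))
  # indel passed through by the reader
  expect_equal(x$alt[3], "GA")
  expect_equal(x$contig_lengths, c(chr1 = 500))
  expect_equal(x$info$FS, c(NA, 10, NA))
})

test_that("sample subsetting works and absent samples error informatively", {
  p <- write_vcf_text(vcf_3line_fixture())
  x <- read_allsites_vcf(p, samples = "s2")
  expect_equal(x$samples, "s2")
  expect_true(is.na(x$gt1[2, 1]))
  expect_error(read_allsites_vcf(p, samples = c("s1", "sX", "sY")),
               "sX.*sY")
})

test_that("malformed VCF raises a parse error naming the file", {
  bad <- c(vcf_3line_fixture(), "chr1\tnot_a_position\t.\tA\t.\t.")
  p <- write_vcf_text(bad)
  expect_error(read_allsites_vcf(p), "malformed|scan|parse|invalid")
})

test_that("write + read round-trips genotypes, missingness, GQ/DP and INFO", {
  set.seed(42)
  x <- random_sites(n_samples = 5, n_sites = 60, miss = 0.2, seed = 9)
  x$gq <- matrix(sample(10:99, 60 * 5, TRUE), 60, 5)
  x$dp <- matrix(sample(1:120, 60 * 5, TRUE), 60, 5)
  x$info <- data.frame(FS = round(runif(60, 0, 80), 3),
                       MQ = round(runif(60, 20, 60), 3))
  p <- tempfile(fileext = ".vcf")
  write_allsites_vcf(x, p)
  y <- read_allsites_vcf(p)
  expect_equal(y$chrom, x$chrom)
  expect_equal(y$pos0, x$pos0)
  expect_equal(y$ref, x$ref)
  expect_equal(y$alt, x$alt)
  expect_equal(y$gt1, x$gt1)
  expect_equal(y$gt2, x$gt2)
  expect_equal(y$gq, x$gq)
  expect_equal(y$dp, x$dp)
  expect_equal(y$info$FS, x$info$FS, tolerance = 1e-6)
  expect_equal(y$info$MQ, x$info$MQ, tolerance = 1e-6)
  expect_equal(y$samples, x$samples)
})

test_that("half-called genotypes are treated as fully missing", {
  lines <- c("##fileformat=VCFv4.2",
             "##contig=<ID=chr1,length=100>",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
             "chr1\t5\t.\tA\tT\t.\t.\t.\tGT\t./1")
  x <- read_allsites_vcf(write_vcf_text(lines))
  expect_true(is.na(x$gt1[1, 1]) && is.na(x$gt2[1, 1]))
})

test_that("site filters follow the printed thresholds with strict bounds", {
  samples <- c("a", "b")
  mk <- function(info) sites_from_rows(
    list(list(pos = 0L, ref = "A", alt = "T", gt = "0/1 0/0")),
    samples, info = info)
  cfg <- filter_config()
  # FS = 61 -> removed; FS = 60 -> kept (bound is "> 60.0")
  expect_equal(length(apply_filters(mk(data.frame(FS = 61)), cfg)$pos0), 0L)
  expect_equal(length(apply_filters(mk(data.frame(FS = 60)), cfg)$pos0), 1L)
  expect_equal(length(apply_filters(mk(data.frame(MQ = 39.9)), cfg)$pos0), 0L)
  expect_equal(length(apply_filters(mk(data.frame(QD = 1.9)), cfg)$pos0), 0L)
  expect_equal(length(apply_filters(
    mk(data.frame(MQRankSum = -12.6)), cfg)$pos0), 0L)
  expect_equal(length(apply_filters(
    mk(data.frame(ReadPosRankSum = -8.1)), cfg)$pos0), 0L)
  expect_equal(length(apply_filters(mk(data.frame(SOR = 3.1)), cfg)$pos0), 0L)
  # absent INFO metrics never trigger removal
  expect_equal(length(apply_filters(mk(NULL), cfg)$pos0), 1L)
  expect_equal(length(apply_filters(
    mk(data.frame(FS = NA_real_)), cfg)$pos0), 1L)
})

test_that("genotype GQ/DP bounds mask genotypes, not sites", {
  samples <- c("a", "b")
  x <- sites_from_rows(
    list(list(pos = 0L, ref = "A", alt = "T", gt = "0/1 1/1")),
    samples,
    gq = matrix(c(19L, 20L), 1), dp = matrix(c(50L, 100L), 1))
  y <- apply_filters(x)
  expect_equal(length(y$pos0), 1L)               # site kept
  expect_true(is.na(y$gt1[1, 1]))                # GQ 19 masked
  expect_false(is.na(y$gt1[1, 2]))               # GQ 20, DP 100 kept
  expect_equal(attr(y, "n_genotypes_masked"), 1L)

  x2 <- sites_from_rows(
    list(list(pos = 0L, ref = "A", alt = "T", gt = "0/1 1/1")),
    samples,
    gq = matrix(c(50L, 50L), 1), dp = matrix(c(1L, 101L), 1))
  y2 <- apply_filters(x2)
  expect_true(all(is.na(y2$gt1)))                # DP 1 and DP 101 both masked
})

test_that("indels are dropped, invariant and multiallelic SNPs pass", {
  samples <- "a"
  x <- sites_from_rows(list(
    list(pos = 0L, ref = "A", alt = "", gt = "0/0"),
    list(pos = 1L, ref = "A", alt = "AT", gt = "0/1"),
    list(pos = 2L, ref = "AC", alt = "A", gt = "0/1"),
    list(pos = 3L, ref = "A", alt = "T,G", gt = "1/2"),
    list(pos = 4L, ref = "A", alt = "T", gt = "0/1")), samples)
  y <- apply_filters(x)
  expect_equal(y$pos0, c(0L, 3L, 4L))
  expect_equal(attr(y, "n_sites_removed"), 2L)
  y2 <- apply_filters(x, filter_config(drop_indels = FALSE))
  expect_equal(length(y2$pos0), 5L)
})

test_that("apply_filters is idempotent and order-independent", {
  set.seed(5)
  x <- random_sites(n_samples = 6, n_sites = 80, miss = 0.1, seed = 5)
  x$gq <- matrix(sample(10:40, 80 * 6, TRUE), 80, 6)
  x$dp <- matrix(sample(1:110, 80 * 6, TRUE), 80, 6)
  x$info <- data.frame(FS = runif(80, 0, 80))
  cfg <- filter_config()
  y1 <- apply_filters(x, cfg)
  y2 <- apply_filters(y1, cfg)
  expect_equal(unclass(y1)[c("pos0", "gt1", "gt2")],
               unclass(y2)[c("pos0", "gt1", "gt2")])
  expect_equal(attr(y2, "n_sites_removed"), 0L)
  expect_equal(attr(y2, "n_genotypes_masked"), 0L)
  # masking only, then site-dropping only == one combined pass
  cfg_mask <- filter_config(fs_max = Inf, drop_indels = FALSE)
  cfg_drop <- filter_config(gq_min = -Inf, dp_min = -1L, dp_max = .Machine$integer.max)
  z <- apply_filters(apply_filters(x, cfg_mask), cfg_drop)
  expect_equal(unclass(z)[c("pos0", "gt1", "gt2")],
               unclass(y1)[c("pos0", "gt1", "gt2")])
})

test_that("population maps parse, validate and preserve group sizes", {
  p <- tempfile()
  writeLines(c("s1\tA", "s2\tA", "s3\tB", "s4\tB"), p)
  pm <- read_population_map(p)
  expect_equal(length(attr(pm, "pops")), 2L)
  expect_equal(lengths(attr(pm, "pops")), c(A = 2L, B = 2L))

  writeLines(c("s1\tA", "s1\tB"), p)
  expect_error(read_population_map(p), "duplicated")
  writeLines(character(0), p)
  expect_error(read_population_map(p), "empty")

  # 63 samples, two populations, sizes preserved through a round trip
  ids <- sprintf("ind%02d", 1:63)
  pops <- rep(c("atl", "pac"), c(30, 33))
  writeLines(paste(ids, pops, sep = "\t"), p)
  pm2 <- read_population_map(p)
  expect_equal(lengths(attr(pm2, "pops")), c(atl = 30L, pac = 33L))
  expect_equal(names(pm2), ids)
})
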