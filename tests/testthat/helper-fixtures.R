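# In-code fixture builders shared across test files.

# Random small allsites cohort: biallelic SNPs + invariant sites + optional
# missingness; genotypes drawn from per-site allele frequencies.
random_sites <- function(n_samples = 8L, n_sites = 200L, p_variant = 0.1,
                         miss = 0.1, chrom = "chrT", seed = 1L) {
  set.seed(seed)
  variant <- runif(n_sites) < p_variant
  freq <- ifelse(variant, runif(n_sites, 0.05, 0.95), 0)
  draw <- function() {
    g <- matrix(rbinom(n_sites * n_samples, 1L, rep(freq, n_samples)),
                n_sites, n_samples)
    g
  }
  gt1 <- draw(); gt2 <- draw()
  if (miss > 0) {
    m <- matrix(runif(n_sites * n_samples) < miss, n_sites, n_samples)
    gt1[m] <- NA_integer_; gt2[m] <- NA_integer_
  }
  allsites(rep(chrom, n_sites), seq_len(n_sites) - 1L,
           rep("A", n_sites), ifelse(variant, "T", ""),
           gt1, gt2, sprintf("s%02d", seq_len(n_samples)),
           setNames(n_sites, chrom))
}

two_pop_map <- function(x) {
  n <- length(x$samples)
  population_map(x$samples,
                 rep(c("pop1", "pop2"), c(ceiling(n / 2), floor(n / 2))))
}

# Hand-built allsites from a compact spec: list of rows, each
# list(pos, ref, alt, gt = "0/0 0/1 ..." space-separated)
sites_from_rows <- function(rows, samples, chrom = "chrT", contig_len = NULL,
                            gq = NULL, dp = NULL, info = NULL) {
  S <- length(rows)
  parse_gt <- function(s) {
    gts <- strsplit(strsplit(s, " ", fixed = TRUE)[[1]], "/", fixed = TRUE)
    a1 <- vapply(gts, function(g) suppressWarnings(as.integer(g[1])), 1L)
    a2 <- vapply(gts, function(g) suppressWarnings(as.integer(g[2])), 1L)
    half <- xor(is.na(a1), is.na(a2))
    a1[half] <- NA_integer_; a2[half] <- NA_integer_
    rbind(a1, a2)
  }
  gt <- lapply(rows, function(r) parse_gt(r$gt))
  allsites(rep(chrom, S),
           vapply(rows, function(r) r$pos, 1L),
           vapply(rows, function(r) r$ref, ""),
           vapply(rows, function(r) r$alt, ""),
           do.call(rbind, lapply(gt, function(g) g[1, ])),
           do.call(rbind, lapply(gt, function(g) g[2, ])),
           samples,
           setNames(if (is.null(contig_len))
             max(vapply(rows, function(r) r$pos, 1L)) + 1L
             else contig_len, chrom),
           gq = gq, dp = dp, info = info)
}

write_vcf_text <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

# minimal AllSites VCF text: invariant, biallelic SNP, indel
vcf_3line_fixture <- function() {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=500>",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"f\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t10\t.\tA\t.\t.\t.\t.\tGT\t0/0\t0/0",
    "chr1\t20\t.\tC\tT\t.\t.\tFS=10.0\tGT\t0/1\t./.",
    "chr1\t30\t.\tG\tGA\t.\t.\t.\tGT\t1/1\t0/1")
}
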