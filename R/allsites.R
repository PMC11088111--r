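#' AllSites site-set container
#'
#' An `allsites` object holds one cohort's genotypes at every retained genomic
#' position, variant and invariant alike. Invariant sites carry an empty ALT
#' (`alt = ""`); missing genotypes are `NA` in both allele slots. Coordinates
#' are 0-based half-open internally; conversion to/from the 1-based VCF/GFF
#' convention happens only in the readers and writers.
#'
#' @param chrom character vector of contig names, one per site.
#' @param pos0 integer vector of 0-based positions.
#' @param ref,alt character vectors of REF and ALT alleles; `alt` is `""` for
#'   invariant sites and comma-separated for multiallelic sites.
#' @param gt1,gt2 integer matrices (sites x samples) of allele indices
#'   (0 = REF, 1 = first ALT, ...), `NA` for missing genotypes. A genotype is
#'   missing as a whole: `gt1` and `gt2` share the same `NA` pattern.
#' @param samples character vector of sample names (matrix columns).
#' @param contig_lengths named numeric vector of contig lengths in bp.
#' @param gq,dp optional integer matrices of genotype quality and depth.
#' @param info optional data.frame of per-site INFO metrics (columns such as
#'   `FS`, `MQ`, `QD`, `MQRankSum`, `ReadPosRankSum`, `SOR`).
#' @return An object of class `allsites`.
#' @export
allsites <- function(chrom, pos0, ref, alt, gt1, gt2, samples,
                     contig_lengths, gq = NULL, dp = NULL, info = NULL) {
  S <- length(pos0)
  gt1 <- as.matrix(gt1); gt2 <- as.matrix(gt2)
  stopifnot(
    length(chrom) == S, length(ref) == S, length(alt) == S,
    nrow(gt1) == S, nrow(gt2) == S,
    ncol(gt1) == length(samples), ncol(gt2) == length(samples),
    all(pos0 >= 0L)
  )
  if (any(is.na(gt1) != is.na(gt2)))
    stop("gt1 and gt2 must share the same missingness pattern")
  alt <- as.character(alt)
  n_alleles <- 1L + ifelse(alt == "", 0L,
                           nchar(alt) - nchar(gsub(",", "", alt,
                                                   fixed = TRUE)) + 1L)
  mx <- suppressWarnings(max(gt1, gt2, na.rm = TRUE))
  if (is.finite(mx) && any(pmax(gt1, gt2, na.rm = TRUE) >= n_alleles,
                           na.rm = TRUE))
    stop("genotype allele index out of range for its ALT list")
  structure(list(
    chrom = as.character(chrom), pos0 = as.integer(pos0),
    ref = as.character(ref), alt = as.character(alt),
    gt1 = gt1, gt2 = gt2,
    gq = gq, dp = dp, info = info,
    samples = as.character(samples),
    contig_lengths = contig_lengths
  ), class = "allsites")
}

#' @export
print.allsites <- function(x, ...) {
  cat(sprintf("<allsites> %d sites, %d samples, %d contig(s)\n",
              length(x$pos0), length(x$samples),
              length(unique(x$chrom))))
  cat(sprintf("  variant: %d  invariant: %d\n",
              sum(x$alt != ""), sum(x$alt == "")))
  invisible(x)
}

#' @export
dim.allsites <- function(x) c(length(x$pos0), length(x$samples))

# Row subset keeping all parallel slots in register.
subset_sites <- function(x, i) {
  allsites(x$chrom[i], x$pos0[i], x$ref[i], x$alt[i],
           x$gt1[i, , drop = FALSE], x$gt2[i, , drop = FALSE],
           x$samples, x$contig_lengths,
           gq = if (!is.null(x$gq)) x$gq[i, , drop = FALSE],
           dp = if (!is.null(x$dp)) x$dp[i, , drop = FALSE],
           info = if (!is.null(x$info)) x$info[i, , drop = FALSE])
}

#' Concatenate allsites objects (same cohort, disjoint coordinates)
#' @param ... `allsites` objects with identical sample vectors.
#' @return A single `allsites` object.
#' @export
concat_sites <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "allsites"))
    xs <- xs[[1]]
  stopifnot(length(xs) >= 1L)
  smp <- xs[[1]]$samples
  for (x in xs) stopifnot(identical(x$samples, smp))
  cl <- unlist(lapply(xs, `[[`, "contig_lengths"))
  cl <- cl[!duplicated(names(cl))]
  has_gq <- all(vapply(xs, function(x) !is.null(x$gq), TRUE))
  has_dp <- all(vapply(xs, function(x) !is.null(x$dp), TRUE))
  has_info <- all(vapply(xs, function(x) !is.null(x$info), TRUE))
  allsites(
    unlist(lapply(xs, `[[`, "chrom")), unlist(lapply(xs, `[[`, "pos0")),
    unlist(lapply(xs, `[[`, "ref")), unlist(lapply(xs, `[[`, "alt")),
    do.call(rbind, lapply(xs, `[[`, "gt1")),
    do.call(rbind, lapply(xs, `[[`, "gt2")),
    smp, cl,
    gq = if (has_gq) do.call(rbind, lapply(xs, `[[`, "gq")),
    dp = if (has_dp) do.call(rbind, lapply(xs, `[[`, "dp")),
    info = if (has_info)
      as.data.frame(rbindlist(lapply(xs, function(x) as.data.table(x$info)),
                              fill = TRUE))
  )
}
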