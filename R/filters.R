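#' Hard-filter configuration for AllSites VCFs
#'
#' Defaults are the standard GATK germline hard filters for SNPs plus the
#' genotype-level GQ/DP bounds used for the herring cohorts: sites are removed
#' when FS > 60.0, MQRankSum < -12.5, MQ < 40.0, QD < 2.0,
#' ReadPosRankSum < -8.0 or SOR > 3.0; genotypes with GQ < 20, DP < 2 or
#' DP > 100 are set to missing. Absent INFO metrics never trigger removal
#' (GATK VariantFiltration semantics for missing annotations).
#'
#' @param fs_max,mqranksum_min,mq_min,qd_min,readposranksum_min,sor_max
#'   site-level INFO thresholds.
#' @param gq_min,dp_min,dp_max genotype-level thresholds (all bounds strict:
#'   a genotype with DP exactly `dp_max` is kept).
#' @param drop_indels drop sites where any allele is not a single base.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(fs_max = 60.0, mqranksum_min = -12.5, mq_min = 40.0,
                          qd_min = 2.0, readposranksum_min = -8.0,
                          sor_max = 3.0, gq_min = 20L, dp_min = 2L,
                          dp_max = 100L, drop_indels = TRUE) {
  stopifnot(dp_min <= dp_max)
  structure(list(fs_max = fs_max, mqranksum_min = mqranksum_min,
                 mq_min = mq_min, qd_min = qd_min,
                 readposranksum_min = readposranksum_min, sor_max = sor_max,
                 gq_min = gq_min, dp_min = dp_min, dp_max = dp_max,
                 drop_indels = drop_indels),
            class = "filter_config")
}

# TRUE where a present INFO value violates its threshold; NA never triggers.
info_violates <- function(info, cfg) {
  S <- nrow(info)
  bad <- rep(FALSE, S)
  chk <- function(field, f) {
    v <- info[[field]]
    if (is.null(v)) return(rep(FALSE, S))
    out <- f(v)
    out[is.na(out)] <- FALSE
    out
  }
  bad <- bad | chk("FS", function(v) v > cfg$fs_max)
  bad <- bad | chk("MQRankSum", function(v) v < cfg$mqranksum_min)
  bad <- bad | chk("MQ", function(v) v < cfg$mq_min)
  bad <- bad | chk("QD", function(v) v < cfg$qd_min)
  bad <- bad | chk("ReadPosRankSum", function(v) v < cfg$readposranksum_min)
  bad <- bad | chk("SOR", function(v) v > cfg$sor_max)
  bad
}

is_indel_site <- function(x) {
  alt_lists <- strsplit(x$alt, ",", fixed = TRUE)
  nchar(x$ref) != 1L |
    vapply(alt_lists, function(a) length(a) > 0L && any(nchar(a) != 1L),
           logical(1))
}

#' Apply site- and genotype-level hard filters
#'
#' Removes indel sites (when configured) and sites whose present INFO metrics
#' violate the configured thresholds; masks (sets to missing) genotypes
#' failing the GQ/DP bounds. Invariant sites, which typically lack the
#' variant-site annotations, are never removed by absent metrics. The
#' operation is total and idempotent, and genotype masking commutes with
#' site removal.
#'
#' @param x an [allsites()] object.
#' @param cfg a [filter_config()].
#' @return A filtered `allsites` object with attributes `n_sites_removed` and
#'   `n_genotypes_masked`.
#' @export
apply_filters <- function(x, cfg = filter_config()) {
  stopifnot(inherits(x, "allsites"), inherits(cfg, "filter_config"))
  drop <- rep(FALSE, length(x$pos0))
  if (isTRUE(cfg$drop_indels)) drop <- drop | is_indel_site(x)
  if (!is.null(x$info)) drop <- drop | info_violates(x$info, cfg)

  mask <- matrix(FALSE, nrow(x$gt1), ncol(x$gt1))
  if (!is.null(x$gq)) {
    m <- x$gq < cfg$gq_min; m[is.na(m)] <- FALSE; mask <- mask | m
  }
  if (!is.null(x$dp)) {
    m <- x$dp < cfg$dp_min | x$dp > cfg$dp_max
    m[is.na(m)] <- FALSE; mask <- mask | m
  }
  gt1 <- x$gt1; gt2 <- x$gt2
  n_masked <- sum(mask & !is.na(gt1))
  gt1[mask] <- NA_integer_; gt2[mask] <- NA_integer_

  keep <- !drop
  out <- allsites(x$chrom[keep], x$pos0[keep], x$ref[keep], x$alt[keep],
                  gt1[keep, , drop = FALSE], gt2[keep, , drop = FALSE],
                  x$samples, x$contig_lengths,
                  gq = if (!is.null(x$gq)) x$gq[keep, , drop = FALSE],
                  dp = if (!is.null(x$dp)) x$dp[keep, , drop = FALSE],
                  info = if (!is.null(x$info)) x$info[keep, , drop = FALSE])
  attr(out, "n_sites_removed") <- sum(drop)
  attr(out, "n_genotypes_masked") <- n_masked
  out
}
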