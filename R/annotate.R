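#' Parse a RepeatMasker .out annotation
#'
#' Standard RepeatMasker output: header lines followed by whitespace-
#' delimited columns, query coordinates 1-based inclusive. The class/family
#' string (e.g. `LINE/L2`) is mapped to its superclass by the prefix before
#' `/`.
#'
#' @param path path to a RepeatMasker `.out` file.
#' @return data.table with `chrom`, `start`, `end` (0-based half-open),
#'   `repeat_name`, `class_family`, `superclass`.
#' @export
parse_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_data <- grepl("^\\s*\\d+\\s", lines)
  first <- which(is_data)[1]
  if (is.na(first)) stop("no data rows in RepeatMasker file: ", path)
  rows <- lapply(which(is_data), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 11)
      stop("malformed RepeatMasker row at line ", i, ": ", lines[i])
    b <- suppressWarnings(as.integer(f[6])); e <- suppressWarnings(as.integer(f[7]))
    if (is.na(b) || is.na(e) || e < b)
      stop("malformed coordinates at line ", i, ": ", lines[i])
    data.table(chrom = f[5], start = b - 1L, end = e,
               repeat_name = f[10], class_family = f[11])
  })
  out <- rbindlist(rows)
  out[, superclass := sub("/.*$", "", class_family)]
  out[]
}

#' Per-window repeat coverage proportions
#'
#' For every window, the fraction of bases covered by repeats, overall and
#' per superclass. Coverage is the union of (possibly overlapping or nested)
#' repeat intervals clipped to the window, so a base under two repeats
#' counts once; `mode = "sum"` switches to additive coverage.
#'
#' @param repeats data.table from [parse_repeatmasker_out()] (or any table
#'   with `chrom`, `start`, `end`, `superclass`).
#' @param windows window table (`chrom`, `start`, `end`), disjoint.
#' @param mode `"union"` (default) or `"sum"`.
#' @return data.table: window coordinates, `prop_total`, and one
#'   `prop_<superclass>` column per superclass present, all in `[0, 1]`
#'   (additive mode can exceed 1 for nested annotations).
#' @export
window_repeat_proportion <- function(repeats, windows,
                                     mode = c("union", "sum")) {
  mode <- match.arg(mode)
  repeats <- as.data.table(repeats)
  out <- as.data.table(windows)[, .(chrom, start, end)]
  wlen <- out$end - out$start
  win_gr <- GenomicRanges::GRanges(out$chrom,
                                   IRanges::IRanges(out$start + 1L, out$end))
  covered <- function(rep_sub) {
    gr <- GenomicRanges::GRanges(rep_sub$chrom,
                                 IRanges::IRanges(rep_sub$start + 1L,
                                                  rep_sub$end))
    if (mode == "union") gr <- GenomicRanges::reduce(gr)
    ov <- GenomicRanges::findOverlaps(gr, win_gr)
    if (!length(ov)) return(numeric(nrow(out)))
    w <- GenomicRanges::width(IRanges::pintersect(
      gr[S4Vectors::queryHits(ov)], win_gr[S4Vectors::subjectHits(ov)]))
    as.numeric(tapply(w, factor(S4Vectors::subjectHits(ov),
                                levels = seq_len(nrow(out))), sum,
                      default = 0))
  }
  out[, prop_total := covered(repeats) / wlen]
  for (sc in sort(unique(repeats$superclass)))
    out[[paste0("prop_", sc)]] <- covered(repeats[superclass == sc]) / wlen
  out[]
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value.
#'
#' @param x,y numeric vectors, each with at least 2 finite values.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each group needs >= 2 finite values")
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) stop("zero variance in both groups")
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tstat, df = df,
       p = 2 * pt(abs(tstat), df = df, lower.tail = FALSE))
}

#' Read gene-level features from a GFF3 annotation
#'
#' @param path GFF3 file.
#' @param protein_coding_only keep only protein-coding genes when a
#'   biotype attribute (`gene_biotype` or `biotype`) is annotated.
#' @return data.table with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `biotype` (`NA` when unannotated).
#' @export
read_gff_genes <- function(path, protein_coding_only = TRUE) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "gene"]
  md <- S4Vectors::mcols(gr)
  biotype <- if ("gene_biotype" %in% names(md)) md$gene_biotype
    else if ("biotype" %in% names(md)) md$biotype
    else rep(NA_character_, length(gr))
  if (protein_coding_only && !all(is.na(biotype))) {
    keep <- is.na(biotype) | biotype == "protein_coding"
    gr <- gr[keep]; biotype <- biotype[keep]
  }
  id <- if ("ID" %in% names(S4Vectors::mcols(gr))) gr$ID else
    as.character(seq_along(gr))
  data.table(gene_id = as.character(id),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             biotype = as.character(biotype))
}

#' Flag genes overlapping high-diversity regions
#'
#' A gene is flagged iff it shares at least one base with any region
#' (half-open interval intersection, so a gene ending exactly where a region
#' starts does not overlap).
#'
#' @param genes data.table from [read_gff_genes()].
#' @param regions data.table with `chrom`, `start`, `end` (e.g. from
#'   [merge_windows_to_regions()]).
#' @return `genes` with an added logical column `in_region`.
#' @export
genes_overlapping_regions <- function(genes, regions) {
  genes <- copy(as.data.table(genes))
  if (nrow(regions) == 0L) {
    genes[, in_region := FALSE]
    return(genes[])
  }
  g <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start + 1L, genes$end))
  r <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1L,
                                               regions$end))
  genes[, in_region := GenomicRanges::countOverlaps(g, r) > 0L]
  genes[]
}
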