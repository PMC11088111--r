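#' Tabulate gene copy number per haplotype assembly
#'
#' Summarizes per-assembly annotations of a copy-number-variable gene
#' cluster: complete and null copies (alleles with inactivating mutations)
#' both count as genes; pseudogenes (coding fragments only) are counted
#' separately; span is the declared region length in kb.
#'
#' @param copies data.frame of annotated copies with columns `assembly`,
#'   `region`, `chrom`, `start`, `end` (0-based half-open) and `status`
#'   (one of `complete`, `null`, `pseudogene`).
#' @param regions data.frame with one row per (`assembly`, `region`):
#'   `chrom`, `start`, `end`. A copy outside its declared region is an
#'   error.
#' @return data.table: `region`, `assembly`, `n_genes`, `n_pseudogenes`,
#'   `span_kb`.
#' @export
tabulate_copy_number <- function(copies, regions) {
  copies <- as.data.table(copies)
  regions <- as.data.table(regions)
  stopifnot(all(copies$status %in% c("complete", "null", "pseudogene")))
  m <- regions[copies, on = c("assembly", "region"),
               .(assembly, region, chrom = i.chrom, start = i.start,
                 end = i.end, status,
                 r_chrom = x.chrom, r_start = x.start, r_end = x.end)]
  if (anyNA(m$r_start))
    stop("copy refers to an undeclared (assembly, region)")
  bad <- m$chrom != m$r_chrom | m$start < m$r_start | m$end > m$r_end
  if (any(bad))
    stop(sum(bad), " cop(ies) outside the declared region, first: ",
         m$assembly[bad][1], "/", m$region[bad][1])
  out <- regions[, .(assembly, region, span_kb = (end - start) / 1000)]
  counts <- copies[, .(n_genes = sum(status %in% c("complete", "null")),
                       n_pseudogenes = sum(status == "pseudogene")),
                   by = .(assembly, region)]
  out <- counts[out, on = c("assembly", "region")]
  out[is.na(n_genes), `:=`(n_genes = 0L, n_pseudogenes = 0L)]
  out[, .(region, assembly, n_genes, n_pseudogenes, span_kb)]
}

#' Nucleotide diversity from aligned coding sequences
#'
#' Mean pairwise p-distance over all sequence pairs:
#' `pi = 2 / (m (m - 1)) * sum_pairs(differences / valid sites)`. With
#' `gap_mode = "pairwise_deletion"` (the conventional default) a position
#' counts for a pair when both members carry an unambiguous base; with
#' `"complete_deletion"` positions with a gap or N in *any* sequence are
#' discarded for all pairs.
#'
#' @param seqs aligned, equal-length sequences: a character vector, a
#'   `Biostrings::DNAStringSet`, or a character matrix (rows = sequences).
#'   Alphabet `ACGTN-`; comparison is case-insensitive.
#' @param gap_mode `"pairwise_deletion"` (default) or `"complete_deletion"`.
#' @return The diversity estimate (a single number).
#' @export
cds_pi <- function(seqs, gap_mode = c("pairwise_deletion",
                                      "complete_deletion")) {
  gap_mode <- match.arg(gap_mode)
  m <- seq_char_matrix(seqs)
  if (nrow(m) < 2L) stop("need >= 2 sequences")
  valid <- matrix(m %in% c("A", "C", "G", "T"), nrow(m))
  if (gap_mode == "complete_deletion") {
    keep <- colSums(valid) == nrow(m)
    m <- m[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  n <- nrow(m)
  total <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- valid[i, ] & valid[j, ]
    nv <- sum(both)
    if (nv == 0L) stop("a sequence pair shares zero valid sites")
    total <- total + sum(m[i, both] != m[j, both]) / nv
  }
  total / (n * (n - 1) / 2)
}

seq_char_matrix <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet") || methods::is(seqs, "BStringSet"))
    seqs <- as.character(seqs)
  if (is.character(seqs)) {
    if (length(unique(nchar(seqs))) != 1L)
      stop("sequences must be aligned to equal length")
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
  } else if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else stop("unsupported sequence input")
  m
}

#' Compare long-read and short-read diversity estimates per gene
#'
#' Joins per-gene pi estimated from haplotype-resolved assemblies
#' (long reads) with pi estimated from short-read mapping over the same
#' intervals, reporting the short/long ratio and flagging genes where the
#' short-read estimate exceeds the long-read one — the signature of
#' collapsed-copy read cross-mapping inflating apparent heterozygosity.
#' (The reverse, short < long, also occurs when mapping misses alleles; it
#' is reported but not flagged.)
#'
#' @param long_read,short_read named numeric vectors (gene -> pi) or
#'   two-column data.frames (`gene`, `pi`). Only shared gene labels are
#'   compared.
#' @return data.table: `gene`, `pi_long`, `pi_short`, `ratio`
#'   (short / long, `NA` when long-read pi is 0), `inflated`.
#' @export
compare_pi <- function(long_read, short_read) {
  to_dt <- function(v, col) {
    if (is.data.frame(v)) data.table(gene = as.character(v$gene),
                                     val = as.numeric(v$pi))
    else data.table(gene = names(v), val = as.numeric(v))
  }
  lr <- to_dt(long_read); sr <- to_dt(short_read)
  out <- merge(lr, sr, by = "gene", suffixes = c("_long", "_short"))
  setnames(out, c("val_long", "val_short"), c("pi_long", "pi_short"))
  out[, ratio := ifelse(pi_long > 0, pi_short / pi_long, NA_real_)]
  out[, inflated := pi_short > pi_long]
  out[]
}

#' Read an aligned CDS FASTA with assembly:copy ids
#'
#' Record ids follow the convention `assembly:copy[:status]`, e.g.
#' `CS4_h1:IFIT10A:complete`. Status defaults to `complete` when absent.
#'
#' @param path FASTA of aligned sequences.
#' @return data.table: `assembly`, `copy`, `status`, `seq`.
#' @export
read_cds_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(sub(" .*$", "", names(s)), ":", fixed = TRUE)
  data.table(
    assembly = vapply(parts, `[`, "", 1L),
    copy = vapply(parts, function(p) if (length(p) >= 2) p[2] else NA, ""),
    status = vapply(parts, function(p) if (length(p) >= 3) p[3]
                    else "complete", ""),
    seq = as.character(s))
}
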