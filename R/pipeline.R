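#' Configuration for the end-to-end scan
#'
#' Defaults are the settings of the herring-style scan: 5 kb windows, the
#' GATK hard filters and GQ/DP bounds of [filter_config()], joint 5th/95th
#' percentile thresholds, GO testing on biological_process with a 10-gene
#' minimum and Bonferroni P <= 0.01.
#'
#' @param vcf,popmap paths to the AllSites VCF and population map
#'   (required).
#' @param gff,repeats,obo,gene2go,recomb,cds optional annotation inputs:
#'   GFF3 genes, RepeatMasker .out, OBO ontology, gene-to-GO TSV
#'   (columns gene, term), per-window recombination TSV
#'   (chrom, start, end, rate), aligned CDS FASTA (ids `assembly:copy`).
#' @param window_size window size in bp.
#' @param filters a [filter_config()].
#' @param q_fst,q_pi selection quantiles.
#' @param max_gap window gap bridged when merging regions.
#' @param go_namespace,go_algorithm,go_min_genes,go_alpha GO settings.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(vcf, popmap, gff = NULL, repeats = NULL, obo = NULL,
                        gene2go = NULL, recomb = NULL, cds = NULL,
                        window_size = 5000L, filters = filter_config(),
                        q_fst = 0.05, q_pi = 0.95, max_gap = 0L,
                        go_namespace = "BP", go_algorithm = "elim",
                        go_min_genes = 10L, go_alpha = 0.01) {
  if (missing(vcf) || is.null(vcf)) stop("scan_config: 'vcf' is required")
  if (missing(popmap) || is.null(popmap))
    stop("scan_config: 'popmap' is required")
  stopifnot(window_size >= 1)
  structure(list(vcf = vcf, popmap = popmap, gff = gff, repeats = repeats,
                 obo = obo, gene2go = gene2go, recomb = recomb, cds = cds,
                 window_size = as.integer(window_size), filters = filters,
                 q_fst = q_fst, q_pi = q_pi, max_gap = as.integer(max_gap),
                 go_namespace = go_namespace, go_algorithm = go_algorithm,
                 go_min_genes = as.integer(go_min_genes),
                 go_alpha = go_alpha),
            class = "scan_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full high-diversity-region scan
#'
#' Deterministic pipeline: read and filter the AllSites VCF, compute
#' windowed pi/dxy/FST, call high-diversity regions by joint percentiles,
#' then (when inputs are configured) contrast repeat content, flag
#' overlapping genes, test GO overrepresentation and compare CDS diversity.
#' Outputs are plain TSV/BED with stable headers plus a JSON manifest
#' recording the configuration, the realized thresholds (the audit trail
#' for "FST < x, pi1 > y, pi2 > z") and counts at each stage.
#'
#' @param cfg a [scan_config()].
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly; files written: `windows.tsv`,
#'   `hdr_regions.bed`, `hdr_summary.tsv`, and optionally
#'   `repeat_contrast.tsv`, `genes.tsv`, `go_<ns>.tsv`, `cds_pi.tsv`,
#'   `correlations.tsv`, always `manifest.json`.
#' @export
run_scan <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "scan_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg[!vapply(cfg, is.null, TRUE) &
                                  !names(cfg) %in% "filters"],
                   filters = unclass(cfg$filters))

  pm <- stage("popmap", read_population_map(cfg$popmap))
  x <- stage("read_vcf", read_allsites_vcf(cfg$vcf))
  manifest$n_sites_read <- length(x$pos0)
  x <- stage("filter", apply_filters(x, cfg$filters))
  manifest$n_sites_removed <- attr(x, "n_sites_removed")
  manifest$n_genotypes_masked <- attr(x, "n_genotypes_masked")

  wins <- stage("windows", make_windows(x$contig_lengths, cfg$window_size))
  ws <- stage("window_stats", window_summaries(x, wins, pm))
  sel <- stage("hdr_select", select_hdr_windows(ws, cfg$q_fst, cfg$q_pi))
  regions <- stage("hdr_merge", merge_windows_to_regions(sel, cfg$max_gap))
  manifest$thresholds <- as.list(attr(sel, "thresholds"))
  manifest$n_windows <- nrow(ws)
  manifest$n_windows_retained <- sum(sel$retained)
  manifest$n_windows_selected <- sum(sel$selected)
  manifest$n_regions <- nrow(regions)

  fwrite(sel, file.path(out_dir, "windows.tsv"), sep = "\t")
  fwrite(regions[, .(chrom, start, end)],
         file.path(out_dir, "hdr_regions.bed"), sep = "\t",
         col.names = FALSE)
  fwrite(regions, file.path(out_dir, "hdr_summary.tsv"), sep = "\t")

  if (!is.null(cfg$recomb)) {
    rec <- stage("recomb", fread(cfg$recomb))
    m <- merge(as.data.table(sel), rec, by = c("chrom", "start", "end"))
    ct <- stage("correlations", {
      pops <- attr(sel, "pops")
      rows <- lapply(c("fst", paste0("pi_", pops), "dxy"), function(stat) {
        r <- pearson_correlation(m[[stat]], m$rate)
        data.table(stat = stat, vs = "recomb_rate", r = r$r, p = r$p,
                   n = r$n)
      })
      rbindlist(rows)
    })
    fwrite(ct, file.path(out_dir, "correlations.tsv"), sep = "\t")
  }

  if (!is.null(cfg$repeats)) {
    reps <- stage("repeats", parse_repeatmasker_out(cfg$repeats))
    prop <- stage("repeat_windows", window_repeat_proportion(reps, wins))
    in_hdr <- rep(FALSE, nrow(prop))
    if (nrow(regions)) {
      pg <- GenomicRanges::GRanges(prop$chrom,
                                   IRanges::IRanges(prop$start + 1L,
                                                    prop$end))
      rg <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1L,
                                                    regions$end))
      in_hdr <- GenomicRanges::countOverlaps(pg, rg) > 0
    }
    contrast <- rbindlist(lapply(
      grep("^prop_", names(prop), value = TRUE), function(cn) {
        wt <- tryCatch(welch_t_test(prop[[cn]][in_hdr],
                                    prop[[cn]][!in_hdr]),
                       error = function(e) list(t = NA, df = NA, p = NA))
        data.table(track = cn, mean_hdr = mean(prop[[cn]][in_hdr]),
                   mean_background = mean(prop[[cn]][!in_hdr]),
                   t = wt$t, df = wt$df, p = wt$p)
      }))
    fwrite(contrast, file.path(out_dir, "repeat_contrast.tsv"), sep = "\t")
  }

  genes <- NULL
  if (!is.null(cfg$gff)) {
    genes <- stage("genes", read_gff_genes(cfg$gff))
    genes <- stage("gene_overlap", genes_overlapping_regions(genes, regions))
    manifest$n_genes <- nrow(genes)
    manifest$n_genes_in_regions <- sum(genes$in_region)
    fwrite(genes, file.path(out_dir, "genes.tsv"), sep = "\t")
  }

  if (!is.null(cfg$obo) && !is.null(cfg$gene2go) && !is.null(genes)) {
    dag <- stage("obo", parse_obo(cfg$obo))
    g2g <- stage("gene2go",
                 build_gene2go(fread(cfg$gene2go), dag, propagate = TRUE))
    enr <- stage("go", run_enrichment(
      study = genes$gene_id[genes$in_region], universe = genes$gene_id,
      g2g = g2g, dag = dag, algorithm = cfg$go_algorithm,
      namespace = cfg$go_namespace, min_genes = cfg$go_min_genes))
    manifest$go_n_tested <- attr(enr, "n_tested")
    manifest$go_n_significant <- sum(enr$p_bonferroni <= cfg$go_alpha)
    fwrite(enr, file.path(out_dir,
                          sprintf("go_%s.tsv", cfg$go_namespace)),
           sep = "\t")
  }

  if (!is.null(cfg$cds)) {
    cds <- stage("cds", read_cds_fasta(cfg$cds))
    by_gene <- split(cds[status == "complete"], by = "copy")
    pis <- vapply(by_gene, function(d) cds_pi(d$seq), numeric(1))
    fwrite(data.table(gene = names(pis), pi_long = pis),
           file.path(out_dir, "cds_pi.tsv"), sep = "\t")
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
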