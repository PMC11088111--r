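#' Synthetic GO ontology and gene-to-GO map with implanted enrichment
#'
#' Builds a small random is_a DAG (one root per namespace used) plus a
#' two-level implanted chain root -> A -> B, and a gene2go table in which
#' the designated study set is strongly enriched for B (and hence,
#' by propagation, for A). Every other term's gene set draws study and
#' non-study genes proportionally to the study fraction, so background
#' terms are null by construction, not merely in expectation. Ground truth:
#' with classic testing the Bonferroni-significant set is exactly {A, B};
#' with elim, B's genes are eliminated from A before A is tested,
#' leaving {B}.
#'
#' @param n_genes universe size.
#' @param n_terms number of background (non-implanted) terms.
#' @param study_size study set size.
#' @param term_genes_B genes annotated to the implanted leaf B.
#' @param extra_genes_A extra genes annotated to A beyond B's.
#' @param study_from_B study genes drawn from B's genes (the implanted
#'   signal; the rest of the study is drawn from the complement).
#' @param bg_size_range annotated-gene count range for background terms.
#' @param seed integer RNG seed.
#' @return list: `dag` (a [parse_obo()]-compatible `go_dag` built in
#'   memory), `gene2go` (data.table `gene`, `term`), `study`, `universe`,
#'   `implanted` (character: c(A, B)), `obo_text` (the ontology as OBO
#'   lines, so the fixture also exercises [parse_obo()]).
#' @export
sim_go_fixture <- function(n_genes = 1000L, n_terms = 40L, study_size = 50L,
                           term_genes_B = 40L, extra_genes_A = 20L,
                           study_from_B = 20L,
                           bg_size_range = c(15L, 120L), seed = 1L) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  root <- "GO:0000001"; A <- "GO:0000002"; B <- "GO:0000003"
  bg <- sprintf("GO:%07d", 100L + seq_len(n_terms))
  ids <- c(root, A, B, bg)
  parents <- c(list(character(0), root, A),
               lapply(seq_len(n_terms), function(i) {
                 # random DAG: hang off root or an earlier background term
                 if (i == 1L || runif(1) < 0.4) root
                 else unique(sample(bg[seq_len(i - 1L)],
                                    sample.int(min(2L, i - 1L), 1L)))
               }))
  names(parents) <- ids

  obo <- c("format-version: 1.2", "")
  for (t in ids) {
    obo <- c(obo, "[Term]", paste0("id: ", t), paste0("name: term ", t),
             "namespace: biological_process",
             if (length(parents[[t]]))
               paste0("is_a: ", parents[[t]], " ! parent"), "")
  }
  dag <- parse_obo(textConnection_lines(obo))

  genes_B <- sample(genes, term_genes_B)
  genes_A <- c(genes_B, sample(setdiff(genes, genes_B), extra_genes_A))
  study <- c(sample(genes_B, study_from_B),
             sample(setdiff(genes, genes_B), study_size - study_from_B))
  g2g <- list(data.table(gene = genes_B, term = B),
              data.table(gene = genes_A, term = A),
              data.table(gene = genes, term = root))
  # background terms are null BY CONSTRUCTION: each draws study and
  # non-study genes in proportion to the study fraction, so no background
  # term can reach Bonferroni significance by sampling accident and the
  # implanted family is guaranteed to be the complete significant set
  nonstudy <- setdiff(genes, study)
  for (t in bg) {
    sz <- sample(bg_size_range[1]:bg_size_range[2], 1L)
    n_st <- min(length(study), round(sz * study_size / n_genes))
    g2g[[length(g2g) + 1L]] <- data.table(
      gene = c(sample(study, n_st), sample(nonstudy, sz - n_st)), term = t)
  }
  g2g <- rbindlist(g2g)
  list(dag = dag, gene2go = g2g, study = study, universe = genes,
       implanted = c(A = A, B = B), obo_text = obo)
}

# parse_obo from in-memory lines via a temp file (parse_obo reads a path)
textConnection_lines <- function(lines) {
  f <- tempfile(fileext = ".obo")
  writeLines(lines, f)
  f
}

#' Synthetic RepeatMasker-style annotation with depleted windows
#'
#' Places repeats of several superclasses by a Poisson process along the
#' window tiling; windows listed in `depleted` get their placement density
#' multiplied by `depletion` (e.g. 0.5 halves repeat density there),
#' emulating the repeat-depleted character of high-diversity regions.
#'
#' @param windows window table from [make_windows()].
#' @param density expected repeats per window at baseline.
#' @param depleted integer indices (rows of `windows`) to deplete.
#' @param depletion density multiplier for depleted windows.
#' @param superclasses superclass labels to draw from.
#' @param len_range repeat length range in bp.
#' @param seed integer RNG seed.
#' @return list: `repeats` (data.table `chrom`, `start`, `end`,
#'   `repeat_name`, `class_family`, `superclass`), `out_text` (the same in
#'   RepeatMasker `.out` layout, for [parse_repeatmasker_out()]).
#' @export
sim_repeat_fixture <- function(windows, density = 8, depleted = integer(0),
                               depletion = 0.5,
                               superclasses = c("DNA", "LINE", "SINE", "LTR",
                                                "Simple_repeat",
                                                "Low_complexity"),
                               len_range = c(30L, 400L), seed = 1L) {
  set.seed(seed)
  windows <- as.data.table(windows)
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    lam <- density * if (i %in% depleted) depletion else 1
    n <- rpois(1, lam)
    if (n == 0L) return(NULL)
    len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
    wlen <- windows$end[i] - windows$start[i]
    st <- windows$start[i] + floor(runif(n) * pmax(1, wlen - len))
    sc <- sample(superclasses, n, replace = TRUE)
    data.table(chrom = windows$chrom[i], start = as.integer(st),
               end = as.integer(st + len),
               repeat_name = paste0(sc, "-rep"),
               class_family = ifelse(sc %in% c("Simple_repeat",
                                               "Low_complexity"),
                                     sc, paste0(sc, "/fam1")),
               superclass = sc)
  })
  repeats <- rbindlist(rows)
  setorder(repeats, chrom, start)
  out_text <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "",
    sprintf(" %4d %5.1f %4.1f %4.1f  %s %8d %8d (%d) + %s %s %d %d (%d) %d",
            1000L + seq_len(nrow(repeats)), 10.0, 1.0, 1.0,
            repeats$chrom, repeats$start + 1L, repeats$end, 0L,
            repeats$repeat_name, repeats$class_family,
            1L, repeats$end - repeats$start, 0L, seq_len(nrow(repeats))))
  list(repeats = repeats[], out_text = out_text)
}

#' Synthetic non-overlapping gene annotation (GFF3)
#'
#' @param contig_lengths named vector of contig lengths.
#' @param n_genes number of genes.
#' @param len_range gene length range in bp.
#' @param seed integer RNG seed.
#' @return list: `genes` (data.table as from [read_gff_genes()]),
#'   `gff_text` (GFF3 lines).
#' @export
sim_gene_fixture <- function(contig_lengths, n_genes = 100L,
                             len_range = c(500L, 4000L), seed = 1L) {
  set.seed(seed)
  chroms <- sample(names(contig_lengths), n_genes, replace = TRUE,
                   prob = as.numeric(contig_lengths) /
                     sum(as.numeric(contig_lengths)))
  rows <- lapply(names(contig_lengths), function(ch) {
    n <- sum(chroms == ch)
    if (!n) return(NULL)
    len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
    # place without overlap: partition the contig and keep genes that fit
    gap <- floor(contig_lengths[[ch]] / n)
    st <- (seq_len(n) - 1L) * gap +
      floor(runif(n) * pmax(1, gap - len))
    keep <- st + len <= contig_lengths[[ch]]
    data.table(gene_id = NA_character_, chrom = ch,
               start = as.integer(st[keep]),
               end = as.integer(st[keep] + len[keep]),
               strand = sample(c("+", "-"), sum(keep), replace = TRUE),
               biotype = "protein_coding")
  })
  genes <- rbindlist(rows)
  setorder(genes, chrom, start)
  genes[, gene_id := sprintf("gene%04d", .I)]
  gff <- c("##gff-version 3",
           sprintf("%s\thdrscan_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_biotype=protein_coding",
                   genes$chrom, genes$start + 1L, genes$end, genes$strand,
                   genes$gene_id))
  list(genes = genes[], gff_text = gff)
}

#' Synthetic per-window recombination track correlated with FST
#'
#' Generates a nonnegative cM/Mb track whose Pearson correlation with a
#' supplied FST track is `rho` in expectation, by mixing the standardized
#' FST with Gaussian noise and mapping to a positive scale.
#'
#' @param fst numeric per-window FST track (windows with `NA` get `NA`).
#' @param rho target correlation (use negative values for the canonical
#'   negative FST/recombination relationship).
#' @param mean_rate,sd_rate location and spread of the emitted rates.
#' @param seed integer RNG seed.
#' @return Numeric vector of rates (cM/Mb), `NA` where `fst` is `NA`.
#' @export
sim_recomb_track <- function(fst, rho = -0.5, mean_rate = 3, sd_rate = 1,
                             seed = 1L) {
  stopifnot(abs(rho) <= 1)
  set.seed(seed)
  ok <- is.finite(fst)
  z <- (fst[ok] - mean(fst[ok])) / stats::sd(fst[ok])
  mix <- rho * z + sqrt(1 - rho^2) * stats::rnorm(sum(ok))
  out <- rep(NA_real_, length(fst))
  out[ok] <- pmax(0, mean_rate + sd_rate * mix)
  out
}

#' Synthetic aligned CDS set with planted pairwise distances
#'
#' Each sequence receives a disjoint set of private mutated positions, so
#' the pairwise difference count between sequences i and j is exactly
#' `private[i] + private[j]` and [cds_pi()] recovers the planted mean
#' pairwise distance exactly. Optional null copies carry a premature stop;
#' truncated copies are emitted shorter and flagged.
#'
#' @param length_bp alignment length (made divisible by 3).
#' @param private integer vector: private mutation count per sequence (its
#'   length sets the number of complete sequences).
#' @param n_null number of null copies (complete length, internal stop).
#' @param n_truncated number of truncated (pseudogene-like) copies.
#' @param assemblies assembly labels recycled across copies.
#' @param gene gene label used in copy ids.
#' @param seed integer RNG seed.
#' @return data.table: `assembly`, `copy`, `status`, `seq` (aligned; all
#'   complete/null sequences share `length_bp`).
#' @export
sim_cds_fixture <- function(length_bp = 300L, private = c(3L, 5L, 4L),
                            n_null = 0L, n_truncated = 0L,
                            assemblies = c("CS4_h1", "CS4_h2", "CS5_h1",
                                           "CS5_h2"),
                            gene = "geneX", seed = 1L) {
  set.seed(seed)
  length_bp <- as.integer(length_bp)
  m <- length(private)
  stopifnot(sum(private) <= length_bp)
  # ancestor built from stop-free codons, truncated to the exact length
  stops <- c("TAA", "TAG", "TGA")
  codons <- replicate(ceiling(length_bp / 3L), {
    repeat {
      cd <- paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE),
                  collapse = "")
      if (!cd %in% stops) return(cd)
    }
  })
  anc <- strsplit(paste(codons, collapse = ""), "")[[1]][seq_len(length_bp)]
  sites <- sample(length_bp, sum(private))
  idx <- split(sites, factor(rep(seq_len(m), private), levels = seq_len(m)))
  seqs <- vapply(seq_len(m), function(i) {
    s <- anc
    if (length(idx[[i]]))
      s[idx[[i]]] <- vapply(s[idx[[i]]], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    paste(s, collapse = "")
  }, "")
  # allelic copies of the same gene share its label across assemblies
  rows <- data.table(
    assembly = rep(assemblies, length.out = m),
    copy = gene,
    status = "complete", seq = seqs)
  if (n_null > 0L) {
    for (i in seq_len(n_null)) {
      s <- anc
      stop_at <- 3L * sample.int(length_bp %/% 3L - 2L, 1L) + 1L
      s[stop_at:(stop_at + 2L)] <- c("T", "A", "A")
      rows <- rbind(rows, data.table(
        assembly = assemblies[(m + i - 1L) %% length(assemblies) + 1L],
        copy = sprintf("%s_null%d", gene, i), status = "null",
        seq = paste(s, collapse = "")))
    }
  }
  if (n_truncated > 0L) {
    for (i in seq_len(n_truncated)) {
      keep <- 3L * sample.int(length_bp %/% 6L, 1L)
      rows <- rbind(rows, data.table(
        assembly = assemblies[(m + n_null + i - 1L) %% length(assemblies) + 1L],
        copy = sprintf("%s_psi%d", gene, i), status = "pseudogene",
        seq = paste(anc[seq_len(keep)], collapse = "")))
    }
  }
  rows[]
}
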