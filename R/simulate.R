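#' Configuration for the two-population split simulator
#'
#' Defaults describe the regime the windowed-scan estimators are validated
#' in: two cohorts of 10 diploids, per-site scaled mutation rate
#' theta = 4*N*mu = 0.005 (of the order of marine-fish silent diversity) and
#' a split T = 1 in units of 2N generations, which puts the expected
#' Hudson-style differentiation at T/(1+T) = 0.5.
#'
#' @param n1,n2 diploid sample sizes (>= 2 each, n1 + n2 <= 32).
#' @param L number of independent sites.
#' @param theta per-site scaled mutation rate (<= 0.05 so the probability
#'   of multiple hits stays negligible).
#' @param T_split split time in units of 2N generations (>= 0).
#' @param seed integer RNG seed.
#' @param chrom contig name for the emitted sites.
#' @param pop_names the two population labels.
#' @param mutation_model `"bernoulli"` (default; a site is variant with
#'   probability theta/2 x total branch length, exactly unbiased for the
#'   closed-form expectations) or `"poisson_redraw"` (Poisson mutation
#'   count, sites with >= 2 mutations redrawn; the rejection biases
#'   diversity low by a few percent at theta ~ 0.005 — see the methods
#'   vignette).
#' @return list of class `split_model_config`.
#' @export
split_model_config <- function(n1 = 10L, n2 = 10L, L = 200000L,
                               theta = 0.005, T_split = 1, seed = 1L,
                               chrom = "sim1",
                               pop_names = c("pop1", "pop2"),
                               mutation_model = c("bernoulli",
                                                  "poisson_redraw")) {
  stopifnot(n1 >= 2L, n2 >= 2L, n1 + n2 <= 32L, L >= 1L,
            theta >= 0, theta <= 0.05, T_split >= 0)
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), L = as.integer(L),
                 theta = theta, T_split = T_split, seed = as.integer(seed),
                 chrom = chrom, pop_names = pop_names,
                 mutation_model = match.arg(mutation_model)),
            class = "split_model_config")
}

# Build allsites genotypes from a variant-site/derived-haplotype pair.
masks_to_allsites <- function(sites_idx, derived, n1, n2, L, chrom,
                              pos_offset = 0L, contig_length = NULL) {
  N <- n1 + n2
  S <- L
  ref <- rep("A", S); alt <- rep("", S)
  gt1 <- matrix(0L, S, N); gt2 <- matrix(0L, S, N)
  if (length(sites_idx)) {
    alt[sites_idx] <- "T"
    hap1 <- derived[, seq(1L, 2L * N, by = 2L), drop = FALSE]
    hap2 <- derived[, seq(2L, 2L * N, by = 2L), drop = FALSE]
    gt1[sites_idx, ] <- as.integer(hap1)
    gt2[sites_idx, ] <- as.integer(hap2)
  }
  samples <- c(sprintf("p1_%02d", seq_len(n1)),
               sprintf("p2_%02d", seq_len(n2)))
  if (is.null(contig_length)) contig_length <- pos_offset + L
  allsites(rep(chrom, S), pos_offset + seq_len(S) - 1L, ref, alt, gt1, gt2,
           samples, setNames(contig_length, chrom))
}

#' Simulate an AllSites cohort under a clean two-population split
#'
#' Per site independently (no linkage), a structured-coalescent genealogy of
#' the 2(n1+n2) haploid lineages is drawn — within-population coalescence
#' until the split time, then a merged ancestral population — and at most
#' one mutation is placed on a branch chosen proportional to length, so
#' every variant is a biallelic SNP (see `mutation_model` in
#' [split_model_config()] for how the per-site mutation count is drawn).
#' Closed-form expectations: `E[pi] = theta` in each population,
#' `E[dxy] = theta (1 + T)`, and Hudson-style `1 - pi/dxy -> T/(1+T)`.
#'
#' @param cfg a [split_model_config()].
#' @return list with `sites` (an [allsites()] object; the matching
#'   [population_map()] is in `popmap`) and `truth` (the configuration plus
#'   the closed-form expectations).
#' @export
sim_split_coalescent <- function(cfg) {
  stopifnot(inherits(cfg, "split_model_config"))
  set.seed(cfg$seed)
  r <- .sim_split_sites_cpp(cfg$n1, cfg$n2, cfg$L, cfg$theta, cfg$T_split,
                            identical(cfg$mutation_model, "poisson_redraw"))
  x <- masks_to_allsites(r$site, r$derived, cfg$n1, cfg$n2, cfg$L, cfg$chrom)
  pm <- population_map(x$samples,
                       rep(cfg$pop_names, c(cfg$n1, cfg$n2)))
  truth <- list(theta = cfg$theta, T_split = cfg$T_split,
                E_pi = cfg$theta,
                E_dxy = cfg$theta * (1 + cfg$T_split),
                E_fst_hudson = cfg$T_split / (1 + cfg$T_split))
  list(sites = x, popmap = pm, truth = truth, config = cfg)
}

#' Configuration for the collapsed-paralog (CNV cross-mapping) simulator
#'
#' Models a multigene cluster whose K near-identical copies are collapsed
#' into one locus on the reference, so short reads from every copy pile onto
#' it: paralogous sequence variants (PSVs, fixed differences between copies)
#' then appear as polymorphic sites that are heterozygous in essentially
#' every individual.
#'
#' @param K number of paralog copies (>= 2).
#' @param psv_density per-bp probability that a position is a PSV
#'   (divergence between copies; 0 < d < 0.2).
#' @param presence_prob probability that a haplotype carries each copy
#'   (1 = no CNV, every haplotype has every copy).
#' @param allelic_theta per-site scaled mutation rate of true allelic
#'   variation within each copy (0 disables it).
#' @param span cluster length in bp.
#' @param seed integer RNG seed.
#' @return list of class `collapse_config`.
#' @export
collapse_config <- function(K = 2L, psv_density = 0.02, presence_prob = 1,
                            allelic_theta = 0, span = 5000L, seed = 1L) {
  stopifnot(K >= 2L, psv_density > 0, psv_density < 0.2,
            presence_prob > 0, presence_prob <= 1,
            allelic_theta >= 0, allelic_theta <= 0.05, span >= 1L)
  structure(list(K = as.integer(K), psv_density = psv_density,
                 presence_prob = presence_prob,
                 allelic_theta = allelic_theta, span = as.integer(span),
                 seed = as.integer(seed)),
            class = "collapse_config")
}

#' Simulate the collapsed-cluster artifact over a two-population cohort
#'
#' Generates the apparent genotypes a collapsed reference would yield. Each
#' haplotype of each individual carries each of the K copies with
#' probability `presence_prob`; at each PSV position one copy (chosen
#' uniformly) carries the derived allele, and an individual's collapsed
#' genotype is heterozygous iff its pooled copies carry both alleles,
#' homozygous for the allele they do carry otherwise, and missing if it
#' pools no copies. True allelic variation within copies (when
#' `allelic_theta > 0`) is laid on top via per-copy split-coalescent sites,
#' pooled the same way.
#'
#' With all copies on every haplotype and no allelic variation, every PSV is
#' heterozygous in all samples: apparent per-site pi is n/(2(n-1)) for n
#' called alleles, apparent window pi is ~ d n/(2(n-1)), apparent allele
#' frequencies are 0.5 in both populations so Weir-Cockerham FST collapses
#' to ~0 — a low-FST/high-pi island, the artifact this package's scan
#' detects.
#'
#' @param cfg a [collapse_config()].
#' @param n1,n2 diploid sample sizes per population.
#' @param T_split split time used for allelic variation within copies.
#' @param chrom contig name.
#' @param pos_offset 0-based start of the cluster on the contig.
#' @param contig_length declared contig length (default: cluster end).
#' @return list with `sites`, `popmap`, and `truth` (per-site PSV
#'   expectations and the expected apparent window pi).
#' @export
sim_collapsed_cluster <- function(cfg, n1 = 10L, n2 = 10L, T_split = 1,
                                  chrom = "sim1", pos_offset = 0L,
                                  contig_length = NULL) {
  stopifnot(inherits(cfg, "collapse_config"))
  set.seed(cfg$seed)
  N <- n1 + n2; H <- 2L * N; S <- cfg$span
  # copy presence per haplotype
  present <- matrix(runif(H * cfg$K) < cfg$presence_prob, H, cfg$K)
  is_psv <- runif(S) < cfg$psv_density
  psv_pos <- which(is_psv)
  psv_copy <- sample.int(cfg$K, length(psv_pos), replace = TRUE)

  # per-haplotype pooled allele content: for each PSV, haplotype carries alt
  # iff it has the carrier copy, ref iff it has any other copy
  gt1 <- matrix(0L, S, N); gt2 <- matrix(0L, S, N)
  ref <- rep("A", S); alt <- rep("", S)
  alt[psv_pos] <- "T"
  hap_has_copy <- present                       # H x K
  hap_any_other <- vapply(seq_len(cfg$K), function(k)
    rowSums(present[, -k, drop = FALSE]) > 0, logical(H))  # H x K
  ind1 <- seq(1L, H, by = 2L); ind2 <- ind1 + 1L
  for (v in seq_along(psv_pos)) {
    k <- psv_copy[v]
    hap_alt <- hap_has_copy[, k]
    hap_ref <- hap_any_other[, k]
    ind_alt <- hap_alt[ind1] | hap_alt[ind2]
    ind_ref <- hap_ref[ind1] | hap_ref[ind2]
    g1 <- ifelse(ind_ref, 0L, ifelse(ind_alt, 1L, NA_integer_))
    g2 <- ifelse(ind_alt, 1L, ifelse(ind_ref, 0L, NA_integer_))
    gt1[psv_pos[v], ] <- g1
    gt2[psv_pos[v], ] <- g2
  }

  # true allelic variation within each copy, pooled over present copies
  if (cfg$allelic_theta > 0) {
    for (k in seq_len(cfg$K)) {
      r <- .sim_split_sites_cpp(n1, n2, S, cfg$allelic_theta, T_split)
      keep <- which(!(r$site %in% psv_pos))
      for (v in keep) {
        s <- r$site[v]
        der <- r$derived[v, ]                       # per haplotype, copy k
        hap_alt <- der & present[, k]
        hap_ref <- (present[, k] & !der) | hap_any_other[, k]
        ind_alt <- hap_alt[ind1] | hap_alt[ind2]
        ind_ref <- hap_ref[ind1] | hap_ref[ind2]
        has_any <- (present[ind1, , drop = FALSE] |
                      present[ind2, , drop = FALSE])
        called <- rowSums(has_any) > 0
        g1 <- ifelse(ind_ref, 0L, ifelse(ind_alt, 1L, NA_integer_))
        g2 <- ifelse(ind_alt, 1L, ifelse(ind_ref, 0L, NA_integer_))
        g1[!called] <- NA_integer_; g2[!called] <- NA_integer_
        if (any(g1 == 1L | g2 == 1L, na.rm = TRUE)) {
          gt1[s, ] <- g1; gt2[s, ] <- g2
          if (alt[s] == "") alt[s] <- "T"
        }
      }
    }
  }

  # haplotypes with no copy at all yield missing genotypes everywhere
  no_copy_ind <- which(rowSums(present[ind1, , drop = FALSE] +
                                 present[ind2, , drop = FALSE]) == 0)
  if (length(no_copy_ind)) {
    gt1[, no_copy_ind] <- NA_integer_
    gt2[, no_copy_ind] <- NA_integer_
  }

  samples <- c(sprintf("p1_%02d", seq_len(n1)),
               sprintf("p2_%02d", seq_len(n2)))
  if (is.null(contig_length)) contig_length <- pos_offset + S
  x <- allsites(rep(chrom, S), pos_offset + seq_len(S) - 1L, ref, alt,
                gt1, gt2, samples, setNames(contig_length, chrom))
  pm <- population_map(samples, rep(c("pop1", "pop2"), c(n1, n2)))
  n_alleles_pop <- 2 * c(n1, n2)
  truth <- list(
    n_psv = length(psv_pos), psv_pos0 = pos_offset + psv_pos - 1L,
    psv_copy = psv_copy, present = present,
    E_site_pi = n_alleles_pop / (2 * (n_alleles_pop - 1)),
    E_window_pi = cfg$psv_density * n_alleles_pop /
      (2 * (n_alleles_pop - 1)),
    E_fst = 0)
  list(sites = x, popmap = pm, truth = truth, config = cfg)
}

#' Inject random genotype missingness
#'
#' Each called genotype is independently set to missing with probability
#' `rate`; the ratio-of-sums estimators are invariant in expectation to
#' this masking.
#'
#' @param x an [allsites()] object.
#' @param rate missingness probability in [0, 1).
#' @param seed integer RNG seed.
#' @return The masked `allsites` object.
#' @export
inject_missingness <- function(x, rate, seed = 1L) {
  stopifnot(inherits(x, "allsites"), rate >= 0, rate < 1)
  if (rate == 0) return(x)
  set.seed(seed)
  drop <- matrix(runif(length(x$gt1)) < rate, nrow(x$gt1))
  x$gt1[drop] <- NA_integer_
  x$gt2[drop] <- NA_integer_
  x
}

#' Composite genome: split baseline with embedded collapsed clusters
#'
#' Tiles `n_windows` fixed-size windows over several contigs, simulates the
#' split model everywhere, and replaces `n_clusters` randomly placed whole
#' windows with collapsed-cluster output. This is the end-to-end fixture for
#' the scan: collapsed windows must surface in the joint low-FST/high-pi
#' tails and be recovered by [select_hdr_windows()].
#'
#' @param split_cfg a [split_model_config()] (its `L` is ignored; window
#'   tiling defines the length).
#' @param collapse_cfg a [collapse_config()] with `span` equal to
#'   `window_size`.
#' @param n_windows total windows in the genome.
#' @param n_clusters number of collapsed windows to implant.
#' @param window_size window size in bp.
#' @param windows_per_contig windows per simulated contig (memory is
#'   bounded per contig).
#' @param seed integer RNG seed.
#' @return list with `sites_by_contig` (list of [allsites()]),
#'   `contig_lengths`, `popmap`, `cluster_windows` (data.table of implanted
#'   window coordinates) and `truth` from the collapse simulator.
#' @export
sim_composite_genome <- function(split_cfg, collapse_cfg,
                                 n_windows = 1000L, n_clusters = 20L,
                                 window_size = 5000L,
                                 windows_per_contig = 100L, seed = 1L) {
  stopifnot(collapse_cfg$span == window_size, n_clusters < n_windows)
  window_size <- as.integer(window_size)
  n_windows <- as.integer(n_windows)
  windows_per_contig <- as.integer(windows_per_contig)
  set.seed(seed)
  cluster_at <- sort(sample.int(n_windows, n_clusters))
  n_contig <- ceiling(n_windows / windows_per_contig)
  contigs <- sprintf("simc%02d", seq_len(n_contig))
  seeds <- sample.int(.Machine$integer.max, 2L * n_windows)
  sites_by_contig <- vector("list", n_contig)
  contig_lengths <- numeric(0)
  cl_rows <- list()
  truth <- NULL
  pm <- NULL
  w_global <- 0L
  for (ci in seq_len(n_contig)) {
    nw <- min(windows_per_contig, n_windows - (ci - 1L) * windows_per_contig)
    parts <- vector("list", nw)
    for (wi in seq_len(nw)) {
      w_global <- w_global + 1L
      off <- (wi - 1L) * window_size
      if (w_global %in% cluster_at) {
        cc <- collapse_cfg; cc$seed <- seeds[2L * w_global - 1L]
        sim <- sim_collapsed_cluster(cc, split_cfg$n1, split_cfg$n2,
                                     split_cfg$T_split, chrom = contigs[ci],
                                     pos_offset = off,
                                     contig_length = nw * window_size)
        truth <- sim$truth
        cl_rows[[length(cl_rows) + 1L]] <-
          data.table(chrom = contigs[ci], start = as.integer(off),
                     end = as.integer(off + window_size),
                     n_psv = sim$truth$n_psv)
      } else {
        sc <- split_cfg; sc$L <- window_size
        sc$seed <- seeds[2L * w_global]
        sc$chrom <- contigs[ci]
        sim <- sim_split_coalescent(sc)
        sim$sites$pos0 <- sim$sites$pos0 + off
        sim$sites$contig_lengths <- setNames(nw * window_size, contigs[ci])
      }
      parts[[wi]] <- sim$sites
      pm <- sim$popmap
    }
    sites_by_contig[[ci]] <- concat_sites(parts)
    contig_lengths[contigs[ci]] <- nw * window_size
  }
  list(sites_by_contig = sites_by_contig, contig_lengths = contig_lengths,
       popmap = pm,
       cluster_windows = rbindlist(cl_rows),
       truth = truth)
}
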