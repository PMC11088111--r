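---
title: "Methods: windowed diversity scans, high-diversity regions, and the collapsed-paralog artifact"
author: "hdrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed diversity scans and high-diversity regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Genome scans comparing two closely related populations or sister species
usually look for windows of *elevated* differentiation. The mirror-image
signal is just as interesting and far less studied: windows where
Weir–Cockerham $F_{ST}$ drops far below the genomic baseline while
nucleotide diversity $\pi$ is high *in both* cohorts and between-population
divergence $d_{xy}$ is not reduced. Clusters of fast-evolving immune genes
produce exactly this signature, for two very different reasons:

1. **Biology** — balancing selection and gene birth-and-death maintain deep
   allelic variation shared across the split.
2. **Artifact** — when near-identical gene copies are collapsed into one
   locus on the reference, short reads from every copy cross-map onto it.
   Fixed differences between copies (paralogous sequence variants, PSVs)
   then masquerade as polymorphic sites that are heterozygous in
   essentially every individual: apparent $\pi$ is inflated, apparent
   allele frequencies sit near $1/2$ in both cohorts, and $F_{ST}$
   collapses toward zero.

`hdrscan` implements the whole scan — missing-data-aware windowed
estimators from AllSites VCFs, joint-percentile calling of high-diversity
regions (HDRs), repeat/gene annotation, hierarchy-aware GO
overrepresentation, haplotype-resolved coding-sequence diversity — plus
simulators that generate data with known truth for both the biological and
the artifactual signal.

## Estimators

All windowed statistics are **ratios of sums**. For each biallelic SNP or
invariant site $s$ and population $p$ with $n_{ps}$ called alleles of which
$a_{ps}$ are alternate,

$$\hat\pi_p = \frac{\sum_s (n_{ps}-a_{ps})\,a_{ps}}
                   {\sum_s n_{ps}(n_{ps}-1)/2},\qquad
  \hat d_{xy} = \frac{\sum_s (n_{1s}-a_{1s})a_{2s} + a_{1s}(n_{2s}-a_{2s})}
                     {\sum_s n_{1s} n_{2s}},$$

summing numerators and denominators over the window *before* dividing.
Invariant sites contribute zero to numerators but their comparison counts
to denominators; a genotype set missing reduces both. This is what makes
the estimators unbiased under arbitrary per-genotype missingness — the
property the test suite verifies by Monte-Carlo masking — and it is why an
AllSites VCF (invariant records retained) is a hard input requirement:
dropping invariant sites silently turns the denominator into "number of
SNPs" and inflates $\pi$ by orders of magnitude.

$F_{ST}$ uses the diploid two-population variance components $a$, $b$, $c$
of Weir & Cockerham (1984), computed per site from per-population sample
sizes, allele frequencies and observed heterozygote counts, and aggregated
as $\sum a / \sum (a+b+c)$ over the window. Per-site ratios are never
averaged; negative estimates are reported unclipped. Sites where either
population has fewer than two called genotypes contribute nothing to
$F_{ST}$ but still feed $\pi$ (where $n \ge 2$) and $d_{xy}$ (where both
$n \ge 1$) — maximizing data use, matching the reference estimator's
documented behaviour. Multiallelic and indel sites contribute to nothing
and are counted in a log attribute.

Coordinates are 0-based half-open internally; 1-based conversion happens
only in the VCF/GFF/RepeatMasker readers and writers. Half-called
genotypes (`./1`) are treated as fully missing — the simplest consistent
contract, since upstream callers differ in how they emit them.

## Filters

Defaults reproduce the standard GATK germline hard-filter recipe for
SNPs — remove sites with FS > 60, MQRankSum < −12.5, MQ < 40, QD < 2,
ReadPosRankSum < −8 or SOR > 3 — plus genotype masking at GQ < 20, DP < 2
or DP > 100. All bounds are strict (DP = 100 survives), absent INFO
metrics never remove a site (GATK semantics for missing annotations), and
invariant records, which lack variant-site annotations, are therefore
never removed by them. Filtering is total, idempotent, and genotype
masking commutes with indel dropping.

## HDR calling

Windows missing any statistic (zero denominator anywhere) are excluded;
thresholds are then computed genome-wide on the retained set: the lower
`q_fst` = 5% quantile of $F_{ST}$ and the upper `q_pi` = 95% quantile of
$\pi$ in each population, with the type-7 linear-interpolation quantile
(the default of mainstream statistical environments). A window is selected
iff $F_{ST} < $ cut **and** $\pi > $ cut in **both** populations, strict
inequalities. Selected windows merge into regions, bridging up to
`max_gap` unselected windows (default 0; the merging rule upstream of the
published region tables is not stated, so the knob is exposed). The
realized thresholds are recorded in the run manifest so any scan is
auditable in the form "$F_{ST} < x$, $\pi_1 > y$, $\pi_2 > z$".

## Annotation and GO

Repeat coverage per window is the **union** of repeat intervals clipped to
the window (a base under two nested repeats counts once; additive mode is
available as a switch since the upstream choice is not stated), per
superclass (prefix before `/` in the RepeatMasker class/family column) and
overall. HDR-versus-background contrasts use Welch's unequal-variance $t$
with Satterthwaite degrees of freedom. Gene overlap is gene-level
(protein-coding when a biotype is annotated), flagged at $\ge$ 1 bp
half-open intersection.

GO overrepresentation runs on ancestor-propagated annotations restricted
to one namespace, excludes terms with fewer than 10 annotated universe
genes, and tests the one-sided hypergeometric upper tail. Two algorithms
are provided: `classic` (every term independent) and `elim`, which
processes terms deepest-first and, when a term reaches
`p <= elim_cutoff` (0.01), removes its genes from all ancestors before
they are tested — decorrelating nested terms so parents are not flagged
merely for containing a significant child. The reference analysis used
`weight01`, whose exact semantics interleave elim- and weight-style
down-weighting; `elim` is the fully specified member of that family and
captures the decorrelation behaviour the analysis relies on, so it is the
default here and `weight01` is declared out of scope. Bonferroni
correction multiplies by the number of tested terms, as in the upstream
analysis, although decorrelated p-values are not independent — we follow
that convention deliberately. The DAG uses `is_a` edges by default;
`part_of` can be added with a flag (the upstream hierarchy choice is
unstated).

## Long-read side

For copy-number-variable clusters, per-haplotype assemblies give direct
access to allelic sequences. `tabulate_copy_number()` reproduces the
copy-table semantics — complete and null copies (inactivating mutations)
both count as genes, pseudogene fragments separately. `cds_pi()` is the
mean pairwise p-distance over aligned coding sequences
($\frac{2}{m(m-1)}\sum_{i<j} d_{ij}/L_{ij}$), pairwise deletion by default
(the convention of the standard R estimator it replaces), complete
deletion as an option; alignment itself is delegated to external MSA
tools, as upstream. `compare_pi()` joins long-read and short-read per-gene
estimates and flags `short > long` — the collapse-inflation signature.
Deflation (short < long, alleles missed by mapping) is reported unflagged:
the module reports, it does not interpret.

## Simulators: the stated world

The generators are first-class, tested code; their defaults are the
conditions the validation criteria state.

**Split model** (`sim_split_coalescent`): per site independently, a
structured-coalescent genealogy of the $2(n_1+n_2)$ haploid lineages —
within-deme coalescence at rate $\binom{k}{2}$ until the split time $T$
(units of $2N$ generations), then a merged ancestral population — with at
most one mutation per site placed on a branch chosen proportional to
length. Defaults $n_1=n_2=10$, $\theta = 4N\mu = 0.005$ per site (the
order of silent-site diversity in large marine fish populations), $T=1$,
giving $E[\pi]=\theta$, $E[d_{xy}]=\theta(1+T)$ and Hudson-style
$1-\pi/d_{xy} = T/(1+T) = 0.5$.

*Numerical choice worth recording*: drawing the per-site mutation count as
Poisson$(\tfrac{\theta}{2} T_{tot})$ and redrawing sites with $\ge 2$ hits
keeps sites biallelic but reweights every site by
$(1+\lambda)e^{-\lambda}$, down-weighting long genealogies; at
$\theta = 0.005$ this biases $\hat\pi$ and $\hat d_{xy}$ low by 4–5%,
several times the Monte-Carlo error of the recovery checks. The default
therefore draws the count as Bernoulli$(\tfrac{\theta}{2} T_{tot})$ — the
single-mutation analogue of Poisson thinning — which never conditions the
genealogy on the mutation outcome and is exactly unbiased:
$E[\text{pair difference}] = \tfrac{\theta}{2} E[\text{pair path length}]$.
The Poisson-redraw mechanism remains available as
`mutation_model = "poisson_redraw"` for anyone wanting to reproduce its
bias. Per-site independence (no linkage) is a stated limitation: means are
faithful, window-to-window autocorrelation of real genomes is not
emulated, so a green recovery test establishes estimator calibration, not
realistic genomic noise.

**Collapsed cluster** (`sim_collapsed_cluster`): $K$ paralog copies
diverged at PSV density $d$ (each PSV's derived allele carried by one
copy), each haplotype carrying each copy with probability
`presence_prob` (CNV), optional true allelic variation within copies. The
emitted genotype at a PSV is deterministic given the pooled copies:
heterozygous iff they carry both alleles, missing iff the individual pools
no copy — a deterministic idealization of read sampling (a read-depth
binomial option exists for robustness tests). With all copies present and
no allelic variation, every PSV is heterozygous in everyone: apparent
per-site $\pi = n/(2(n-1))$ for $n$ called alleles (the enumeration oracle
over all pairs at an all-heterozygote site), apparent window
$\pi \approx d\,n/(2(n-1))$, apparent allele frequencies $1/2$ in both
cohorts so the Weir–Cockerham components vanish and window $F_{ST} = 0$ —
the low-$F_{ST}$/high-$\pi$ island the scan must find.

**Composite genome** (`sim_composite_genome`): a split-model baseline of
1000 × 5 kb windows with 20 whole windows replaced by collapsed clusters
(sizes chosen to match the validation cohort of the split model and an
implanted fraction safely below the 5% selection quantile), generated
per-contig to bound memory. End-to-end, the implanted windows must fall in
the joint tails and be recovered by the caller with zero false positives.

**Fixtures** (`sim_go_fixture`, `sim_repeat_fixture`, `sim_gene_fixture`,
`sim_recomb_track`, `sim_cds_fixture`): a random GO DAG with an implanted
two-level family (root → A → B) whose study enrichment sits in the leaf;
background terms draw study/non-study genes proportionally, so they are
null *by construction*, making "the implanted family is exactly the
Bonferroni-significant set" a guarantee rather than a high-probability
event. Repeats are Poisson-placed with a density multiplier for designated
windows; the recombination track mixes standardized $F_{ST}$ with Gaussian
noise to hit a target correlation; CDS fixtures plant disjoint private
mutations so every pairwise distance is known exactly, with optional
premature-stop null copies and truncated pseudogenes. All simulators are
seed-deterministic: same configuration and seed, byte-identical outputs.

## What the tests establish — and what they do not

Oracle tests prove the production estimators equal independent
re-implementations (all-pairs sequence comparison; scalar per-site
Weir–Cockerham; `choose()`-sum hypergeometric tails; double-loop
p-distance) on random inputs with missingness. Recovery tests prove the
estimators are calibrated in the simulators' stated world: free
recombination between sites, no sequencing error, no mapping bias other
than the modelled collapse, mutation–drift equilibrium. Real AllSites
VCFs violate all of these to some degree; the scan's outputs on real data
inherit those caveats, and the printed genome-wide numbers of any
particular study (averages, thresholds, window counts) are properties of
its full dataset, not reproducible from synthetic inputs.

## Known limitations

- Two populations only; the Weir–Cockerham machinery is the $r=2$ diploid
  form.
- `weight01` GO semantics not implemented (see above); `elim` and
  `classic` only.
- Collapse genotypes are deterministic given pooled copies; no
  base-calling error model.
- Haplotype masks cap cohorts at 32 diploids in the simulators (64-bit
  masks); the estimators themselves have no such limit.
- No linkage, no Tajima's D, no sliding windows, no plotting — all
  deliberate non-goals.
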