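test_that("RepeatMasker .out parsing round-trips coordinates and superclasses", {
  wins <- make_windows(c(c1 = 20000), 5000)
  fx <- sim_repeat_fixture(wins, density = 2, seed = 4)
  p <- tempfile(fileext = ".out")
  writeLines(fx$out_text, p)
  got <- parse_repeatmasker_out(p)
  expect_equal(nrow(got), nrow(fx$repeats))
  expect_equal(got$start, fx$repeats$start)
  expect_equal(got$end, fx$repeats$end)
  expect_equal(got$superclass, fx$repeats$superclass)
  # superclass mapping: prefix before "/"
  expect_equal(unique(got$superclass[got$class_family == "LINE/fam1"]),
               "LINE")
  expect_true(all(got$superclass[got$class_family == "Simple_repeat"] ==
                    "Simple_repeat"))
  # malformed row errors with its line number
  writeLines(c(fx$out_text, " 100 1.0 1.0 1.0 c1 oops"), p)
  expect_error(parse_repeatmasker_out(p), "line")
})

test_that("window repeat proportions use union coverage with clipping", {
  wins <- data.table::data.table(chrom = "c1", start = c(0L, 5000L),
                                 end = c(5000L, 10000L))
  # one repeat covering half of window 1
  r1 <- data.table::data.table(chrom = "c1", start = 0L, end = 2500L,
                               superclass = "DNA")
  p1 <- window_repeat_proportion(r1, wins)
  expect_equal(p1$prop_total, c(0.5, 0))

  # overlapping repeats of one superclass: union = 150 bases, not 200
  r2 <- data.table::data.table(chrom = "c1", start = c(0L, 50L),
                               end = c(100L, 150L), superclass = "LINE")
  p2 <- window_repeat_proportion(r2, wins)
  expect_equal(p2$prop_total[1], 150 / 5000)
  expect_equal(p2$prop_LINE[1], 150 / 5000)
  p2s <- window_repeat_proportion(r2, wins, mode = "sum")
  expect_equal(p2s$prop_total[1], 200 / 5000)

  # repeat spanning the window boundary splits its contribution
  r3 <- data.table::data.table(chrom = "c1", start = 4000L, end = 6000L,
                               superclass = "LTR")
  p3 <- window_repeat_proportion(r3, wins)
  expect_equal(p3$prop_total, c(1000 / 5000, 1000 / 5000))

  # disjoint superclasses sum exactly to the total
  r4 <- data.table::data.table(chrom = "c1",
                               start = c(0L, 1000L, 6000L),
                               end = c(500L, 1200L, 6600L),
                               superclass = c("DNA", "LINE", "DNA"))
  p4 <- window_repeat_proportion(r4, wins)
  percl <- rowSums(as.matrix(p4[, .(prop_DNA, prop_LINE)]))
  expect_equal(percl, p4$prop_total)
})

test_that("welch_t_test matches the closed form and stats::t.test", {
  r <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_error(welch_t_test(rep(0, 4), rep(1, 4)), "variance")
  expect_error(welch_t_test(1, c(1, 2)), ">= 2")

  x <- c(2.1, 2.5, 2.3); y <- c(1.1, 1.0, 1.2)
  got <- welch_t_test(x, y)
  tt <- stats::t.test(x, y)
  expect_equal(got$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(got$df, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(got$p, tt$p.value, tolerance = 1e-10)

  # equal sizes and variances: df reduces to the pooled 2n - 2
  set.seed(8)
  a <- rnorm(10); b <- a + 0.5    # identical sample variance
  expect_equal(welch_t_test(a, b)$df, 18)
})

test_that("welch test rejects on the depleted-window repeat fixture", {
  wins <- make_windows(c(c1 = 300 * 5000), 5000)
  hdr_idx <- 1:100                                 # >= 200 per group overall
  fx <- sim_repeat_fixture(wins, density = 8, depleted = hdr_idx,
                           depletion = 0.5, seed = 17)
  prop <- window_repeat_proportion(fx$repeats, wins)
  wt <- welch_t_test(prop$prop_total[hdr_idx], prop$prop_total[-hdr_idx])
  expect_lt(wt$p, 0.001)
  expect_lt(mean(prop$prop_total[hdr_idx]),
            mean(prop$prop_total[-hdr_idx]))
})

test_that("gene/region overlap is half-open and matches brute force", {
  genes <- data.table::data.table(
    gene_id = c("g1", "g2"), chrom = "c1",
    start = c(100L, 100L), end = c(200L, 200L),
    strand = "+", biotype = "protein_coding")
  regions <- data.table::data.table(chrom = "c1", start = c(199L, 200L),
                                    end = c(300L, 300L))
  got <- genes_overlapping_regions(genes, regions[1])
  expect_true(got$in_region[1])                    # 1 bp overlap
  got2 <- genes_overlapping_regions(genes, regions[2])
  expect_false(got2$in_region[1])                  # adjacent, no overlap

  set.seed(30)
  g10 <- data.table::data.table(
    gene_id = sprintf("g%d", 1:10), chrom = "c1",
    start = as.integer(seq(0, 9000, by = 1000)),
    end = as.integer(seq(0, 9000, by = 1000)) + 800L,
    strand = "+", biotype = "protein_coding")
  reg <- data.table::data.table(chrom = "c1", start = c(2500L, 7900L),
                                end = c(3100L, 8200L))
  got3 <- genes_overlapping_regions(g10, reg)
  brute <- vapply(seq_len(10), function(i)
    any(pmax(g10$start[i], reg$start) < pmin(g10$end[i], reg$end)),
    logical(1))
  expect_equal(got3$in_region, brute)
  # empty region set
  got4 <- genes_overlapping_regions(g10, reg[0])
  expect_false(any(got4$in_region))
})

test_that("GFF3 genes read through rtracklayer with biotype filtering", {
  fx <- sim_gene_fixture(c(c1 = 50000, c2 = 30000), n_genes = 20, seed = 2)
  p <- tempfile(fileext = ".gff3")
  writeLines(fx$gff_text, p)
  genes <- read_gff_genes(p)
  expect_equal(nrow(genes), nrow(fx$genes))
  expect_equal(genes$start, fx$genes$start)
  expect_equal(genes$end, fx$genes$end)
  expect_equal(genes$gene_id, fx$genes$gene_id)
  # non-coding genes are dropped when biotype is annotated
  extra <- sub("gene_biotype=protein_coding", "gene_biotype=lncRNA",
               fx$gff_text[2])
  extra <- sub("ID=gene0001", "ID=geneNC", extra)
  writeLines(c(fx$gff_text, extra), p)
  genes2 <- read_gff_genes(p)
  expect_false("geneNC" %in% genes2$gene_id)
  genes3 <- read_gff_genes(p, protein_coding_only = FALSE)
  expect_true("geneNC" %in% genes3$gene_id)
})
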