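ann_two_genes <- function() {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      strand = c("+", "-"), start = c(5000L, 20000L),
                      end = c(9000L, 24000L),
                      biotype = c("protein_coding", "pseudogene"))
  exons <- data.frame(gene_id = c("gA", "gA", "gB"),
                      start = c(5000L, 7000L, 20000L),
                      end = c(6000L, 9000L, 24000L))
  make_annotation(genes, exons, chrom_len = 50000L,
                  promoter_length = 2000)
}

test_that("feature assignment is strand-aware with documented priority", {
  ann <- ann_two_genes()
  got <- assign_feature("chr1", c(5500, 4900, 6500, 100, 24500, 19000),
                        ann)
  expect_equal(got$feature, c("exon",       # inside first exon of gA
                              "promoter",   # 100 bp upstream of gA TSS
                              "intron",     # between gA exons
                              "intergenic",
                              "promoter",   # upstream of minus-strand gB
                              "intergenic"))
  expect_equal(got$gene_id[1:3], c("gA", "gA", "gA"))
  expect_equal(got$gene_id[5], "gB")

  # promoter of one gene overlapping an exon of another wins
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = "+", start = c(1000L, 4000L),
                      end = c(3000L, 6000L), biotype = "protein_coding")
  exons <- data.frame(gene_id = c("g1", "g2"), start = c(1000L, 4000L),
                      end = c(3000L, 6000L))
  ann2 <- make_annotation(genes, exons, promoter_length = 2000)
  # 2500 is inside g1's exon and inside g2's promoter [2000,4000)
  expect_equal(assign_feature("chr1", 2500, ann2)$feature, "promoter")
  expect_equal(assign_feature("chr1", 2500, ann2)$gene_id, "g2")
})

test_that("gene methylation averages site ratios over the gene span", {
  ann <- ann_two_genes()
  ctl <- make_sites("chr1", c(5100, 5200, 8000), c(2, 4, 6), c(8, 6, 4))
  trt <- make_sites("chr1", c(5100, 5200, 8000), c(5, 5, 5), c(5, 5, 5))
  pairs <- pair_sites(ctl, trt)
  gm <- gene_methylation(pairs, ann)
  expect_equal(nrow(gm), 1L)
  expect_equal(gm$gene_id, "gA")
  expect_equal(gm$ratio_c, mean(c(0.2, 0.4, 0.6)))
  expect_equal(gm$ratio_t, 0.5)
  expect_equal(gm$total_c, 30L)

  # single qualifying site: gene values equal site values
  gm1 <- gene_methylation(pair_sites(ctl[1], trt[1]), ann)
  expect_equal(gm1$ratio_c, 0.2)
  expect_equal(gm1$n_sites, 1L)

  # identical conditions: p = 1, diff = 0
  same <- gene_methylation(pair_sites(ctl, ctl), ann)
  expect_equal(same$p, 1)
  expect_equal(same$diff, 0)
})

test_that("gene-level calls ignore exon/intron restructuring", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 1000L, end = 5000L,
                      biotype = "protein_coding")
  ex1 <- data.frame(gene_id = "g1", start = 1000L, end = 5000L)
  ex2 <- data.frame(gene_id = "g1", start = c(1000L, 3000L),
                    end = c(2000L, 5000L))
  ctl <- make_sites("chr1", seq(1100, 4900, 200), 3, 7)
  trt <- make_sites("chr1", seq(1100, 4900, 200), 6, 4)
  pairs <- pair_sites(ctl, trt)
  gm1 <- gene_methylation(pairs, make_annotation(genes, ex1))
  gm2 <- gene_methylation(pairs, make_annotation(genes, ex2))
  expect_equal(as.data.frame(gm1), as.data.frame(gm2))

  # condition-swap antisymmetry at gene level
  rev <- gene_methylation(pair_sites(trt, ctl),
                          make_annotation(genes, ex1))
  expect_equal(rev$diff, -gm1$diff)
  expect_equal(rev$p, gm1$p)
})

test_that("DMG membership counts DEGs per context", {
  gm <- data.table::data.table(
    gene_id = c("g1", "g1", "g2", "g3"),
    context = c("CG", "CHH", "CHH", "CG"),
    feature = "all", n_sites = 5L,
    ratio_c = 0.2, ratio_t = 0.4, total_c = 50L, total_t = 50L,
    diff = 0.2, p = c(0.01, 0.2, 0.03, 0.5), q = 0.1)
  degs <- data.table::data.table(gene_id = c("g1", "g2", "g4"),
                                 status = c("up", "down", "up"))
  expect_warning(dmgs <- call_dmgs(gm, degs), "no covered cytosines")
  # g1 is a DMG in CG only; g2 in CHH only; g4 uncovered -> none
  fl <- dmgs$flags
  expect_true(fl[fl$gene_id == "g1" & fl$context == "CG", ]$is_dmg)
  expect_false(fl[fl$gene_id == "g1" & fl$context == "CHH", ]$is_dmg)
  expect_true(fl[fl$gene_id == "g2" & fl$context == "CHH", ]$is_dmg)
  expect_false(any(fl[fl$gene_id == "g4", ]$is_dmg))
  expect_equal(unname(dmgs$membership_pct["CG"]), 100 / 3)
  expect_equal(unname(dmgs$membership_pct["CHH"]), 100 / 3)

  pres <- suppressWarnings(call_dmgs(gm, degs, membership = "presence"))
  expect_equal(unname(pres$membership_pct["CHH"]), 200 / 3)
})

test_that("feature comparisons use a Welch test and degrade gracefully", {
  ann <- ann_two_genes()
  set.seed(41)
  n <- 60
  pos <- seq(5100, 8900, length.out = n)
  x <- data.table::data.table(
    chrom = "chr1", pos = as.integer(pos), context = "CG",
    ratio_c = runif(n, 0.3, 0.7), ratio_t = 0)
  x$ratio_t <- x$ratio_c                       # identical distributions
  res <- feature_condition_comparison(x, ann)
  expect_true(all(abs(res$mean_diff) < 1e-12))
  expect_true(all(res$p > 0.99))

  # planted promoter-only shift: promoter significant, exon/intron not
  x2 <- data.table::data.table(
    chrom = "chr1",
    pos = as.integer(c(seq(3100, 4900, 60), seq(5100, 8900, 60))),
    context = "CG")
  set.seed(42)
  x2$ratio_c <- runif(nrow(x2), 0.3, 0.5)
  x2$ratio_t <- x2$ratio_c +
    ifelse(x2$pos < 5000, 0.4, 0) + rnorm(nrow(x2), 0, 0.01)
  res2 <- feature_condition_comparison(x2, ann)
  expect_lt(res2[res2$feature == "promoter", ]$p, 0.001)
  expect_gt(min(res2[res2$feature != "promoter", ]$p), 0.05)

  # single observation per group: test absent
  one <- x[1]
  res3 <- feature_condition_comparison(one, ann)
  expect_true(is.na(res3$p))
})
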