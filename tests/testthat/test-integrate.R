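test_that("pseudocounts are a tenth of the smallest nonzero value", {
  expect_equal(expression_pseudocount(c(1.58882, 0, 7), c(3, 2)),
               0.158882)
  expect_equal(expression_pseudocount(10, 20), 1)
  expect_error(expression_pseudocount(c(0, 0), c(0, 0)), "all expression")

  expect_equal(methylation_pseudocount(c(2.75e-6, 0.5, 0)), 2.75e-7)
  expect_equal(methylation_pseudocount(0.5), 0.05)
  expect_error(methylation_pseudocount(c(0, 0)), "all methylation")
})

test_that("log2 fold change substitutes zeros only", {
  expect_equal(log2_fold_change(8, 2, 0.1), 2)
  expect_equal(log2_fold_change(0, 0, 0.1), 0)
  expect_equal(log2_fold_change(0.2, 0, 0.1), 1)  # pc*2 vs substituted pc
  # nonzero values are untouched by the pseudocount choice
  expect_equal(log2_fold_change(5, 3, 0.001), log2_fold_change(5, 3, 0.9))
  expect_error(log2_fold_change(1, 1, 0), "pseudocount")
})

test_that("DEG gates are inclusive and monotone", {
  e <- data.table::data.table(
    gene_id = c("g1", "g2", "g3", "g4"),
    fpkm_control = c(2, 1, 8, 4),
    fpkm_treated = c(4, 8, 1, 4.1),
    p_value = c(1e-4, 0.01, 1e-5, 1e-5),
    q_value = c(0.01, 0.01, 0.01, 0.01))
  d <- select_degs(e)
  # g1: log2fc exactly 1, gates pass -> up (boundary inclusive)
  expect_equal(d$status, c("up", "ns", "down", "ns"))
  expect_equal(attr(d, "n_up"), 1L)

  # relaxing any gate never shrinks the DEG set
  base <- sum(select_degs(e)$status != "ns")
  expect_gte(sum(select_degs(e, p_max = 0.05)$status != "ns"), base)
  expect_gte(sum(select_degs(e, fold = 1.01)$status != "ns"), base)
  expect_gte(sum(select_degs(e, fdr_max = 0.5)$status != "ns"), base)
})

test_that("planted up/down proportions are reported as percentages", {
  n_up <- 409; n_down <- 231
  e <- data.table::data.table(
    gene_id = sprintf("g%04d", seq_len(n_up + n_down)),
    fpkm_control = c(rep(1, n_up), rep(4, n_down)),
    fpkm_treated = c(rep(4, n_up), rep(1, n_down)),
    p_value = 1e-5, q_value = 1e-3)
  d <- select_degs(e)
  expect_equal(attr(d, "n_up") + attr(d, "n_down"), 640L)
  expect_equal(round(attr(d, "pct_up")), 64)
})

test_that("correlation equals a from-scratch covariance computation", {
  set.seed(71)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    gm <- data.table::data.table(
      gene_id = sprintf("g%03d", seq_len(n)), context = "CG",
      feature = "all", ratio_c = runif(n, 0.01, 0.99),
      ratio_t = runif(n, 0.01, 0.99))
    e <- data.table::data.table(
      gene_id = gm$gene_id, fpkm_control = rlnorm(n),
      fpkm_treated = rlnorm(n), p_value = 0.5, q_value = 0.5)
    got <- correlate_methylation_expression(gm, e, "control")
    x <- log2(gm$ratio_c); y <- log2(e$fpkm_control)
    want <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(got$r, want, tolerance = 1e-12)
    expect_equal(got$n, n)
  }
})

test_that("correlation handles exact relations and degenerate inputs", {
  n <- 20
  gm <- data.table::data.table(
    gene_id = sprintf("g%03d", 1:n), context = "CG", feature = "all",
    ratio_c = seq(0.1, 0.9, length.out = n),
    ratio_t = seq(0.1, 0.9, length.out = n))
  e <- data.table::data.table(
    gene_id = gm$gene_id,
    fpkm_control = 2^(3 * log2(gm$ratio_c) + 1),  # exactly log-linear
    fpkm_treated = 1, p_value = 0.5, q_value = 0.5)
  expect_equal(correlate_methylation_expression(gm, e, "control")$r, 1,
               tolerance = 1e-12)
  # treated axis has zero variance -> r absent
  expect_true(is.na(correlate_methylation_expression(gm, e,
                                                     "treated")$r))
  # fewer than 3 genes -> absent with n reported
  few <- correlate_methylation_expression(gm[1:2], e[1:2], "control")
  expect_true(is.na(few$r))
  expect_equal(few$n, 2L)
})

test_that("joint permutation preserves r; marginal permutation destroys it", {
  set.seed(72)
  n <- 200
  ratio <- runif(n, 0.05, 0.95)
  gm <- data.table::data.table(
    gene_id = sprintf("g%03d", 1:n), context = "CHH", feature = "promoter",
    ratio_c = ratio, ratio_t = ratio)
  e <- data.table::data.table(
    gene_id = gm$gene_id,
    fpkm_control = 2^(2 * log2(ratio) + rnorm(n, 0, 0.5)),
    fpkm_treated = 1, p_value = 0.5, q_value = 0.5)
  r0 <- correlate_methylation_expression(gm, e, "control")$r
  perm <- sample(n)
  # permuting rows of both tables jointly (ids travel along) changes nothing
  r1 <- correlate_methylation_expression(gm[perm], e[perm], "control")$r
  expect_equal(r1, r0, tolerance = 1e-12)
  # permuting one axis against the other collapses the correlation
  e2 <- data.table::copy(e)[, fpkm_control := fpkm_control[perm]]
  r2 <- correlate_methylation_expression(gm, e2, "control")$r
  expect_lt(abs(r2), abs(r0) / 2)
})

test_that("planted coupling is recovered with the planted sign", {
  cfg <- sim_config(seed = 81, n_chroms = 2, chrom_length = 1000000,
                    n_genes = 300, plastid_length = 5000,
                    coupling = data.frame(context = "CHH",
                                          feature = "promoter",
                                          strength = 0.5))
  ann <- simulate_annotation(cfg)
  lv <- simulate_gene_levels(ann, cfg)
  gm <- simulate_gene_methylation(lv, cfg)
  e <- simulate_expression(ann, cfg, levels = lv)
  got <- correlate_methylation_expression(
    gm[context == "CHH" & feature == "promoter"], e, "control")
  expect_gt(got$r, 0)
  expect_lt(got$p, 0.05)
  # uncoupled stratum stays near zero
  null <- correlate_methylation_expression(
    gm[context == "CG" & feature == "exon"], e, "control")
  expect_lt(abs(null$r), 3 / sqrt(null$n))
})
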