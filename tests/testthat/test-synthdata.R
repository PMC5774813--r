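test_that("the generator is deterministic given the seed", {
  cfg <- sim_config(seed = 101, n_chroms = 1, chrom_length = 60000,
                    n_genes = 8, plastid_length = 5000)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.data.frame(a$annotation$genes),
                   as.data.frame(b$annotation$genes))
  expect_identical(as.data.frame(a$control), as.data.frame(b$control))
  expect_identical(as.data.frame(a$treated), as.data.frame(b$treated))
  expect_identical(as.data.frame(a$expression),
                   as.data.frame(b$expression))

  # and written outputs are byte-identical
  d1 <- tempfile(); d2 <- tempfile()
  simulate_dataset(cfg, dir = d1)
  simulate_dataset(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("annotation boundaries: empty, all-pseudogene, too-small genome", {
  cfg0 <- sim_config(seed = 102, n_genes = 0, n_chroms = 2,
                     chrom_length = 10000, plastid_length = 2000)
  ann0 <- simulate_annotation(cfg0)
  expect_equal(nrow(ann0$genes), 0L)
  expect_equal(nrow(ann0$contigs), 3L)      # contigs still emitted
  expect_true(any(ann0$contigs$is_plastid))

  cfg1 <- sim_config(seed = 103, n_genes = 10, n_chroms = 1,
                     chrom_length = 80000, pseudogene_fraction = 1,
                     plastid_length = 2000)
  ann1 <- simulate_annotation(cfg1)
  expect_true(all(ann1$genes$biotype == "pseudogene"))

  cfg2 <- sim_config(seed = 104, n_genes = 50, n_chroms = 1,
                     chrom_length = 20000, plastid_length = 2000)
  expect_error(simulate_annotation(cfg2), "too short")
})

test_that("simulated gene models are well-formed", {
  sim <- shared_sim()
  ann <- sim$annotation
  # non-overlapping genes per chromosome
  g <- ann$genes[order(ann$genes$chrom, ann$genes$start), ]
  by_chr <- split(g, g$chrom)
  for (gg in by_chr) {
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
  }
  # exons partition into the gene span's ends
  ex <- ann$exons[order(ann$exons$gene_id, ann$exons$start), ]
  first_last <- do.call(rbind, lapply(split(ex, ex$gene_id), function(e) {
    data.frame(gene_id = e$gene_id[1], lo = min(e$start), hi = max(e$end))
  }))
  m <- merge(first_last, g, by = "gene_id")
  expect_equal(m$lo, m$start)
  expect_equal(m$hi, m$end)
})

test_that("counts are consistent and ratios recompute into [0, 1]", {
  sim <- shared_sim()
  for (tbl in list(sim$control, sim$treated)) {
    expect_true(all(tbl$n_meth >= 0 & tbl$n_unmeth >= 0))
    covered <- tbl[tbl$n_meth + tbl$n_unmeth > 0, ]
    r <- covered$n_meth / (covered$n_meth + covered$n_unmeth)
    expect_true(all(r >= 0 & r <= 1))
    expect_true(all(tbl$context %in% c("CG", "CHG", "CHH")))
    expect_true(all(substr(tbl$trinucleotide, 1, 1) == "C"))
  }
  # control and treated describe the same cytosines
  expect_identical(sim$control[, c("chrom", "pos", "strand", "context")],
                   sim$treated[, c("chrom", "pos", "strand", "context")])
})

test_that("a planted shift moves the mean ratio difference by its effect", {
  cfg <- sim_config(
    seed = 105, n_chroms = 1, chrom_length = 120000, n_genes = 0,
    plastid_length = 2000,
    planted_dmrs = data.frame(context = "CHH", direction = "hyper",
                              effect = 0.5, length = 2000, count = 10))
  sim <- simulate_dataset(cfg)
  pairs <- pair_sites(sim$control, sim$treated)
  iv <- sim$truth$dmr_intervals
  inside <- rep(FALSE, nrow(pairs))
  for (i in seq_len(nrow(iv))) {
    inside <- inside | (pairs$chrom == iv$chrom[i] &
                          pairs$pos >= iv$start[i] &
                          pairs$pos < iv$end[i])
  }
  planted <- pairs[inside & pairs$context == "CHH", ]
  expect_gt(nrow(planted), 1000)
  expect_equal(mean(planted$diff), 0.5, tolerance = 0.02)
  # outside the plants the difference is centred on zero
  outside <- pairs[!inside, ]
  expect_lt(abs(mean(outside$diff)), 0.005)
})

test_that("a null simulation has no systematic ratio difference", {
  sim <- shared_sim()
  pairs <- pair_sites(sim$control, sim$treated)
  for (ctx in c("CG", "CHG", "CHH")) {
    d <- pairs$diff[pairs$context == ctx]
    expect_lt(abs(mean(d)), 3 * stats::sd(d) / sqrt(length(d)) + 0.002)
  }
})

test_that("expression dropouts and couplings behave as configured", {
  cfg <- sim_config(seed = 106, n_chroms = 4, chrom_length = 1500000,
                    n_genes = 1000, plastid_length = 2000,
                    zero_fpkm_fraction = 0.1)
  ann <- simulate_annotation(cfg)
  e <- simulate_expression(ann, cfg)
  n0 <- sum(e$fpkm_control == 0 | e$fpkm_treated == 0)
  expect_equal(n0, 100)
  expect_true(all(e$fpkm_control >= 0 & e$fpkm_treated >= 0))
  # planted DE genes carry gate-passing p and q
  planted <- attr(e, "planted")
  expect_true(all(e$p_value[planted$is_de] <= 0.001))
  expect_true(all(e$q_value[planted$is_de] <= 0.05))

  # with no coupling the methylation-expression correlation is null
  lv <- simulate_gene_levels(ann, cfg)
  gm <- simulate_gene_methylation(lv, cfg)
  got <- correlate_methylation_expression(
    gm[context == "CHH" & feature == "promoter"], e, "control")
  expect_lt(abs(got$r), 3 / sqrt(got$n))
})
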