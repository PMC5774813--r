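test_that("expression grouping is quantile-based and deterministic", {
  e <- data.table::data.table(
    gene_id = sprintf("g%02d", 1:10),
    fpkm_control = c(100, 90, 50, 40, 20, 15, 8, 2, 0, 0),
    fpkm_treated = 1, p_value = 0.5, q_value = 0.5)
  g <- expression_groups(e, "control")
  expect_equal(as.character(g$group),
               c("first_high", "first_high", "second_high", "second_high",
                 "medium", "medium", "low", "low",
                 "no_expression", "no_expression"))

  # permutation of the input permutes, not changes, the grouping
  perm <- sample(10)
  g2 <- expression_groups(e[perm], "control")
  expect_equal(g2[order(g2$gene_id), ]$group,
               g[order(g$gene_id), ]$group)

  all0 <- data.table::copy(e)[, fpkm_control := 0]
  expect_true(all(expression_groups(all0, "control")$group ==
                    "no_expression"))
  expect_error(expression_groups(e[1:3], "control"), "at least 4")
})

test_that("a flat methylome gives a flat profile at the site ratio", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 3000L, end = 6000L,
                      biotype = "protein_coding")
  exons <- data.frame(gene_id = "g1", start = 3000L, end = 6000L)
  ann <- make_annotation(genes, exons, chrom_len = 9000L)
  pos <- seq(0, 8999, 3)
  ctl <- make_sites("chr1", pos, 5, 5)
  trt <- make_sites("chr1", pos, 5, 5)
  pairs <- pair_sites(ctl, trt)
  prof <- metagene_profile(pairs, ann, "control")
  vals <- prof$value[prof$context == "CG"]
  expect_true(all(!is.na(vals)))
  expect_true(all(abs(vals - 0.5) < 1e-12))
  expect_equal(nrow(prof), 120L)   # 30 + 60 + 30 bins
})

test_that("site-weighted bin means conserve the global mean ratio", {
  # one gene whose extended interval covers the whole chromosome, so
  # every paired site contributes exactly once
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "-",
                      start = 3000L, end = 6000L,
                      biotype = "protein_coding")
  exons <- data.frame(gene_id = "g1", start = 3000L, end = 6000L)
  ann <- make_annotation(genes, exons, chrom_len = 9000L)
  set.seed(51)
  pos <- sort(sample(0:8999, 2000))
  cov <- rpois(length(pos), 17) + 5L
  m <- rbinom(length(pos), cov, runif(length(pos)))
  ctl <- make_sites("chr1", pos, m, cov - m)
  trt <- make_sites("chr1", pos, pmin(m + 1L, cov), pmax(cov - m - 1L, 0L))
  pairs <- pair_sites(ctl, trt)
  for (cond in c("control", "treated")) {
    prof <- metagene_profile(pairs, ann, cond)
    d <- prof[!is.na(prof$value), ]
    got <- sum(d$value * d$n_sites) / sum(d$n_sites)
    want <- if (cond == "control") mean(pairs$ratio_c)
            else mean(pairs$ratio_t)
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(sum(d$n_sites), nrow(pairs))
  }
})

test_that("minus-strand genes mirror plus-strand profiles exactly", {
  L <- 12000L
  pos <- seq(100, 11900, 40)
  ratios <- round(seq(0.1, 0.9, length.out = length(pos)), 3)
  cov <- 20L
  m <- as.integer(round(ratios * cov))
  plus_genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                           start = 4000L, end = 8000L,
                           biotype = "protein_coding")
  plus_ex <- data.frame(gene_id = "g1", start = 4000L, end = 8000L)
  minus_genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "-",
                            start = L - 8000L, end = L - 4000L,
                            biotype = "protein_coding")
  minus_ex <- data.frame(gene_id = "g1", start = L - 8000L,
                         end = L - 4000L)
  mk_pairs <- function(p, mm) {
    pair_sites(make_sites("chr1", p, mm, cov - mm),
               make_sites("chr1", p, mm, cov - mm))
  }
  prof_plus <- metagene_profile(mk_pairs(pos, m),
                                make_annotation(plus_genes, plus_ex,
                                                chrom_len = L), "control")
  prof_minus <- metagene_profile(mk_pairs(L - 1L - pos, m),
                                 make_annotation(minus_genes, minus_ex,
                                                 chrom_len = L), "control")
  expect_equal(as.data.frame(prof_minus), as.data.frame(prof_plus))
})

test_that("the pooled profile is the weighted blend of group profiles", {
  sim <- shared_sim()
  pairs <- pair_sites(sim$control, sim$treated)
  ann <- sim$annotation
  grp <- expression_groups(sim$expression, "control")
  whole <- metagene_profile(pairs, ann, "control")
  parts <- lapply(levels(grp$group), function(g) {
    ids <- grp$gene_id[grp$group == g]
    if (!length(ids)) return(NULL)
    as.data.frame(metagene_profile(pairs, ann, "control",
                                   gene_ids = ids))
  })
  parts <- data.table::rbindlist(parts)
  blend <- parts[, .(value = sum(value * n_sites, na.rm = TRUE) /
                       pmax(1L, sum(n_sites)),
                     n_sites = sum(n_sites)), by = .(context, bin)]
  w <- as.data.frame(whole)
  b <- as.data.frame(blend[order(context, bin)])
  keep <- w$n_sites > 0
  expect_equal(b$n_sites[keep], w$n_sites[keep])
  expect_equal(b$value[keep], w$value[keep], tolerance = 1e-12)
})

test_that("pseudogene bodies run hotter than protein-coding bodies", {
  cfg <- sim_config(seed = 61, n_chroms = 2, chrom_length = 80000,
                    n_genes = 24, pseudogene_fraction = 0.5,
                    plastid_length = 5000)
  sim <- simulate_dataset(cfg)
  pairs <- pair_sites(sim$control, sim$treated)
  ann <- sim$annotation
  pc <- metagene_profile(pairs, ann, "control",
                         gene_ids = ann$genes[biotype == "protein_coding",
                                              gene_id],
                         contexts = "CG")
  pg <- metagene_profile(pairs, ann, "control",
                         gene_ids = ann$genes[biotype == "pseudogene",
                                              gene_id],
                         contexts = "CG")
  body_mean <- function(p) {
    d <- as.data.frame(p)
    mean(d$value[d$region == "body"], na.rm = TRUE)
  }
  expect_gt(body_mean(pg), body_mean(pc) + 0.1)
})

test_that("promoter profiles handle empty gene sets without crashing", {
  sim <- shared_sim()
  pairs <- pair_sites(sim$control, sim$treated)
  prof <- promoter_profile(pairs, sim$annotation, "control",
                           gene_ids = character(0))
  expect_s3_class(prof, "metagene_profile")
  expect_true(all(prof$n_sites == 0L))
  expect_true(all(is.na(prof$value)))

  full <- promoter_profile(pairs, sim$annotation, "treated")
  expect_equal(nrow(as.data.frame(full)), 3L * (20L + 40L + 20L))
})
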