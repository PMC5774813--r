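#' Simulate a per-gene expression table
#'
#' Log-normal FPKM in both conditions (log2 location/scale from the
#' config), with three planted structures:
#' \itemize{
#'   \item methylation-expression coupling: for each configured
#'     (context, feature, strength) stratum, the standardized log2 of the
#'     gene's true methylation level enters the log2-FPKM with weight
#'     `strength`, the residual noise being shrunk so the population
#'     correlation between log methylation and log expression equals
#'     `strength` (attenuated only by measurement noise downstream);
#'   \item differential expression: a `de_fraction` of genes receives a
#'     log2 fold change of planted sign and magnitude, and p/q columns
#'     consistent with it (planted genes get p <= 0.001; q is BH over
#'     the p column);
#'   \item dropouts: a `zero_fpkm_fraction` of genes is set to exactly 0
#'     FPKM in one or both conditions.
#' }
#'
#' @param annotation A [gene_annotation()].
#' @param config The matching [sim_config()].
#' @param levels Optional [simulate_gene_levels()] result (computed if
#'   NULL).
#' @return data.table `gene_id`, `fpkm_control`, `fpkm_treated`,
#'   `p_value`, `q_value`; attribute `planted` records per-gene planted
#'   log2 fold change and DE flag.
#' @export
simulate_expression <- function(annotation, config, levels = NULL) {
  stopifnot(inherits(annotation, "gene_annotation"),
            inherits(config, "sim_config"))
  if (is.null(levels)) levels <- simulate_gene_levels(annotation, config)
  set.seed(config$seed + 4L)
  g <- annotation$genes
  n <- nrow(g)
  if (n == 0L) {
    out <- data.table(gene_id = character(), fpkm_control = numeric(),
                      fpkm_treated = numeric(), p_value = numeric(),
                      q_value = numeric())
    return(structure(out, planted = data.table(
      gene_id = character(), planted_lfc = numeric(),
      is_de = logical())))
  }
  eps <- stats::rnorm(n)
  shift <- rep(0, n)
  rho2 <- 0
  if (!is.null(config$coupling) && nrow(config$coupling)) {
    lv <- as.data.table(levels)
    for (r in seq_len(nrow(config$coupling))) {
      row <- config$coupling[r]
      lr <- lv[context == row$context & feature == row$feature]
      z <- log2(lr$true_level[match(g$gene_id, lr$gene_id)])
      z <- as.numeric(scale(z))
      z[is.na(z)] <- 0
      shift <- shift + row$strength * z
    }
    rho2 <- sum(config$coupling$strength^2)
  }
  log2c <- config$expr_log2_mean +
    config$expr_log2_sd * (shift + sqrt(1 - rho2) * eps)

  n_de <- round(config$de_fraction * n)
  lfc <- rep(0, n)
  is_de <- rep(FALSE, n)
  if (n_de > 0) {
    de_idx <- sample.int(n, n_de)
    is_de[de_idx] <- TRUE
    n_up <- round(config$de_up_fraction * n_de)
    sgn <- rep(-1, n_de)
    if (n_up > 0) sgn[seq_len(n_up)] <- 1
    sgn <- sample(sgn)
    lfc[de_idx] <- sgn * stats::runif(n_de, config$de_lfc_range[1],
                                      config$de_lfc_range[2])
  }
  log2t <- log2c + lfc
  fpkm_c <- 2^log2c
  fpkm_t <- 2^log2t

  n_zero <- round(config$zero_fpkm_fraction * n)
  if (n_zero > 0) {
    zi <- sample.int(n, n_zero)
    pat <- sample(c("control", "treated", "both"), n_zero, replace = TRUE,
                  prob = c(0.4, 0.4, 0.2))
    fpkm_c[zi[pat != "treated"]] <- 0
    fpkm_t[zi[pat != "control"]] <- 0
  }

  p <- stats::runif(n, 0.0012, 1)
  if (n_de > 0) p[is_de] <- stats::runif(n_de, 1e-8, 0.001)
  q <- bh_adjust(p)

  out <- data.table(gene_id = g$gene_id, fpkm_control = fpkm_c,
                    fpkm_treated = fpkm_t, p_value = p, q_value = q)
  structure(out[], planted = data.table(gene_id = g$gene_id,
                                        planted_lfc = lfc, is_de = is_de))
}

#' Simulate a complete two-condition study
#'
#' Convenience wrapper running [simulate_annotation()],
#' [simulate_truth()], [simulate_gene_levels()], [simulate_methylome()]
#' and [simulate_expression()] in order, optionally writing everything
#' (GFF3 annotation, two cytosine reports, expression TSV and the truth
#' ledger) to a directory.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @return List: `annotation`, `truth`, `levels`, `control`, `treated`,
#'   `expression`, and `config`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ann <- simulate_annotation(config)
  truth <- simulate_truth(ann, config)
  levels <- simulate_gene_levels(ann, config)
  meth <- simulate_methylome(ann, config, truth = truth, levels = levels)
  expr <- simulate_expression(ann, config, levels = levels)
  out <- list(annotation = ann, truth = truth, levels = levels,
              control = meth$control, treated = meth$treated,
              expression = expr, config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_annotation(ann, file.path(dir, "annotation.gff3"))
    write_cx_report(meth$control, file.path(dir, "control.cx.tsv"))
    write_cx_report(meth$treated, file.path(dir, "treated.cx.tsv"))
    write_expression(expr, file.path(dir, "expression.tsv"))
    write_sim_truth(truth, dir)
  }
  out
}
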