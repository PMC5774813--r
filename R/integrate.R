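#' Expression pseudocount
#'
#' One-tenth of the smallest nonzero FPKM across both conditions: the
#' value substituted for exact zeros before log transformation so fold
#' changes stay finite.
#'
#' @param fpkm_control,fpkm_treated Non-negative FPKM vectors.
#' @return A single positive pseudocount.
#' @export
expression_pseudocount <- function(fpkm_control, fpkm_treated) {
  v <- c(fpkm_control, fpkm_treated)
  if (any(v < 0)) stop("expression_pseudocount: FPKM must be non-negative")
  nz <- v[v > 0]
  if (!length(nz)) {
    stop("expression_pseudocount: all expression values are zero")
  }
  min(nz) / 10
}

#' Methylation pseudocount
#'
#' One-tenth of the smallest nonzero methylation ratio across both
#' conditions, substituted for exact zeros before log transformation.
#'
#' @param ratios Non-negative methylation ratios (both conditions pooled).
#' @return A single positive pseudocount.
#' @export
methylation_pseudocount <- function(ratios) {
  if (any(ratios < 0)) {
    stop("methylation_pseudocount: ratios must be non-negative")
  }
  nz <- ratios[ratios > 0]
  if (!length(nz)) {
    stop("methylation_pseudocount: all methylation ratios are zero")
  }
  min(nz) / 10
}

# substitute a pseudocount for exact zeros only
sub_zero <- function(x, pseudocount) ifelse(x == 0, pseudocount, x)

#' Log2 expression fold change with pseudocounting
#'
#' `log2(treated / control)` after substituting `pseudocount` for any
#' exact-zero FPKM. Both-zero genes therefore have fold change 0.
#'
#' @param fpkm_treated,fpkm_control FPKM vectors.
#' @param pseudocount Positive value substituted for zeros.
#' @return Numeric log2 fold changes.
#' @export
log2_fold_change <- function(fpkm_treated, fpkm_control, pseudocount) {
  if (pseudocount <= 0) stop("log2_fold_change: pseudocount must be > 0")
  if (any(fpkm_treated < 0 | fpkm_control < 0)) {
    stop("log2_fold_change: FPKM must be non-negative")
  }
  log2(sub_zero(fpkm_treated, pseudocount) /
         sub_zero(fpkm_control, pseudocount))
}

#' Select differentially expressed genes (DEGs)
#'
#' Gates: at least `fold`-fold change (inclusive, i.e. `|log2fc| >= 1`
#' for the default fold of 2), `p <= p_max` and `q <= fdr_max`, using the
#' externally supplied differential-expression p/q columns. Relaxing any
#' gate can only grow the up/down sets.
#'
#' @param expr Expression table ([read_expression()] layout).
#' @param fold Minimum fold change (default 2).
#' @param p_max Maximum p-value (default 0.001).
#' @param fdr_max Maximum q-value (default 0.05).
#' @param pseudocount Expression pseudocount; computed from the table via
#'   [expression_pseudocount()] when NULL.
#' @return `expr` with added `log2fc` and `status` (`up`/`down`/`ns`)
#'   columns; attributes `n_up`, `n_down`, `pct_up`, `pct_down`,
#'   `pseudocount`.
#' @export
select_degs <- function(expr, fold = 2, p_max = 0.001, fdr_max = 0.05,
                        pseudocount = NULL) {
  e <- copy(as.data.table(expr))
  if (!all(c("p_value", "q_value") %in% names(e))) {
    stop("select_degs: expression table lacks p_value/q_value columns")
  }
  if (is.null(pseudocount)) {
    pseudocount <- expression_pseudocount(e$fpkm_control, e$fpkm_treated)
  }
  lfc_min <- log2(fold)
  e[, log2fc := log2_fold_change(fpkm_treated, fpkm_control, pseudocount)]
  e[, status := "ns"]
  e[log2fc >= lfc_min & p_value <= p_max & q_value <= fdr_max,
    status := "up"]
  e[log2fc <= -lfc_min & p_value <= p_max & q_value <= fdr_max,
    status := "down"]
  n_up <- sum(e$status == "up")
  n_down <- sum(e$status == "down")
  n_deg <- n_up + n_down
  structure(e[], n_up = n_up, n_down = n_down,
            pct_up = if (n_deg) 100 * n_up / n_deg else NA_real_,
            pct_down = if (n_deg) 100 * n_down / n_deg else NA_real_,
            pseudocount = pseudocount)
}

#' Pearson correlation between gene methylation and expression
#'
#' Sample Pearson correlation between `log2(methylation ratio)` and
#' `log2(FPKM)` across genes, for one condition, after substituting the
#' tenth-of-minimum pseudocounts for exact zeros on both axes. The
#' two-tailed p-value comes from the t transform with n - 2 degrees of
#' freedom ([stats::cor.test()]).
#'
#' @param gene_meth One stratum of [gene_methylation()] output (one
#'   context, one feature).
#' @param expr Expression table.
#' @param condition `"control"` or `"treated"`.
#' @param genes Optional gene subset (e.g. DMGs of the context).
#' @param meth_pseudocount,expr_pseudocount Pseudocounts; computed from
#'   the full tables via [methylation_pseudocount()] /
#'   [expression_pseudocount()] when NULL.
#' @return One-row data.table `context`, `feature`, `condition`, `r`,
#'   `p`, `n`. `r` is NA (with n reported) when fewer than 3 gene pairs
#'   exist or either axis has zero variance.
#' @export
correlate_methylation_expression <- function(gene_meth, expr,
                                             condition = c("control",
                                                           "treated"),
                                             genes = NULL,
                                             meth_pseudocount = NULL,
                                             expr_pseudocount = NULL) {
  condition <- match.arg(condition)
  gm <- as.data.table(gene_meth)
  e <- as.data.table(expr)
  ctx <- if (nrow(gm)) unique(gm$context) else NA_character_
  feat <- if (nrow(gm) && "feature" %in% names(gm)) unique(gm$feature)
          else "all"
  if (length(ctx) > 1L || length(feat) > 1L) {
    stop("correlate_methylation_expression: pass one (context, feature) ",
         "stratum at a time")
  }
  if (is.null(meth_pseudocount) && nrow(gm)) {
    meth_pseudocount <- methylation_pseudocount(c(gm$ratio_c, gm$ratio_t))
  }
  if (is.null(expr_pseudocount)) {
    expr_pseudocount <- expression_pseudocount(e$fpkm_control,
                                               e$fpkm_treated)
  }
  if (!is.null(genes)) gm <- gm[gene_id %in% genes]
  m <- merge(gm, e, by = "gene_id")
  out <- data.table(context = ctx, feature = feat, condition = condition,
                    r = NA_real_, p = NA_real_, n = nrow(m))
  if (nrow(m) < 3L) return(out[])
  meth <- if (condition == "control") m$ratio_c else m$ratio_t
  fpkm <- if (condition == "control") m$fpkm_control else m$fpkm_treated
  x <- log2(sub_zero(meth, meth_pseudocount))
  y <- log2(sub_zero(fpkm, expr_pseudocount))
  if (stats::var(x) == 0 || stats::var(y) == 0) return(out[])
  ct <- stats::cor.test(x, y, method = "pearson")
  out[, `:=`(r = unname(ct$estimate), p = ct$p.value)]
  out[]
}

#' Methylation-expression correlation table
#'
#' Builds the full correlation panel: for every context, feature
#' (promoter, exon, intron and the whole gene span "all") and condition,
#' the Pearson correlation between log2 gene methylation and log2
#' expression over the DMGs of that context (or over all DEGs with
#' `genes = "degs"`, or every annotated gene with `genes = "every"`).
#' Pseudocounts are computed once from the full tables.
#'
#' @param pairs Paired sites from [pair_sites()].
#' @param ann A [gene_annotation()].
#' @param expr Expression table.
#' @param dmgs Optional [call_dmgs()] result (required for
#'   `genes = "dmgs"`).
#' @param genes Gene universe per stratum: `"dmgs"` (default),
#'   `"degs"` or `"every"`.
#' @param degs [select_degs()] output (required for `genes = "degs"`).
#' @return data.table with one row per (context, feature, condition).
#' @export
correlation_table <- function(pairs, ann, expr, dmgs = NULL,
                              genes = c("dmgs", "degs", "every"),
                              degs = NULL) {
  genes <- match.arg(genes)
  if (genes == "dmgs" && is.null(dmgs)) {
    stop("correlation_table: genes = 'dmgs' needs a call_dmgs() result")
  }
  if (genes == "degs" && is.null(degs)) {
    stop("correlation_table: genes = 'degs' needs a select_degs() result")
  }
  features <- c("promoter", "exon", "intron", "all")
  gm_all <- lapply(stats::setNames(features, features), function(f) {
    gene_methylation(pairs, ann, feature = f)
  })
  meth_pc <- methylation_pseudocount(
    unlist(lapply(gm_all, function(g) c(g$ratio_c, g$ratio_t)))
  )
  expr_pc <- expression_pseudocount(expr$fpkm_control, expr$fpkm_treated)
  res <- list()
  contexts <- sort(unique(gm_all$all$context))
  for (ctx in contexts) {
    ids <- switch(genes,
      dmgs = dmgs$flags[context == ctx & is_dmg == TRUE, gene_id],
      degs = as.data.table(degs)[status %in% c("up", "down"), gene_id],
      every = NULL
    )
    for (f in features) {
      gm <- gm_all[[f]][context == ctx]
      for (cond in c("control", "treated")) {
        res[[paste(ctx, f, cond)]] <- correlate_methylation_expression(
          gm, expr, condition = cond, genes = ids,
          meth_pseudocount = meth_pc, expr_pseudocount = expr_pc
        )
      }
    }
  }
  data.table::rbindlist(res)
}
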