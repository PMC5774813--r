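#' Assign genomic positions to gene features
#'
#' Strand-aware classification of positions into `promoter`, `exon`,
#' `intron` or `intergenic`. Where features of different genes overlap,
#' priority is promoter > exon > intron; remaining ties are broken by the
#' lexicographically smaller `gene_id` so the assignment is deterministic.
#'
#' @param chrom,pos Position vectors (0-based).
#' @param ann A [gene_annotation()].
#' @param promoter_length Override of the annotation's promoter length.
#' @return data.table aligned with the input: `chrom`, `pos`, `feature`,
#'   `gene_id` (NA for intergenic).
#' @export
assign_feature <- function(chrom, pos, ann, promoter_length = NULL) {
  stopifnot(inherits(ann, "gene_annotation"))
  chrom <- rep_len(as.character(chrom), length(pos))
  feats <- feature_intervals(ann, promoter_length)
  pts <- data.table(xid = seq_along(pos), chrom = as.character(chrom),
                    start = as.integer(pos), end = as.integer(pos) + 1L)
  out <- data.table(chrom = pts$chrom, pos = as.integer(pos),
                    feature = "intergenic", gene_id = NA_character_)
  if (nrow(feats)) {
    data.table::setkey(feats, chrom, start, end)
    hits <- data.table::foverlaps(pts, feats, by.x = c("chrom", "start", "end"), type = "within",
                                  nomatch = NULL)
    if (nrow(hits)) {
      data.table::setorder(hits, xid, prio, gene_id)
      best <- hits[!duplicated(xid)]
      out[best$xid, `:=`(feature = best$feature, gene_id = best$gene_id)]
    }
  }
  out[]
}

# promoter/exon/intron intervals with priority ranks
feature_intervals <- function(ann, promoter_length = NULL) {
  pr <- promoters_of(ann, promoter_length)
  ex <- merge(ann$exons, ann$genes[, .(gene_id, chrom)], by = "gene_id")
  intr <- introns_of(ann)
  data.table::rbindlist(list(
    pr[end > start, .(gene_id, chrom, start, end, feature = "promoter",
                      prio = 1L)],
    ex[, .(gene_id, chrom, start, end, feature = "exon", prio = 2L)],
    intr[, .(gene_id, chrom, start, end, feature = "intron", prio = 3L)]
  ))
}

#' Gene-level differential methylation
#'
#' Per (gene, context): the unweighted mean of qualifying site ratios per
#' condition over the gene span (or over one feature of the gene), summed
#' read totals, the same ratio-reconstructed 2x2 Fisher test used at
#' region level ([fisher_window()]), and BH adjustment across genes within
#' each context. Coverage filtering (>= 5x in both conditions) is
#' inherited from [pair_sites()]. Genes with no qualifying site are
#' excluded and counted in a message.
#'
#' @param pairs Paired sites from [pair_sites()].
#' @param ann A [gene_annotation()].
#' @param feature `"all"` (whole gene span, the default), `"promoter"`,
#'   `"exon"` or `"intron"`.
#' @param promoter_length Override of the annotation's promoter length.
#' @param verbose Report the number of genes without covered sites.
#' @return data.table `gene_id`, `context`, `feature`, `n_sites`,
#'   `ratio_c`, `ratio_t`, `total_c`, `total_t`, `diff`, `p`, `q`.
#' @export
gene_methylation <- function(pairs, ann,
                             feature = c("all", "promoter", "exon",
                                         "intron"),
                             promoter_length = NULL, verbose = FALSE) {
  feature <- match.arg(feature)
  stopifnot(inherits(ann, "gene_annotation"))
  pr <- as.data.table(pairs)
  iv <- switch(feature,
    all = ann$genes[, .(gene_id, chrom, start, end)],
    promoter = promoters_of(ann, promoter_length)[, .(gene_id, chrom,
                                                      start, end)],
    exon = merge(ann$exons, ann$genes[, .(gene_id, chrom)],
                 by = "gene_id")[, .(gene_id, chrom, start, end)],
    intron = introns_of(ann)[, .(gene_id, chrom, start, end)]
  )
  empty <- data.table(gene_id = character(), context = character(),
                      feature = character(), n_sites = integer(),
                      ratio_c = numeric(), ratio_t = numeric(),
                      total_c = integer(), total_t = integer(),
                      diff = numeric(), p = numeric(), q = numeric())
  iv <- iv[end > start]
  if (!nrow(pr) || !nrow(iv)) return(empty)
  ps <- pr[, .(chrom, start = pos, end = pos + 1L, context,
               ratio_c, ratio_t, tc = m_c + u_c, tt = m_t + u_t)]
  data.table::setkey(iv, chrom, start, end)
  hits <- data.table::foverlaps(ps, iv, by.x = c("chrom", "start", "end"), type = "within", nomatch = NULL)
  if (!nrow(hits)) return(empty)
  agg <- hits[, .(
    n_sites = .N,
    ratio_c = mean(ratio_c), ratio_t = mean(ratio_t),
    total_c = sum(tc), total_t = sum(tt)
  ), by = .(gene_id, context)]
  if (verbose) {
    n_missing <- length(setdiff(ann$genes$gene_id, unique(agg$gene_id)))
    if (n_missing) {
      message("gene_methylation: ", n_missing,
              " gene(s) had no qualifying site in feature '", feature, "'")
    }
  }
  agg[, feature := feature]
  agg[, diff := ratio_t - ratio_c]
  agg[, p := fisher_window(ratio_c, total_c, ratio_t, total_t)]
  agg[, q := bh_adjust(p), by = context]
  data.table::setorder(agg, context, gene_id)
  agg[, .(gene_id, context, feature, n_sites, ratio_c, ratio_t, total_c,
          total_t, diff, p, q)]
}

#' Flag differentially methylated genes (DMGs) among DEGs
#'
#' A differentially expressed gene is a DMG in context X when its
#' gene-level differential-methylation test in X has `p <= p_thresh`.
#' Reports per-context DMG membership percentages among the DEG set. With
#' `membership = "presence"` a DEG instead counts as a member of context X
#' whenever it carries any covered site of that context (methylation
#' presence rather than differential significance).
#'
#' @param gene_meth Output of [gene_methylation()] (whole-gene span).
#' @param degs DEG-status table from [select_degs()] (needs `gene_id`,
#'   `status`).
#' @param p_thresh Gene-level p threshold (default 0.05).
#' @param membership `"significance"` (default) or `"presence"`.
#' @return Object of class `dmg_calls`: list with `flags` (data.table
#'   `gene_id` x `context` x `is_dmg`), `membership_pct` (named percent
#'   vector), `n_degs`.
#' @export
call_dmgs <- function(gene_meth, degs, p_thresh = 0.05,
                      membership = c("significance", "presence")) {
  membership <- match.arg(membership)
  gm <- as.data.table(gene_meth)
  dg <- as.data.table(degs)
  if (!all(c("gene_id", "status") %in% names(dg))) {
    stop("call_dmgs: degs needs columns gene_id, status")
  }
  deg_ids <- dg[status %in% c("up", "down"), gene_id]
  absent <- setdiff(deg_ids, unique(gm$gene_id))
  if (length(absent)) {
    warning("call_dmgs: ", length(absent),
            " DEG(s) have no covered cytosines / annotation entry ",
            "and are excluded from methylation flags")
  }
  contexts <- sort(unique(gm$context))
  flags <- data.table::CJ(gene_id = deg_ids, context = contexts,
                          unique = TRUE)
  gm_deg <- gm[gene_id %in% deg_ids]
  hit <- if (membership == "significance") {
    gm_deg[p <= p_thresh, .(gene_id, context)]
  } else {
    gm_deg[n_sites > 0, .(gene_id, context)]
  }
  hit[, is_dmg := TRUE]
  flags <- merge(flags, hit, by = c("gene_id", "context"), all.x = TRUE)
  flags[is.na(is_dmg), is_dmg := FALSE]
  pct <- flags[, .(pct = 100 * sum(is_dmg) / max(1L, length(deg_ids))),
               by = context]
  structure(
    list(flags = flags[], n_degs = length(deg_ids),
         membership_pct = stats::setNames(pct$pct, pct$context),
         p_thresh = p_thresh, membership = membership),
    class = "dmg_calls"
  )
}

#' @export
print.dmg_calls <- function(x, ...) {
  cat("DMG membership among", x$n_degs, "DEGs (", x$membership,
      ", p <=", x$p_thresh, "):\n")
  for (ctx in names(x$membership_pct)) {
    cat(sprintf("  %s: %.1f%%\n", ctx, x$membership_pct[[ctx]]))
  }
  invisible(x)
}

#' Compare methylation levels between conditions within features
#'
#' For each (feature, context) stratum: per-condition methylation-level
#' distributions, medians, and a two-tailed Welch two-sample t-test
#' comparing the control and treated level distributions. Regions (or
#' sites) are assigned to features by their midpoint. Strata with fewer
#' than two observations, or with zero variance in both groups, report an
#' absent test (NA).
#'
#' @param x Window calls ([call_dmrs()]) or paired sites
#'   ([pair_sites()]); needs `chrom`, `context`, `ratio_c`, `ratio_t` and
#'   either `start`/`end` or `pos`.
#' @param ann A [gene_annotation()].
#' @param promoter_length Override of the annotation's promoter length.
#' @return data.table `feature`, `context`, `n`, `median_c`, `median_t`,
#'   `mean_diff`, `t`, `p`.
#' @export
feature_condition_comparison <- function(x, ann, promoter_length = NULL) {
  d <- as.data.table(x)
  pos <- if ("pos" %in% names(d)) d$pos
         else as.integer(floor((d$start + d$end - 1L) / 2))
  fa <- assign_feature(d$chrom, pos, ann, promoter_length)
  d <- cbind(d[, .(context, ratio_c, ratio_t)],
             fa[, .(feature)])
  d <- d[feature != "intergenic"]
  if (!nrow(d)) {
    return(data.table(feature = character(), context = character(),
                      n = integer(), median_c = numeric(),
                      median_t = numeric(), mean_diff = numeric(),
                      t = numeric(), p = numeric()))
  }
  d[, {
    res <- if (.N >= 2L &&
               (stats::var(ratio_c) > 0 || stats::var(ratio_t) > 0)) {
      tt <- tryCatch(stats::t.test(ratio_t, ratio_c), error = function(e)
        NULL)
      if (is.null(tt)) list(NA_real_, NA_real_)
      else list(unname(tt$statistic), tt$p.value)
    } else {
      list(NA_real_, NA_real_)
    }
    list(n = .N,
         median_c = stats::median(ratio_c),
         median_t = stats::median(ratio_t),
         mean_diff = mean(ratio_t) - mean(ratio_c),
         t = res[[1]], p = res[[2]])
  }, by = .(feature, context)]
}
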