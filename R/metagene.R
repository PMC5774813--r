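#' Group genes by expression level
#'
#' Genes with FPKM exactly 0 in the profiled condition form the
#' `no_expression` group; the remaining genes are split into four
#' equal-size rank groups of that condition's FPKM, ordered high to low:
#' `first_high`, `second_high`, `medium`, `low`. Ties and input order are
#' resolved by `gene_id`, so the grouping is reproducible under
#' permutation of the input.
#'
#' @param expr Expression table ([read_expression()] layout).
#' @param condition `"control"` or `"treated"`: which FPKM column to
#'   group on.
#' @return data.table `gene_id`, `group` (factor, five levels).
#' @export
expression_groups <- function(expr, condition = c("control", "treated")) {
  condition <- match.arg(condition)
  e <- as.data.table(expr)
  fpkm <- e[[paste0("fpkm_", condition)]]
  lev <- c("first_high", "second_high", "medium", "low", "no_expression")
  out <- data.table(gene_id = e$gene_id,
                    group = factor(rep("no_expression", nrow(e)),
                                   levels = lev))
  expressed <- which(fpkm > 0)
  if (length(expressed)) {
    if (length(expressed) < 4L) {
      stop("expression_groups: need at least 4 expressed genes to form ",
           "quantile groups")
    }
    ord <- expressed[order(-fpkm[expressed], e$gene_id[expressed])]
    n <- length(ord)
    sizes <- diff(floor(n * 0:4 / 4))
    out$group[ord] <- factor(rep(lev[1:4], sizes), levels = lev)
  }
  out[]
}

# shared profiling engine: bins sites over oriented body intervals plus
# fixed-width flanks. body_iv: gene_id, chrom, strand, start, end.
profile_engine <- function(pairs, body_iv, flank_bp, flank_bins,
                           body_bins, condition, contexts = NULL) {
  stopifnot(flank_bins >= 1, body_bins >= 1)
  if (flank_bp %% flank_bins != 0) {
    stop("metagene: flank_bp must be divisible by flank_bins")
  }
  pr <- as.data.table(pairs)
  if (!is.null(contexts)) pr <- pr[context %in% contexts]
  ratio_col <- if (condition == "control") "ratio_c" else "ratio_t"
  n_bins <- 2L * flank_bins + body_bins
  grid <- data.table::CJ(context = sort(unique(pr$context)),
                         bin = seq_len(n_bins) - 1L)
  iv <- as.data.table(body_iv)[end > start]
  short <- iv[end - start < body_bins]
  if (nrow(short)) {
    message("metagene: ", nrow(short), " interval(s) shorter than ",
            body_bins, " bp profiled with fractional body rescaling")
  }
  empty <- {
    g <- copy(grid)
    g[, `:=`(condition = condition, value = NA_real_, n_sites = 0L)]
    label_bins(g, flank_bins, body_bins)
  }
  if (!nrow(pr) || !nrow(iv)) {
    return(structure(empty, class = c("metagene_profile", class(empty)),
                     n_genes = nrow(iv),
                     scheme = list(flank_bp = flank_bp,
                                   flank_bins = flank_bins,
                                   body_bins = body_bins)))
  }
  ext <- iv[, .(gene_id, strand, bstart = start, bend = end, chrom,
                start = start - flank_bp, end = end + flank_bp)]
  ps <- pr[, .(chrom, start = pos, end = pos + 1L, context,
               ratio = get(ratio_col))]
  data.table::setkey(ext, chrom, start, end)
  hits <- data.table::foverlaps(ps, ext, by.x = c("chrom", "start", "end"), type = "within", nomatch = NULL)
  if (nrow(hits)) {
    hits[, pos := i.start]
    bw <- flank_bp / flank_bins
    hits[, bin := {
      blen <- bend - bstart
      plus <- strand == "+"
      # oriented distance bookkeeping: bin 0 is the far 5' flank edge
      up <- ifelse(plus, pos < bstart, pos >= bend)
      down <- ifelse(plus, pos >= bend, pos < bstart)
      body <- !up & !down
      b <- integer(.N)
      b[up] <- ifelse(plus[up],
                      (pos[up] - (bstart[up] - flank_bp)) %/% bw,
                      (bend[up] + flank_bp - 1L - pos[up]) %/% bw)
      vfrac <- ifelse(plus, (pos - bstart) / blen,
                      (bend - 1L - pos) / blen)
      b[body] <- flank_bins + pmin(body_bins - 1L,
                                   floor(vfrac[body] * body_bins))
      b[down] <- flank_bins + body_bins +
        ifelse(plus[down], (pos[down] - bend[down]) %/% bw,
               (bstart[down] - 1L - pos[down]) %/% bw)
      as.integer(b)
    }]
    agg <- hits[, .(value = mean(ratio), n_sites = .N),
                by = .(context, bin)]
  } else {
    agg <- data.table(context = character(), bin = integer(),
                      value = numeric(), n_sites = integer())
  }
  out <- merge(grid, agg, by = c("context", "bin"), all.x = TRUE)
  out[is.na(n_sites), n_sites := 0L]
  out[, condition := condition]
  out <- label_bins(out, flank_bins, body_bins)
  structure(out, class = c("metagene_profile", class(out)),
            n_genes = nrow(iv),
            scheme = list(flank_bp = flank_bp, flank_bins = flank_bins,
                          body_bins = body_bins))
}

label_bins <- function(dt, flank_bins, body_bins) {
  dt[, region := ifelse(bin < flank_bins, "upstream",
                        ifelse(bin < flank_bins + body_bins, "body",
                               "downstream"))]
  data.table::setorder(dt, context, bin)
  dt[, .(context, condition, bin, region, value, n_sites)]
}

#' Metagene methylation profile
#'
#' Average methylation ratio in bins spanning the upstream flank, the
#' (length-normalized) gene body and the downstream flank, oriented 5' to
#' 3' (minus-strand genes are mirrored). Bin values are site-weighted
#' means: every qualifying (site, gene) pair counts once, so the
#' site-count-weighted mean over all bins equals the global mean ratio of
#' the profiled sites. Bins without any site report NA.
#'
#' @param pairs Paired sites from [pair_sites()] (already >= 5x in both
#'   conditions).
#' @param ann A [gene_annotation()].
#' @param condition `"control"` or `"treated"` (which ratio to profile).
#' @param gene_ids Optional gene subset (e.g. one expression group, or
#'   pseudogenes only).
#' @param contexts Optional context subset.
#' @param flank_bp Flank width in bp (default 3000).
#' @param flank_bins,body_bins Bin counts (defaults 30 and 60;
#'   `flank_bp` must be divisible by `flank_bins`).
#' @return A `metagene_profile` data.table: `context`, `condition`,
#'   `bin`, `region`, `value`, `n_sites`; attribute `n_genes`.
#' @export
metagene_profile <- function(pairs, ann,
                             condition = c("control", "treated"),
                             gene_ids = NULL, contexts = NULL,
                             flank_bp = 3000, flank_bins = 30,
                             body_bins = 60) {
  condition <- match.arg(condition)
  stopifnot(inherits(ann, "gene_annotation"))
  g <- ann$genes
  if (!is.null(gene_ids)) g <- g[gene_id %in% gene_ids]
  profile_engine(pairs, g[, .(gene_id, chrom, strand, start, end)],
                 flank_bp, flank_bins, body_bins, condition, contexts)
}

#' Promoter-centred methylation profile
#'
#' As [metagene_profile()] but with the promoter interval as the
#' normalized "body" and 1-kb flanks by default. Default bins are 20 per
#' flank (50-bp bins) and 40 over the promoter.
#'
#' @inheritParams metagene_profile
#' @param promoter_length Override of the annotation's promoter length.
#' @param flank_bp Flank width in bp (default 1000).
#' @param flank_bins,body_bins Bin counts (defaults 20 and 40).
#' @return A `metagene_profile` data.table.
#' @export
promoter_profile <- function(pairs, ann,
                             condition = c("control", "treated"),
                             gene_ids = NULL, contexts = NULL,
                             promoter_length = NULL, flank_bp = 1000,
                             flank_bins = 20, body_bins = 40) {
  condition <- match.arg(condition)
  stopifnot(inherits(ann, "gene_annotation"))
  pv <- promoters_of(ann, promoter_length)
  if (!is.null(gene_ids)) pv <- pv[gene_id %in% gene_ids]
  profile_engine(pairs, pv[, .(gene_id, chrom, strand, start, end)],
                 flank_bp, flank_bins, body_bins, condition, contexts)
}

#' Metagene profiles per expression group and gene class
#'
#' Convenience wrapper producing one [metagene_profile()] per expression
#' group ([expression_groups()]) and gene class (protein-coding vs
#' pseudogene), stacked in long format.
#'
#' @inheritParams metagene_profile
#' @param expr Expression table used to form the five expression groups
#'   (grouped on the profiled condition's FPKM).
#' @return Long data.table with added `group` and `gene_class` columns.
#' @export
metagene_by_group <- function(pairs, ann, expr,
                              condition = c("control", "treated"),
                              contexts = NULL, flank_bp = 3000,
                              flank_bins = 30, body_bins = 60) {
  condition <- match.arg(condition)
  grp <- expression_groups(expr, condition)
  res <- list()
  for (cls in c("protein_coding", "pseudogene")) {
    cls_ids <- ann$genes[biotype == cls, gene_id]
    if (!length(cls_ids)) next
    for (g in levels(grp$group)) {
      ids <- intersect(grp[group == g, gene_id], cls_ids)
      if (!length(ids)) next
      p <- metagene_profile(pairs, ann, condition, gene_ids = ids,
                            contexts = contexts, flank_bp = flank_bp,
                            flank_bins = flank_bins,
                            body_bins = body_bins)
      p <- as.data.table(p)
      p[, `:=`(group = g, gene_class = cls)]
      res[[paste(cls, g)]] <- p
    }
  }
  data.table::rbindlist(res)
}

#' @export
plot.metagene_profile <- function(x, ...) {
  d <- as.data.table(x)
  ctxs <- unique(d$context)
  cols <- stats::setNames(seq_along(ctxs) + 1L, ctxs)
  plot(NA, xlim = range(d$bin), ylim = c(0, max(d$value, na.rm = TRUE)),
       xlab = "bin (5' flank | body | 3' flank)",
       ylab = "methylation ratio", ...)
  for (ctx in ctxs) {
    with(d[context == ctx], lines(bin, value, col = cols[[ctx]]))
  }
  fb <- attr(x, "scheme")$flank_bins
  bb <- attr(x, "scheme")$body_bins
  graphics::abline(v = c(fb - 0.5, fb + bb - 0.5), lty = 2, col = "grey")
  graphics::legend("topright", legend = ctxs, col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}
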