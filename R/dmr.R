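#' Chromosomes eligible for region calling
#'
#' A chromosome is retained for a context when it carries at least one
#' site with Fisher `p < alpha` in that context -- the pre-filter applied
#' before windowing, so region tests are only spent on chromosomes with
#' any site-level signal.
#'
#' @param dms Site calls from [call_dms()].
#' @param alpha Site p-value threshold (default 0.05).
#' @return Named list, one character vector of chromosome names per
#'   context.
#' @export
select_chromosomes <- function(dms, alpha = 0.05) {
  dms <- as.data.table(dms)
  sel <- dms[p < alpha, .(chroms = list(sort(unique(chrom)))), by = context]
  out <- stats::setNames(sel$chroms, sel$context)
  for (ctx in setdiff(unique(dms$context), names(out))) {
    out[[ctx]] <- character(0)
  }
  if (!length(unlist(out))) {
    warning("select_chromosomes: no chromosome passed the p < ", alpha,
            " filter; region output will be empty")
  }
  out
}

#' Tile chromosomes into windows
#'
#' Windows `[k*step, k*step + window)` in 0-based half-open coordinates,
#' clipped at the chromosome end. With the default `step = window` this is
#' a disjoint tiling covering every base exactly once; smaller steps give
#' overlapping sliding windows.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param window Window size in bp (default 50).
#' @param step Step size in bp, `1 <= step <= window` (default `window`).
#' @return data.table `chrom`, `start`, `end`.
#' @export
tile_windows <- function(chrom_lengths, window = 50, step = window) {
  stopifnot(window >= 1, step >= 1, step <= window)
  if (is.null(names(chrom_lengths)) || !length(chrom_lengths)) {
    stop("tile_windows: chrom_lengths must be a named vector")
  }
  res <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    data.table(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + window, len)))
  })
  data.table::rbindlist(res)
}

#' Aggregate paired sites over windows
#'
#' Per (window, context): the *unweighted* mean of per-site methylation
#' ratios for each condition (every qualifying site counts equally,
#' regardless of its depth), summed read totals, and the site count.
#' Windows with fewer than `min_sites` qualifying sites are dropped.
#' Coverage filtering is inherited from [pair_sites()].
#'
#' @param pairs Paired sites from [pair_sites()].
#' @param windows Window table from [tile_windows()].
#' @param min_sites Minimum qualifying sites per window (default 1).
#' @return data.table `chrom`, `start`, `end`, `context`, `n_sites`,
#'   `ratio_c`, `ratio_t`, `total_c`, `total_t`, `diff`.
#' @export
window_methylation <- function(pairs, windows, min_sites = 1) {
  pr <- as.data.table(pairs)
  win <- as.data.table(windows)
  if (!nrow(pr) || !nrow(win)) return(empty_windows())
  ps <- pr[, .(chrom, start = pos, end = pos + 1L, context,
               ratio_c, ratio_t, tc = m_c + u_c, tt = m_t + u_t)]
  data.table::setkey(win, chrom, start, end)
  hits <- data.table::foverlaps(ps, win, by.x = c("chrom", "start", "end"), type = "within", nomatch = NULL)
  if (!nrow(hits)) return(empty_windows())
  agg <- hits[, .(
    n_sites = .N,
    ratio_c = mean(ratio_c), ratio_t = mean(ratio_t),
    total_c = sum(tc), total_t = sum(tt)
  ), by = .(chrom, start, end, context)]
  agg <- agg[n_sites >= min_sites]
  agg[, diff := ratio_t - ratio_c]
  data.table::setorder(agg, context, chrom, start)
  agg[]
}

empty_windows <- function() {
  data.table(chrom = character(), start = integer(), end = integer(),
             context = character(), n_sites = integer(),
             ratio_c = numeric(), ratio_t = numeric(),
             total_c = integer(), total_t = integer(), diff = numeric())
}

#' Fisher test on a region's reconstructed 2x2 table
#'
#' The region-level test reconstructs integer methylated counts from the
#' region-average ratio and the summed read total
#' (`meth = round(ratio * total)`, banker's half-to-even rounding, the R
#' default -- the reconstruction recipe fixes the arithmetic but some
#' rounding convention must be chosen and documented) and applies
#' [fisher_exact_2x2()] to
#' `[[meth_c, total_c - meth_c], [meth_t, total_t - meth_t]]`.
#'
#' @param ratio_c,ratio_t Region-average ratios per condition.
#' @param total_c,total_t Summed read counts per condition (must be > 0).
#' @return Two-tailed p-values (vectorized).
#' @export
fisher_window <- function(ratio_c, total_c, ratio_t, total_t) {
  if (any(total_c <= 0 | total_t <= 0)) {
    stop("fisher_window: zero read total; window has no defined test")
  }
  mc <- round(ratio_c * total_c)
  mt <- round(ratio_t * total_t)
  fisher_exact_2x2(mc, total_c - mc, mt, total_t - mt)
}

#' Call 50-bp differentially methylated regions (DMRs)
#'
#' Pipeline: optional chromosome pre-filter (any site with Fisher
#' `p < alpha` in the context), disjoint (or sliding) windows, unweighted
#' region-average ratios, the ratio-reconstructed 2x2 Fisher test, and BH
#' adjustment within each context. `direction` is `hyper` when the
#' treated-minus-control difference is positive.
#'
#' @param pairs Paired sites from [pair_sites()].
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window,step Window geometry in bp (defaults 50/50: disjoint
#'   tiling).
#' @param min_sites Minimum qualifying sites per window (default 1).
#' @param alpha Significance threshold on the region p-value
#'   (default 0.05).
#' @param chrom_filter Apply the chromosome pre-filter (default TRUE).
#' @param site_calls Optional precomputed [call_dms()] output reused for
#'   the pre-filter (avoids re-testing every site).
#' @return data.table of window calls with `p`, `q`, `direction`,
#'   `significant`.
#' @export
call_dmrs <- function(pairs, chrom_lengths, window = 50, step = window,
                      min_sites = 1, alpha = 0.05, chrom_filter = TRUE,
                      site_calls = NULL) {
  pr <- as.data.table(pairs)
  if (chrom_filter) {
    if (is.null(site_calls)) site_calls <- call_dms(pr, alpha = alpha)
    keep <- select_chromosomes(site_calls, alpha = alpha)
    pr <- data.table::rbindlist(lapply(names(keep), function(ctx) {
      pr[context == ctx & chrom %in% keep[[ctx]]]
    }))
  }
  win <- tile_windows(chrom_lengths, window = window, step = step)
  agg <- window_methylation(pr, win, min_sites = min_sites)
  if (!nrow(agg)) {
    out <- empty_windows()
    out[, `:=`(p = numeric(), q = numeric(), direction = character(),
               significant = logical())]
    return(out[])
  }
  agg[, p := fisher_window(ratio_c, total_c, ratio_t, total_t)]
  agg[, q := bh_adjust(p), by = context]
  agg[, direction := ifelse(diff > 0, "hyper", ifelse(diff < 0, "hypo",
                                                      "none"))]
  agg[, significant := p < alpha]
  agg[]
}

#' Per-context methylation-change summary from DMR counts
#'
#' The bookkeeping behind the net methylation-change statistic: per
#' context, `pct_change = (n_hyper - n_hypo) / (n_hyper + n_hypo) * 100`,
#' and the net change is the *sum* of the per-context percent changes.
#' Also reports the overall hyper/hypo split and the per-context
#' composition of significant regions.
#'
#' @param n_hyper,n_hypo Counts of significant hyper-/hypomethylated
#'   regions per context.
#' @param context Context labels (same length).
#' @return Object of class `context_summary`: a data.table (`context`,
#'   `n_hyper`, `n_hypo`, `n_total`, `pct_change`) with attributes
#'   `net_change`, `n_total_all`, `pct_hyper`, `pct_hypo` and
#'   `composition` (named percent vector).
#' @export
methylation_change_summary <- function(n_hyper, n_hypo, context) {
  stopifnot(length(n_hyper) == length(n_hypo),
            length(n_hyper) == length(context))
  if (any(n_hyper < 0 | n_hypo < 0)) {
    stop("methylation_change_summary: counts must be non-negative")
  }
  tab <- data.table(context = as.character(context),
                    n_hyper = as.numeric(n_hyper),
                    n_hypo = as.numeric(n_hypo))
  tab[, n_total := n_hyper + n_hypo]
  tab[, pct_change := ifelse(n_total > 0,
                             (n_hyper - n_hypo) / n_total * 100,
                             NA_real_)]
  total_all <- sum(tab$n_total)
  structure(
    tab[],
    class = c("context_summary", class(tab)),
    net_change = sum(tab$pct_change, na.rm = TRUE),
    n_total_all = total_all,
    pct_hyper = if (total_all > 0) sum(tab$n_hyper) / total_all * 100
                else NA_real_,
    pct_hypo = if (total_all > 0) sum(tab$n_hypo) / total_all * 100
               else NA_real_,
    composition = if (total_all > 0) {
      stats::setNames(tab$n_total / total_all * 100, tab$context)
    } else {
      stats::setNames(rep(NA_real_, nrow(tab)), tab$context)
    }
  )
}

#' Summarize DMR calls per context
#'
#' Partitions significant windows (`p < alpha` by default, matching how
#' region counts are usually tabulated; set `use_q` to gate on the BH
#' q-value instead) into hyper/hypo by the sign of the region difference
#' and delegates to [methylation_change_summary()].
#'
#' @param dmrs Window calls from [call_dmrs()].
#' @param alpha Significance threshold (default 0.05).
#' @param use_q Gate on `q <= alpha` instead of `p < alpha`.
#' @return A `context_summary` (see [methylation_change_summary()]).
#' @export
summarize_contexts <- function(dmrs, alpha = 0.05, use_q = FALSE) {
  d <- as.data.table(dmrs)
  sig <- if (use_q) d[q <= alpha] else d[p < alpha]
  counts <- sig[, .(n_hyper = sum(diff > 0), n_hypo = sum(diff < 0)),
                by = context]
  # keep every context present in the input, even if it has no calls
  all_ctx <- sort(unique(d$context))
  counts <- merge(data.table(context = all_ctx), counts, by = "context",
                  all.x = TRUE)
  counts[is.na(n_hyper), n_hyper := 0]
  counts[is.na(n_hypo), n_hypo := 0]
  methylation_change_summary(counts$n_hyper, counts$n_hypo, counts$context)
}

#' @export
print.context_summary <- function(x, ...) {
  cat("Significant DMRs by context:\n")
  print(as.data.table(x), ...)
  cat(sprintf("Total significant: %d | hyper %.2f%% / hypo %.2f%%\n",
              as.integer(attr(x, "n_total_all")), attr(x, "pct_hyper"),
              attr(x, "pct_hypo")))
  comp <- attr(x, "composition")
  cat("Composition:",
      paste(sprintf("%s %.2f%%", names(comp), comp), collapse = ", "), "\n")
  cat(sprintf("Net methylation change: %+.2f%%\n", attr(x, "net_change")))
  invisible(x)
}

#' Write DMR calls as BED6+ TSV
#'
#' Standard BED columns (chrom, start, end, name = `context:direction`,
#' score = `-log10 p`, strand = ".") followed by the ratio, difference and
#' q columns.
#'
#' @param dmrs Window calls from [call_dmrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmrs <- function(dmrs, path) {
  d <- as.data.table(dmrs)
  out <- d[, .(chrom, start, end,
               name = paste0(context, ":", direction),
               score = round(-log10(pmax(p, 1e-300)), 4),
               strand = ".",
               n_sites, ratio_c, ratio_t, diff, q, significant)]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
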