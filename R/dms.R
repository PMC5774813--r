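#' Methylation ratio of a cytosine
#'
#' Methylated read count divided by total read count. Errors on zero
#' coverage rather than returning NaN, because a ratio at an uncovered
#' site is undefined evidence, not zero methylation.
#'
#' @param n_meth,n_unmeth Non-negative counts (vectorized).
#' @return Proportions in \code{[0, 1]}.
#' @export
methylation_ratio <- function(n_meth, n_unmeth) {
  tot <- n_meth + n_unmeth
  if (any(n_meth < 0 | n_unmeth < 0)) {
    stop("methylation_ratio: counts must be non-negative")
  }
  if (any(tot == 0)) {
    stop("methylation_ratio: undefined at zero coverage")
  }
  n_meth / tot
}

#' Pair control and treated cytosine sites
#'
#' Joins two cytosine tables on (chrom, pos, strand), keeps only sites
#' covered by at least `min_cov` reads in *both* conditions (default 5,
#' the minimum-evidence rule applied throughout the pipeline), and
#' computes per-condition ratios and their difference
#' `diff = ratio_treated - ratio_control`. Strands are never pooled; a
#' cytosine on the minus strand is a distinct site.
#'
#' @param control,treated Site tables ([read_cx_report()] layout).
#' @param min_cov Minimum read coverage per condition (default 5).
#' @return data.table of paired sites: `chrom`, `pos`, `strand`,
#'   `context`, `m_c`, `u_c`, `m_t`, `u_t`, `ratio_c`, `ratio_t`, `diff`.
#' @export
pair_sites <- function(control, treated, min_cov = 5) {
  ctl <- as.data.table(control)
  trt <- as.data.table(treated)
  key <- c("chrom", "pos", "strand")
  for (nm in list(list("control", ctl), list("treated", trt))) {
    if (anyDuplicated(nm[[2]], by = key)) {
      d <- nm[[2]][duplicated(nm[[2]], by = key)][1L]
      stop("pair_sites: duplicate site in ", nm[[1]], " table at ",
           d$chrom, ":", d$pos, " (", d$strand, ")")
    }
  }
  m <- merge(
    ctl[, .(chrom, pos, strand, context, m_c = n_meth, u_c = n_unmeth)],
    trt[, .(chrom, pos, strand, m_t = n_meth, u_t = n_unmeth)],
    by = key
  )
  m <- m[m_c + u_c >= min_cov & m_t + u_t >= min_cov]
  m[, ratio_c := m_c / (m_c + u_c)]
  m[, ratio_t := m_t / (m_t + u_t)]
  m[, diff := ratio_t - ratio_c]
  data.table::setorder(m, chrom, pos, strand)
  m[]
}

#' Classify a methylation-ratio difference
#'
#' Five-way classification of `diff = ratio_treated - ratio_control`:
#' strongly hypermethylated for `diff >= 0.33`, hypermethylated for
#' `0 < diff < 0.33`, unchanged at exactly 0, and the mirrored hypo
#' categories for negative differences (boundary `+/-0.33` counted as
#' "strong" on both sides, a symmetric reading of the 33-percentage-point
#' rule).
#'
#' @param diff Numeric vector in \code{[-1, 1]}.
#' @param strong Magnitude threshold for the "strongly" classes
#'   (default 0.33).
#' @return Factor with levels `strongly_hypomethylated`,
#'   `hypomethylated`, `unchanged`, `hypermethylated`,
#'   `strongly_hypermethylated`.
#' @export
classify_dms <- function(diff, strong = 0.33) {
  if (any(abs(diff) > 1 + 1e-9, na.rm = TRUE)) {
    stop("classify_dms: ratio differences must lie in [-1, 1]")
  }
  lev <- c("strongly_hypomethylated", "hypomethylated", "unchanged",
           "hypermethylated", "strongly_hypermethylated")
  out <- rep("unchanged", length(diff))
  out[diff > 0 & diff < strong] <- "hypermethylated"
  out[diff >= strong] <- "strongly_hypermethylated"
  out[diff < 0 & diff > -strong] <- "hypomethylated"
  out[diff <= -strong] <- "strongly_hypomethylated"
  factor(out, levels = lev)
}

#' Call differentially methylated sites (DMSs)
#'
#' Per paired site, a two-tailed Fisher exact test on the 2x2 table
#' `[[m_c, u_c], [m_t, u_t]]`, Benjamini-Hochberg adjustment (by default
#' within each sequence context separately, since contexts are analyzed
#' and reported separately), and the `+/-33` percentage-point
#' classification. A site is significant iff `p < alpha` and `q <= fdr`.
#'
#' @param pairs Paired sites from [pair_sites()].
#' @param alpha Fisher p-value threshold (default 0.05).
#' @param fdr BH q-value threshold (default 0.05).
#' @param strong Threshold for strong classes (default 0.33).
#' @param per_context Adjust within contexts (default) or globally.
#' @return `pairs` with added columns `p`, `q`, `category`, `significant`.
#' @export
call_dms <- function(pairs, alpha = 0.05, fdr = 0.05, strong = 0.33,
                     per_context = TRUE) {
  if (!nrow(pairs)) stop("call_dms: no paired sites")
  out <- copy(as.data.table(pairs))
  out[, p := fisher_exact_2x2(m_c, u_c, m_t, u_t)]
  if (per_context) {
    out[, q := bh_adjust(p), by = context]
  } else {
    out[, q := bh_adjust(p)]
  }
  out[, category := classify_dms(diff, strong = strong)]
  out[, significant := p < alpha & q <= fdr]
  out[]
}

#' Write DMS calls to TSV
#'
#' Positions are written 1-based to match the cytosine-report convention.
#'
#' @param calls Output of [call_dms()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dms <- function(calls, path) {
  out <- copy(as.data.table(calls))
  out[, pos := pos + 1L]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
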