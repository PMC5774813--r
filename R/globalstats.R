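#' Bisulfite conversion rate from an unmethylated contig
#'
#' The plastid genome is methylation-free, so any methylated call there
#' is a conversion failure:
#' `rate = 100 * (1 - sum(n_meth) / sum(n_meth + n_unmeth))` over the
#' plastid sites.
#'
#' @param sites Cytosine table ([read_cx_report()] layout).
#' @param plastid Contig name(s) of the unmethylated genome (default
#'   `"plastid"`); ignored if `sites` is already plastid-only and carries
#'   no matching chromosome, in which case an error is raised.
#' @return Conversion rate in percent.
#' @export
conversion_rate <- function(sites, plastid = "plastid") {
  s <- as.data.table(sites)[chrom %in% plastid]
  if (!nrow(s)) {
    stop("conversion_rate: no sites on designated plastid contig(s): ",
         paste(plastid, collapse = ", "))
  }
  total <- sum(as.numeric(s$n_meth)) + sum(as.numeric(s$n_unmeth))
  if (total == 0) stop("conversion_rate: zero coverage on plastid contig")
  100 * (1 - sum(as.numeric(s$n_meth)) / total)
}

#' Global 5mdC percentage
#'
#' Percentage of covered cytosine bases read as methylated. Read-weighted
#' by default (`100 * sum(n_meth) / sum(n_meth + n_unmeth)`), which
#' approximates a per-molecule abundance; `weighted = FALSE` averages
#' per-site ratios instead. Plastid sites are excluded -- they estimate
#' conversion error, not biology.
#'
#' @param sites Cytosine table.
#' @param plastid Contig name(s) excluded from the summary.
#' @param weighted Read-weighted (default) or site-averaged.
#' @return Percentage in `[0, 100]`.
#' @export
global_5mdC <- function(sites, plastid = "plastid", weighted = TRUE) {
  s <- as.data.table(sites)[!chrom %in% plastid]
  if (!nrow(s)) stop("global_5mdC: no non-plastid sites")
  if (weighted) {
    total <- sum(as.numeric(s$n_meth)) + sum(as.numeric(s$n_unmeth))
    if (total == 0) stop("global_5mdC: zero total coverage")
    100 * sum(as.numeric(s$n_meth)) / total
  } else {
    s <- s[n_meth + n_unmeth > 0]
    if (!nrow(s)) stop("global_5mdC: zero total coverage")
    100 * mean(s$n_meth / (s$n_meth + s$n_unmeth))
  }
}

#' Percent change between two values
#'
#' `100 * (treated - control) / control`; the relative-increase statistic
#' used for global methylation comparisons.
#'
#' @param control,treated Numeric values; `control` must be positive.
#' @return Percent change (vectorized).
#' @export
percent_change <- function(control, treated) {
  if (any(control <= 0)) {
    stop("percent_change: control value must be positive")
  }
  100 * (treated - control) / control
}

#' Global methylation summary per condition
#'
#' @param sites Cytosine table for one condition.
#' @param condition Label stored in the output.
#' @param plastid Plastid contig name(s).
#' @return One-row data.table: `condition`, `pct_5mdC`,
#'   `conversion_rate` (NA when no plastid sites are present), `n_sites`,
#'   `n_reads_total`.
#' @export
global_summary <- function(sites, condition = "sample",
                           plastid = "plastid") {
  s <- as.data.table(sites)
  conv <- if (any(s$chrom %in% plastid)) conversion_rate(s, plastid)
          else NA_real_
  nonp <- s[!chrom %in% plastid]
  data.table(
    condition = condition,
    pct_5mdC = global_5mdC(s, plastid),
    conversion_rate = conv,
    n_sites = nrow(nonp),
    n_reads_total = sum(as.numeric(nonp$n_meth)) +
      sum(as.numeric(nonp$n_unmeth))
  )
}
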