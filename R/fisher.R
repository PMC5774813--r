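#' Two-tailed Fisher exact test for 2x2 count tables
#'
#' Computes the two-tailed Fisher exact p-value for one or more 2x2
#' tables \code{[[a, b], [c, d]]}. The two-tailed p is the sum of the
#' hypergeometric probabilities of every table with the same margins whose
#' probability does not exceed that of the observed table; ties are
#' resolved with a small relative tolerance so the set of included tables
#' does not depend on floating-point round-off.
#'
#' All four arguments are recycled to a common length, so a whole column
#' of tables can be tested in one call. Tables sharing margins are grouped
#' internally and share one probability-mass computation, which makes the
#' vectorized path fast enough for genome-scale site testing.
#'
#' @param a,b,c,d Non-negative integer counts; \code{a} and \code{b} form
#'   the first row (e.g. control methylated/unmethylated), \code{c} and
#'   \code{d} the second (treated).
#' @param tie_tol Relative tolerance used when comparing table
#'   probabilities to the observed one (default \code{1e-7}).
#' @return Numeric vector of p-values in \code{[0, 1]}. The all-zero
#'   table is defined to have p = 1.
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5)     # 1: no association
#' fisher_exact_2x2(10, 0, 0, 10)   # strong association
#' @export
fisher_exact_2x2 <- function(a, b, c, d, tie_tol = 1e-7) {
  n <- max(length(a), length(b), length(c), length(d))
  if (n == 0L) return(numeric(0))
  a <- rep_len(as.numeric(a), n)
  b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n)
  d <- rep_len(as.numeric(d), n)
  cnt <- cbind(a, b, c, d)
  if (anyNA(cnt) || any(!is.finite(cnt))) {
    stop("fisher_exact_2x2: counts must be finite and non-missing")
  }
  if (any(cnt < 0)) stop("fisher_exact_2x2: counts must be non-negative")
  if (any(abs(cnt - round(cnt)) > 1e-8)) {
    stop("fisher_exact_2x2: counts must be integers")
  }

  m1 <- a + b        # first row margin
  m2 <- c + d        # second row margin
  k  <- a + c        # first column margin
  out <- rep(1, n)
  todo <- which(m1 + m2 > 0)
  if (!length(todo)) return(out)

  dt <- data.table(i = todo, a = a[todo], m1 = m1[todo], m2 = m2[todo],
                   k = k[todo])
  res <- dt[, {
    lo <- max(0, k[1L] - m2[1L])
    hi <- min(k[1L], m1[1L])
    x <- lo:hi
    pmf <- stats::dhyper(x, m1[1L], m2[1L], k[1L])
    obs <- pmf[a - lo + 1]
    pv <- vapply(obs, function(o) sum(pmf[pmf <= o * (1 + tie_tol)]),
                 numeric(1))
    list(i = i, p = pv)
  }, by = .(m1, m2, k)]
  p <- pmin(res$p, 1)
  p[p > 1 - 1e-12] <- 1      # whole support included: exactly 1
  out[res$i] <- p
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard BH step-up false-discovery-rate adjustment, returned in input
#' order. Thin wrapper over [stats::p.adjust()] so downstream code has one
#' named entry point for the correction used throughout the pipeline.
#'
#' @param p Numeric vector of p-values in \code{[0, 1]}.
#' @return Adjusted q-values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
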