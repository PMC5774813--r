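#' Simulate a two-condition WGBS methylome
#'
#' Emits Bismark-style cytosine tables for a control and a treated
#' condition over every contig of the annotation, both strands. Cytosine
#' positions are sampled at `cytosine_density` per strand; contexts and
#' trinucleotides are sampled (strand-locally, mirroring the CX
#' convention) from `context_fractions`. Each site's true methylation
#' level is the context baseline, overridden inside promoters, exons and
#' introns by the gene's level from [simulate_gene_levels()]; plastid
#' sites are truly unmethylated. Planted intervals from
#' [simulate_truth()] shift the *treated* mean by their signed effect
#' (clipped to \[0, 1\]). Per condition, a beta-binomial draw
#' (concentration `overdispersion`; `Inf` = binomial) around the mean is
#' observed through Poisson(`coverage_mean`) reads per strand, with
#' unmethylated cytosines mis-read as methylated at rate
#' `conversion_failure`.
#'
#' @param annotation A [gene_annotation()] from [simulate_annotation()].
#' @param config The matching [sim_config()].
#' @param truth Optional [simulate_truth()] result (computed if NULL).
#' @param levels Optional [simulate_gene_levels()] result (computed if
#'   NULL).
#' @return List with elements `control` and `treated`, each a cytosine
#'   table in [read_cx_report()] layout (identical site coordinates).
#' @export
simulate_methylome <- function(annotation, config, truth = NULL,
                               levels = NULL) {
  stopifnot(inherits(annotation, "gene_annotation"),
            inherits(config, "sim_config"))
  if (is.null(truth)) truth <- simulate_truth(annotation, config)
  if (is.null(levels)) levels <- simulate_gene_levels(annotation, config)
  set.seed(config$seed + 3L)

  frac <- config$context_fractions[c("CG", "CHG", "CHH")]
  sites <- list()
  for (ci in seq_len(nrow(annotation$contigs))) {
    ch <- annotation$contigs$chrom[ci]
    len <- annotation$contigs$length[ci]
    for (st in c("+", "-")) {
      n <- stats::rbinom(1L, len, config$cytosine_density)
      if (n == 0L) next
      pos <- sort(sample.int(len, n)) - 1L
      ctx <- sample(names(frac), n, replace = TRUE, prob = frac)
      h1 <- sample(c("A", "C", "T"), n, replace = TRUE)
      h2 <- sample(c("A", "C", "T"), n, replace = TRUE)
      nt3 <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      tri <- ifelse(ctx == "CG", paste0("CG", nt3),
                    ifelse(ctx == "CHG", paste0("C", h1, "G"),
                           paste0("C", h1, h2)))
      sites[[paste(ch, st)]] <- data.table(
        chrom = ch, pos = pos, strand = st, context = ctx,
        trinucleotide = tri,
        is_plastid = annotation$contigs$is_plastid[ci]
      )
    }
  }
  s <- data.table::rbindlist(sites)
  data.table::setorder(s, chrom, pos, strand)

  # true mean level: context baseline, feature/gene override, plastid zero
  b <- config$baseline_methylation
  s[, mu := ifelse(context == "CG", b[["CG_upstream"]],
                   ifelse(context == "CHG", b[["CHG"]], b[["CHH"]]))]
  feats <- feature_intervals(annotation)
  if (nrow(feats)) {
    pts <- s[, .(xid = .I, chrom, start = pos, end = pos + 1L)]
    data.table::setkey(feats, chrom, start, end)
    hits <- data.table::foverlaps(pts, feats, by.x = c("chrom", "start", "end"), type = "within",
                                  nomatch = NULL)
    if (nrow(hits)) {
      data.table::setorder(hits, xid, prio, gene_id)
      hits <- hits[!duplicated(xid)]
      hits[, context := s$context[xid]]
      hits <- merge(hits, levels, by = c("gene_id", "context", "feature"),
                    sort = FALSE)
      s[hits$xid, mu := hits$true_level]
    }
  }
  s[is_plastid == TRUE, mu := 0]

  s[, mu_t := mu]
  if (nrow(truth$dmr_intervals)) {
    iv <- truth$dmr_intervals[, .(
      chrom, start, end, pctx = context, effect,
      sign_ = ifelse(direction == "hyper", 1, -1))]
    pts <- s[, .(xid = .I, chrom, start = pos, end = pos + 1L, context)]
    data.table::setkey(iv, chrom, start, end)
    hits <- data.table::foverlaps(pts, iv, by.x = c("chrom", "start", "end"), type = "within", nomatch = NULL)
    hits <- hits[context == pctx]
    hits <- hits[!duplicated(xid)]
    if (nrow(hits)) {
      s[hits$xid, mu_t := pmin(1, pmax(0, mu + hits$effect * hits$sign_))]
    }
  }

  draw <- function(mu_vec) {
    n <- length(mu_vec)
    conc <- config$overdispersion
    p <- if (is.infinite(conc)) {
      mu_vec
    } else {
      inner <- mu_vec > 0 & mu_vec < 1
      pv <- mu_vec
      pv[inner] <- stats::rbeta(sum(inner), mu_vec[inner] * conc,
                                (1 - mu_vec[inner]) * conc)
      pv
    }
    p_obs <- p + (1 - p) * config$conversion_failure
    cov <- stats::rpois(n, config$coverage_mean)
    m <- stats::rbinom(n, cov, p_obs)
    list(m = m, u = cov - m)
  }
  dc <- draw(s$mu)
  dt <- draw(s$mu_t)
  mk <- function(d) {
    data.table(chrom = s$chrom, pos = s$pos, strand = s$strand,
               n_meth = d$m, n_unmeth = d$u, context = s$context,
               trinucleotide = s$trinucleotide)
  }
  list(control = mk(dc), treated = mk(dt))
}
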