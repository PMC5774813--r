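# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the Fisher oracle enumerates hypergeometric
# tables from binomial coefficients, the BH oracle is the textbook step-up
# written directly.

# two-tailed Fisher p by exhaustive enumeration over fixed margins
fisher_oracle <- function(a, b, c, d, tol = 1e-7) {
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  pr <- choose(m, x) * choose(n, k - x) / choose(m + n, k)
  min(1, sum(pr[pr <= pr[a - lo + 1] * (1 + tol)]))
}

# textbook BH step-up, returned in input order
bh_oracle <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p)
  qs <- p[o] * m / seq_len(m)
  qs <- pmin(rev(cummin(rev(qs))), 1)
  out <- numeric(m)
  out[o] <- qs
  out
}

# hand-built cytosine table (1 row per site), 0-based positions
make_sites <- function(chrom, pos, n_meth, n_unmeth, strand = "+",
                       context = "CG", trinucleotide = "CGA") {
  data.table::data.table(
    chrom = chrom, pos = as.integer(pos), strand = strand,
    n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth),
    context = context, trinucleotide = trinucleotide
  )
}

# minimal annotation: one contig, explicit genes/exons
make_annotation <- function(genes, exons, chrom_len = 100000,
                            promoter_length = 2000,
                            extra_contigs = NULL) {
  contigs <- data.table::data.table(
    chrom = unique(c(genes$chrom, extra_contigs)),
    length = chrom_len, is_plastid = FALSE
  )
  gene_annotation(genes, exons, contigs,
                  promoter_length = promoter_length)
}

# small simulated study shared by several tests (computed once per run)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 20260901, n_chroms = 2,
                        chrom_length = 60000, n_genes = 20,
                        plastid_length = 20000)
      cache <<- simulate_dataset(cfg)
    }
    cache
  }
})
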