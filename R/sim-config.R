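#' Synthetic-study configuration
#'
#' All knobs of the synthetic WGBS + RNA-seq generator, with defaults
#' matching the emulated study design: ~17x Poisson coverage per DNA
#' strand, 99% bisulfite conversion, context baselines of ~50% mCG in
#' gene bodies / ~35% elsewhere, ~20% mCHG and ~3% mCHH, a cytosine
#' context composition of CG/CHG/CHH = 0.12/0.15/0.73 (the proportions of
#' the three site classes in the emulated genome), pseudogene bodies
#' elevated by +0.25 in the CG and CHG contexts, and moderate
#' beta-binomial overdispersion (concentration 50). Every random draw in
#' the generator flows from `seed`, so identical configurations give
#' byte-identical outputs.
#'
#' @param seed Integer seed (required).
#' @param n_chroms,chrom_length Number and size (bp) of nuclear
#'   chromosomes.
#' @param n_genes Total genes placed across chromosomes.
#' @param pseudogene_fraction Fraction of genes flagged pseudogene.
#' @param promoter_length Promoter size, bp upstream of the TSS.
#' @param gene_length_range Min/max simulated gene length (bp).
#' @param max_exons Maximum exons per gene.
#' @param baseline_methylation Named proportions: `CG_body`,
#'   `CG_upstream`, `CHG`, `CHH`.
#' @param pseudogene_boost Added to CG/CHG body baselines of pseudogenes
#'   (clipped to \[0, 1\]).
#' @param context_fractions Named sampling proportions of CG/CHG/CHH
#'   among simulated cytosines.
#' @param cytosine_density Probability that a strand position carries a
#'   cytosine (default 0.20, a plant-like per-strand C density).
#' @param coverage_mean Mean Poisson read coverage per strand.
#' @param conversion_failure Probability an unmethylated cytosine is read
#'   as methylated (1 - conversion rate).
#' @param overdispersion Beta-binomial concentration; `Inf` recovers pure
#'   binomial counts.
#' @param gene_level_concentration Beta concentration of between-gene
#'   variation in true feature methylation levels.
#' @param planted_dmrs NULL or data.frame with columns `context`,
#'   `direction` (`hyper`/`hypo`, defined treated minus control),
#'   `effect` in (0, 1\], `length` (bp), `count`.
#' @param coupling NULL or data.frame with columns `context`, `feature`
#'   (`promoter`/`exon`/`intron`) and signed `strength` in (-1, 1): the
#'   target correlation between log gene methylation and log expression.
#' @param plastid_length Length of the unmethylated plastid contig (bp).
#' @param expr_log2_mean,expr_log2_sd Log2-FPKM location/scale of the
#'   expression model.
#' @param zero_fpkm_fraction Fraction of genes zeroed in one or both
#'   conditions.
#' @param de_fraction Fraction of genes planted as differentially
#'   expressed.
#' @param de_up_fraction Fraction of planted DE genes that are
#'   up-regulated.
#' @param de_lfc_range Magnitude range of planted log2 fold changes.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chroms = 3,
                       chrom_length = 300000,
                       n_genes = 150,
                       pseudogene_fraction = 0.1,
                       promoter_length = 2000,
                       gene_length_range = c(1000, 4000),
                       max_exons = 5,
                       baseline_methylation = c(CG_body = 0.50,
                                                CG_upstream = 0.35,
                                                CHG = 0.20, CHH = 0.03),
                       pseudogene_boost = 0.25,
                       context_fractions = c(CG = 0.12, CHG = 0.15,
                                             CHH = 0.73),
                       cytosine_density = 0.20,
                       coverage_mean = 17,
                       conversion_failure = 0.01,
                       overdispersion = 50,
                       gene_level_concentration = 20,
                       planted_dmrs = NULL,
                       coupling = NULL,
                       plastid_length = 150000,
                       expr_log2_mean = 3,
                       expr_log2_sd = 2,
                       zero_fpkm_fraction = 0.05,
                       de_fraction = 0.10,
                       de_up_fraction = 0.64,
                       de_lfc_range = c(1, 4)) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("sim_config: a seed is required")
  }
  cfg <- list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes),
    pseudogene_fraction = pseudogene_fraction,
    promoter_length = promoter_length,
    gene_length_range = gene_length_range,
    max_exons = as.integer(max_exons),
    baseline_methylation = baseline_methylation,
    pseudogene_boost = pseudogene_boost,
    context_fractions = context_fractions,
    cytosine_density = cytosine_density,
    coverage_mean = coverage_mean,
    conversion_failure = conversion_failure,
    overdispersion = overdispersion,
    gene_level_concentration = gene_level_concentration,
    planted_dmrs = if (is.null(planted_dmrs)) NULL
                   else as.data.table(planted_dmrs),
    coupling = if (is.null(coupling)) NULL else as.data.table(coupling),
    plastid_length = as.integer(plastid_length),
    expr_log2_mean = expr_log2_mean, expr_log2_sd = expr_log2_sd,
    zero_fpkm_fraction = zero_fpkm_fraction,
    de_fraction = de_fraction, de_up_fraction = de_up_fraction,
    de_lfc_range = de_lfc_range
  )
  props <- c(cfg$pseudogene_fraction, cfg$baseline_methylation,
             cfg$cytosine_density, cfg$conversion_failure,
             cfg$zero_fpkm_fraction, cfg$de_fraction, cfg$de_up_fraction)
  if (any(props < 0 | props > 1)) {
    stop("sim_config: all proportions must lie in [0, 1]")
  }
  need_b <- c("CG_body", "CG_upstream", "CHG", "CHH")
  if (!all(need_b %in% names(cfg$baseline_methylation))) {
    stop("sim_config: baseline_methylation needs ",
         paste(need_b, collapse = ", "))
  }
  if (!all(c("CG", "CHG", "CHH") %in% names(cfg$context_fractions))) {
    stop("sim_config: context_fractions needs CG, CHG, CHH")
  }
  if (cfg$coverage_mean <= 0) stop("sim_config: coverage_mean must be > 0")
  if (!is.null(cfg$planted_dmrs)) {
    pd <- cfg$planted_dmrs
    need <- c("context", "direction", "effect", "length", "count")
    if (!all(need %in% names(pd))) {
      stop("sim_config: planted_dmrs needs columns ",
           paste(need, collapse = ", "))
    }
    if (any(!pd$direction %in% c("hyper", "hypo"))) {
      stop("sim_config: planted direction must be hyper or hypo")
    }
    if (any(pd$effect <= 0 | pd$effect > 1)) {
      stop("sim_config: planted effects must lie in (0, 1]")
    }
  }
  if (!is.null(cfg$coupling)) {
    cp <- cfg$coupling
    if (!all(c("context", "feature", "strength") %in% names(cp))) {
      stop("sim_config: coupling needs columns context, feature, strength")
    }
    if (sum(cp$strength^2) >= 1) {
      stop("sim_config: sum of squared coupling strengths must be < 1")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' The YAML keys mirror the [sim_config()] arguments; `planted_dmrs` and
#' `coupling` are lists of records. `seed` is required.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  for (nm in c("planted_dmrs", "coupling")) {
    if (!is.null(y[[nm]])) {
      y[[nm]] <- data.table::rbindlist(lapply(y[[nm]], as.data.table))
    }
  }
  for (nm in c("baseline_methylation", "context_fractions")) {
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  }
  do.call(sim_config, y)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_chroms, "chroms x",
      x$chrom_length, "bp |", x$n_genes, "genes | coverage",
      x$coverage_mean, "x/strand | conversion failure",
      x$conversion_failure, "\n")
  if (!is.null(x$planted_dmrs)) {
    cat("  planted DMRs:", sum(x$planted_dmrs$count), "\n")
  }
  if (!is.null(x$coupling)) {
    cat("  coupled strata:", nrow(x$coupling), "\n")
  }
  invisible(x)
}
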