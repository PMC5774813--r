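#' Simulate a gene annotation
#'
#' Places non-overlapping gene models (with 1 to `max_exons` exons and
#' derived introns) on `n_chroms` chromosomes, leaving at least a
#' promoter-plus-margin gap between genes so promoters never run into a
#' neighbouring gene. A gene-free `plastid` contig is always emitted for
#' conversion-rate estimation. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A [gene_annotation()].
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  contigs <- data.table(
    chrom = c(chroms, "plastid"),
    length = c(rep(config$chrom_length, config$n_chroms),
               config$plastid_length),
    is_plastid = c(rep(FALSE, config$n_chroms), TRUE)
  )
  if (config$n_genes == 0L) {
    return(gene_annotation(
      data.table(gene_id = character(), chrom = character(),
                 strand = character(), start = integer(), end = integer(),
                 biotype = character()),
      data.table(gene_id = character(), start = integer(),
                 end = integer()),
      contigs, promoter_length = config$promoter_length
    ))
  }
  per_chrom <- diff(floor(config$n_genes * (0:config$n_chroms) /
                            config$n_chroms))
  min_gap <- config$promoter_length + 200
  genes <- list()
  exons <- list()
  gi <- 0L
  for (ci in seq_len(config$n_chroms)) {
    g <- per_chrom[ci]
    if (g == 0L) next
    lens <- round(stats::runif(g, config$gene_length_range[1],
                               config$gene_length_range[2]))
    needed <- sum(lens) + (g + 1) * min_gap
    if (needed > config$chrom_length) {
      stop("simulate_annotation: chromosome ", chroms[ci], " too short ",
           "to place ", g, " genes with ", min_gap, " bp gaps: needs ",
           needed, " bp, has ", config$chrom_length)
    }
    slack <- config$chrom_length - needed
    w <- stats::runif(g + 1)
    extra <- floor(slack * w / sum(w))
    gaps <- min_gap + extra
    starts <- cumsum(gaps[seq_len(g)]) + cumsum(c(0, lens))[seq_len(g)]
    for (k in seq_len(g)) {
      gi <- gi + 1L
      id <- sprintf("gene%04d", gi)
      gstart <- as.integer(starts[k])
      gend <- as.integer(gstart + lens[k])
      genes[[gi]] <- data.table(
        gene_id = id, chrom = chroms[ci],
        strand = sample(c("+", "-"), 1L),
        start = gstart, end = gend, biotype = "protein_coding"
      )
      exons[[gi]] <- simulate_exons(id, gstart, gend, config$max_exons)
    }
  }
  genes <- data.table::rbindlist(genes)
  exons <- data.table::rbindlist(exons)
  n_pseudo <- round(config$pseudogene_fraction * nrow(genes))
  if (n_pseudo > 0) {
    genes[sample(.N, n_pseudo), biotype := "pseudogene"]
  }
  gene_annotation(genes, exons, contigs,
                  promoter_length = config$promoter_length)
}

# cut a gene span into alternating exon/intron segments (>= 50 bp each)
simulate_exons <- function(gene_id, gstart, gend, max_exons) {
  len <- gend - gstart
  k <- sample(seq_len(max_exons), 1L)
  while (k > 1L && len < (2L * k - 1L) * 50L) k <- k - 1L
  nseg <- 2L * k - 1L
  w <- stats::runif(nseg)
  extra <- floor((len - nseg * 50L) * w / sum(w))
  seg <- 50L + extra
  seg[nseg] <- seg[nseg] + (len - sum(seg))   # absorb rounding remainder
  bounds <- gstart + cumsum(c(0L, seg))
  idx <- seq(1L, nseg, by = 2L)               # odd segments are exons
  data.table(gene_id = gene_id,
             start = as.integer(bounds[idx]),
             end = as.integer(bounds[idx + 1L]))
}

#' Plant ground truth for a simulated study
#'
#' Places the configured differentially methylated intervals (aligned to
#' the 50-bp window grid, non-overlapping, on nuclear chromosomes only)
#' and records the coupled (gene, context, feature) strata. Direction is
#' defined treated minus control: `hyper` intervals gain methylation in
#' the treated condition.
#'
#' @param annotation A [gene_annotation()] from [simulate_annotation()].
#' @param config The matching [sim_config()].
#' @return Object of class `sim_truth`: list with `dmr_intervals`,
#'   `coupled_genes`, `conversion_failure`.
#' @export
simulate_truth <- function(annotation, config) {
  stopifnot(inherits(annotation, "gene_annotation"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  nuc <- annotation$contigs[is_plastid == FALSE]
  ivs <- data.table(chrom = character(), start = integer(),
                    end = integer(), context = character(),
                    direction = character(), effect = numeric())
  if (!is.null(config$planted_dmrs) && nrow(nuc)) {
    occupied <- stats::setNames(
      lapply(nuc$chrom, function(x) integer(0)), nuc$chrom)
    for (r in seq_len(nrow(config$planted_dmrs))) {
      row <- config$planted_dmrs[r]
      cells <- as.integer(ceiling(row$length / 50))
      for (i in seq_len(row$count)) {
        placed <- FALSE
        for (try in 1:200) {
          ch <- sample(nuc$chrom, 1L)
          n_cells <- nuc$length[nuc$chrom == ch] %/% 50L
          if (n_cells < cells) next
          c0 <- sample.int(n_cells - cells + 1L, 1L) - 1L
          want <- c0:(c0 + cells - 1L)
          if (any(want %in% occupied[[ch]])) next
          occupied[[ch]] <- c(occupied[[ch]], want)
          ivs <- rbind(ivs, data.table(
            chrom = ch, start = c0 * 50L,
            end = c0 * 50L + as.integer(row$length),
            context = row$context, direction = row$direction,
            effect = row$effect
          ))
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("simulate_truth: could not place planted DMR (genome too ",
               "crowded); reduce count/length or enlarge chromosomes")
        }
      }
    }
  }
  coupled <- data.table(gene_id = character(), context = character(),
                        feature = character(), strength = numeric())
  if (!is.null(config$coupling) && nrow(annotation$genes)) {
    coupled <- data.table::CJ(gene_id = annotation$genes$gene_id,
                              key_ = seq_len(nrow(config$coupling)))
    coupled <- cbind(coupled[, .(gene_id)],
                     config$coupling[coupled$key_,
                                     .(context, feature, strength)])
  }
  structure(list(dmr_intervals = ivs[], coupled_genes = coupled[],
                 conversion_failure = config$conversion_failure),
            class = "sim_truth")
}

#' Simulate per-gene true methylation levels
#'
#' Draws each gene's true methylation level per (context, feature) from a
#' Beta distribution centred on the context/feature baseline (promoter CG
#' uses the upstream baseline, exon/intron CG the gene-body baseline;
#' pseudogene exons/introns get the CG/CHG boost). These levels are the
#' between-gene variation that both the site-level methylome and the
#' methylation-expression coupling are built from, so the two stay
#' consistent.
#'
#' @param annotation A [gene_annotation()].
#' @param config The matching [sim_config()].
#' @return data.table `gene_id`, `context`, `feature`, `true_level`.
#' @export
simulate_gene_levels <- function(annotation, config) {
  stopifnot(inherits(annotation, "gene_annotation"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  g <- annotation$genes
  if (!nrow(g)) {
    return(data.table(gene_id = character(), context = character(),
                      feature = character(), true_level = numeric()))
  }
  grid <- data.table::CJ(gene_id = g$gene_id,
                         context = c("CG", "CHG", "CHH"),
                         feature = c("promoter", "exon", "intron"))
  grid[, biotype := g$biotype[match(gene_id, g$gene_id)]]
  b <- config$baseline_methylation
  grid[, base := ifelse(context == "CG",
                        ifelse(feature == "promoter", b[["CG_upstream"]],
                               b[["CG_body"]]),
                        ifelse(context == "CHG", b[["CHG"]], b[["CHH"]]))]
  grid[biotype == "pseudogene" & feature != "promoter" &
         context %in% c("CG", "CHG"),
       base := pmin(1, base + config$pseudogene_boost)]
  conc <- config$gene_level_concentration
  grid[, true_level := stats::rbeta(.N, base * conc, (1 - base) * conc)]
  grid[, true_level := pmin(pmax(true_level, 1e-4), 1 - 1e-4)]
  grid[, .(gene_id, context, feature, true_level)]
}

#' Simulated gene-level methylation measurements
#'
#' Fast aggregate path: observed per-gene methylation ratios for both
#' conditions, drawn binomially around each gene's true level at a depth
#' equivalent to `sites_per_feature` cytosines at the configured
#' coverage. Used for correlation-recovery studies where the full
#' site-level methylome is not needed.
#'
#' @param levels Output of [simulate_gene_levels()].
#' @param config The matching [sim_config()].
#' @param sites_per_feature Nominal cytosines per gene feature
#'   (default 20).
#' @return data.table in [gene_methylation()] layout (`gene_id`,
#'   `context`, `feature`, `ratio_c`, `ratio_t`, ...).
#' @export
simulate_gene_methylation <- function(levels, config,
                                      sites_per_feature = 20) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 5L)
  lv <- copy(as.data.table(levels))
  depth <- max(1L, round(config$coverage_mean * sites_per_feature))
  eps <- config$conversion_failure
  lv[, total_c := depth]
  lv[, total_t := depth]
  obs <- lv$true_level + (1 - lv$true_level) * eps
  lv[, ratio_c := stats::rbinom(.N, depth, obs) / depth]
  lv[, ratio_t := stats::rbinom(.N, depth, obs) / depth]
  lv[, n_sites := sites_per_feature]
  lv[, diff := ratio_t - ratio_c]
  lv[, .(gene_id, context, feature, n_sites, ratio_c, ratio_t,
         total_c, total_t, diff)]
}

#' Write simulation truth tables
#'
#' Plain-TSV ledger of the planted signal (interval coordinates written
#' 0-based half-open, as labelled), for parameter-recovery checks.
#'
#' @param truth A `sim_truth` from [simulate_truth()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(truth$dmr_intervals,
                     file.path(dir, "truth_dmr_intervals.tsv"), sep = "\t")
  data.table::fwrite(truth$coupled_genes,
                     file.path(dir, "truth_coupled_genes.tsv"), sep = "\t")
  data.table::fwrite(
    data.table(conversion_failure = truth$conversion_failure),
    file.path(dir, "truth_conversion.tsv"), sep = "\t")
  invisible(dir)
}
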