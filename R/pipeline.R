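#' Run the full analysis pipeline
#'
#' Orchestrates simulation (optional), site calls, region calls,
#' gene-level calls, metagene profiles, expression integration and global
#' summaries, writing one TSV per stage plus a JSON manifest into
#' `out_dir`. Identical configuration (including the seed) yields
#' byte-identical stage TSVs.
#'
#' The configuration is a named list, or a path to a YAML file with the
#' same structure:
#' \preformatted{
#' out_dir: results
#' stages: [dms, dmr, dmg, metagene, integrate, summarize]  # default all
#' simulate:            # either this block ...
#'   seed: 1
#'   n_genes: 100
#' paths:               # ... or explicit inputs
#'   control: control.cx.tsv
#'   treated: treated.cx.tsv
#'   annotation: annotation.gff3
#'   expression: expression.tsv
#' thresholds:
#'   min_cov: 5
#'   alpha: 0.05
#'   fdr: 0.05
#'   window: 50
#'   step: 50
#'   fold: 2
#'   deg_p: 0.001
#'   deg_fdr: 0.05
#'   dms_strong: 0.33
#'   promoter_length: 2000
#' plastid: plastid
#' }
#'
#' @param config Named list or YAML path (see above).
#' @return Invisibly, a list of in-memory stage results (also written to
#'   `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% "palmethyl_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- utils::modifyList(
    list(min_cov = 5, alpha = 0.05, fdr = 0.05, window = 50, step = 50,
         fold = 2, deg_p = 0.001, deg_fdr = 0.05, dms_strong = 0.33,
         promoter_length = 2000),
    config$thresholds %||% list()
  )
  stages <- config$stages %||% c("dms", "dmr", "dmg", "metagene",
                                 "integrate", "summarize")
  plastid <- config$plastid %||% "plastid"
  res <- list()

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(config$seed) && is.null(sim_args$seed)) {
      sim_args$seed <- config$seed
    }
    cfg <- do.call(sim_config, sim_args)
    message("[simulate] seed ", cfg$seed, ": generating synthetic study")
    sim <- simulate_dataset(cfg, dir = file.path(out_dir, "simulated"))
    ann <- sim$annotation
    control <- sim$control
    treated <- sim$treated
    expr <- sim$expression
    res$simulation <- sim
  } else {
    paths <- config$paths
    if (is.null(paths$control) || is.null(paths$treated)) {
      stop("run_pipeline: paths$control and paths$treated are required ",
           "when no 'simulate' block is given")
    }
    control <- read_cx_report(paths$control)
    treated <- read_cx_report(paths$treated)
    ann <- if (!is.null(paths$annotation)) {
      read_annotation(paths$annotation,
                      promoter_length = th$promoter_length,
                      plastid = plastid)
    } else NULL
    expr <- if (!is.null(paths$expression)) {
      read_expression(paths$expression)
    } else NULL
  }
  message("[input] sites: control ", nrow(control), ", treated ",
          nrow(treated))

  pairs <- pair_sites(control, treated, min_cov = th$min_cov)
  message("[pair] ", nrow(pairs), " sites covered >= ", th$min_cov,
          "x in both conditions")
  res$pairs <- pairs

  dms <- NULL
  if (any(c("dms", "dmr") %in% stages)) {
    dms <- call_dms(pairs, alpha = th$alpha, fdr = th$fdr,
                    strong = th$dms_strong)
    message("[dms] ", sum(dms$significant), " significant of ",
            nrow(dms), " tested sites")
    write_dms(dms, file.path(out_dir, "dms.tsv"))
    res$dms <- dms
  }

  if ("dmr" %in% stages) {
    lens <- stats::setNames(ann$contigs$length, ann$contigs$chrom)
    lens <- lens[!names(lens) %in% plastid]
    dmrs <- call_dmrs(pairs, lens, window = th$window, step = th$step,
                      alpha = th$alpha, site_calls = dms)
    message("[dmr] ", sum(dmrs$significant), " significant of ",
            nrow(dmrs), " tested windows")
    write_dmrs(dmrs, file.path(out_dir, "dmrs.tsv"))
    ctx_sum <- summarize_contexts(dmrs, alpha = th$alpha)
    sum_dt <- as.data.table(ctx_sum)
    sum_dt[, net_change := attr(ctx_sum, "net_change")]
    data.table::fwrite(sum_dt, file.path(out_dir, "context_summary.tsv"),
                       sep = "\t")
    res$dmrs <- dmrs
    res$context_summary <- ctx_sum
  }

  degs <- NULL
  if (any(c("dmg", "integrate", "metagene") %in% stages)) {
    if (is.null(expr)) {
      stop("run_pipeline: stages ",
           paste(intersect(stages, c("dmg", "integrate", "metagene")),
                 collapse = "/"),
           " need an expression table (paths$expression or simulate)")
    }
    if (is.null(ann)) {
      stop("run_pipeline: gene-level stages need an annotation")
    }
    degs <- select_degs(expr, fold = th$fold, p_max = th$deg_p,
                        fdr_max = th$deg_fdr)
    message("[deg] up ", attr(degs, "n_up"), ", down ",
            attr(degs, "n_down"))
    data.table::fwrite(degs, file.path(out_dir, "degs.tsv"), sep = "\t")
    res$degs <- degs
  }

  dmgs <- NULL
  if (any(c("dmg", "integrate") %in% stages)) {
    gm <- gene_methylation(pairs, ann, feature = "all", verbose = TRUE)
    data.table::fwrite(gm, file.path(out_dir, "gene_methylation.tsv"),
                       sep = "\t")
    dmgs <- call_dmgs(gm, degs, p_thresh = th$alpha)
    message("[dmg] membership: ",
            paste(sprintf("%s %.1f%%", names(dmgs$membership_pct),
                          dmgs$membership_pct), collapse = ", "))
    data.table::fwrite(dmgs$flags, file.path(out_dir, "dmg_flags.tsv"),
                       sep = "\t")
    res$gene_methylation <- gm
    res$dmgs <- dmgs
  }

  if ("metagene" %in% stages) {
    prof <- data.table::rbindlist(lapply(c("control", "treated"),
      function(cond) metagene_by_group(pairs, ann, expr, cond)))
    data.table::fwrite(prof, file.path(out_dir, "metagene.tsv"),
                       sep = "\t")
    message("[metagene] ", nrow(prof), " profile bins written")
    res$metagene <- prof
  }

  if ("integrate" %in% stages) {
    corr <- correlation_table(pairs, ann, expr, dmgs = dmgs)
    data.table::fwrite(corr, file.path(out_dir, "correlations.tsv"),
                       sep = "\t")
    message("[integrate] ", nrow(corr), " correlation strata")
    res$correlations <- corr
  }

  if ("summarize" %in% stages) {
    gs <- rbind(global_summary(control, "control", plastid),
                global_summary(treated, "treated", plastid))
    gs[, pct_change_vs_control :=
         percent_change(pct_5mdC[condition == "control"], pct_5mdC)]
    data.table::fwrite(gs, file.path(out_dir, "global_summary.tsv"),
                       sep = "\t")
    message("[summarize] global 5mdC: ",
            paste(sprintf("%s %.2f%%", gs$condition, gs$pct_5mdC),
                  collapse = ", "))
    res$global_summary <- gs
  }

  manifest <- list(
    package = "palmethyl",
    version = as.character(utils::packageVersion("palmethyl")),
    stages = stages,
    thresholds = th,
    seed = config$seed %||% config$simulate$seed,
    records = list(
      sites_control = nrow(control), sites_treated = nrow(treated),
      sites_paired = nrow(pairs),
      dms_tested = if (!is.null(dms)) nrow(dms) else NULL,
      dmrs_tested = if (!is.null(res$dmrs)) nrow(res$dmrs) else NULL
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
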