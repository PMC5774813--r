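#' Gene annotation container
#'
#' Bundles gene models, their exons and the contig table into a validated
#' object used by every feature-aware stage. Coordinates are 0-based
#' half-open throughout the package; GFF3 (1-based closed) is converted at
#' the I/O boundary.
#'
#' Introns are always derived as the gaps between consecutive exons, and
#' promoters as `promoter_length` bases immediately upstream of the TSS on
#' the strand-appropriate side, so neither can drift out of sync with the
#' exon structure.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `start`, `end` (0-based half-open), `biotype`
#'   (`protein_coding` or `pseudogene`).
#' @param exons data.frame with columns `gene_id`, `start`, `end`; must be
#'   disjoint within a gene and contained in the gene span.
#' @param contigs data.frame with columns `chrom`, `length` and logical
#'   `is_plastid` (the designated unmethylated contig used for
#'   conversion-rate estimation).
#' @param promoter_length Promoter size in bp upstream of the TSS
#'   (default 2000).
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, exons, contigs, promoter_length = 2000) {
  genes <- as.data.table(genes)
  exons <- as.data.table(exons)
  contigs <- as.data.table(contigs)
  need_g <- c("gene_id", "chrom", "strand", "start", "end", "biotype")
  if (length(setdiff(need_g, names(genes)))) {
    stop("gene_annotation: genes must have columns ",
         paste(need_g, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("gene_annotation: duplicate gene_id: ",
         genes$gene_id[duplicated(genes$gene_id)][1L])
  }
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("gene_annotation: unknown strand (must be '+' or '-')")
  }
  if (any(!genes$biotype %in% c("protein_coding", "pseudogene"))) {
    stop("gene_annotation: biotype must be protein_coding or pseudogene")
  }
  if (any(genes$start < 0) || any(genes$end <= genes$start)) {
    stop("gene_annotation: gene intervals must satisfy 0 <= start < end")
  }
  if (nrow(genes) && !all(genes$gene_id %in% exons$gene_id)) {
    stop("gene_annotation: every gene needs at least one exon")
  }
  if (nrow(exons)) {
    if (!all(exons$gene_id %in% genes$gene_id)) {
      stop("gene_annotation: exon references unknown gene")
    }
    ex <- merge(exons, genes[, .(gene_id, gstart = start, gend = end)],
                by = "gene_id")
    if (any(ex$start < ex$gstart | ex$end > ex$gend)) {
      bad <- ex[start < gstart | end > gend][1L]
      stop("gene_annotation: exon outside gene span for gene ", bad$gene_id)
    }
    data.table::setorder(exons, gene_id, start)
    ov <- exons[, any(start[-1L] < end[-.N]), by = gene_id][V1 == TRUE]
    if (nrow(ov)) {
      stop("gene_annotation: overlapping exons in gene ", ov$gene_id[1L])
    }
  }
  if (!all(c("chrom", "length") %in% names(contigs))) {
    stop("gene_annotation: contigs must have columns chrom, length")
  }
  if (!"is_plastid" %in% names(contigs)) contigs[, is_plastid := FALSE]
  if (nrow(genes) && !all(genes$chrom %in% contigs$chrom)) {
    stop("gene_annotation: gene on unknown contig")
  }
  structure(
    list(genes = genes[], exons = exons[], contigs = contigs[],
         promoter_length = as.numeric(promoter_length)),
    class = "gene_annotation"
  )
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes (",
      sum(x$genes$biotype == "pseudogene"), "pseudogenes ) on",
      nrow(x$contigs), "contigs;", nrow(x$exons), "exons; promoter",
      x$promoter_length, "bp\n")
  invisible(x)
}

#' Promoter intervals of an annotation
#'
#' Strand-aware: `promoter_length` bases upstream of the TSS, i.e.
#' `[start - L, start)` for plus-strand genes and `[end, end + L)` for
#' minus-strand genes, clipped to the contig.
#'
#' @param ann A [gene_annotation()].
#' @param promoter_length Override of the annotation's promoter length.
#' @return data.table `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @export
promoters_of <- function(ann, promoter_length = NULL) {
  stopifnot(inherits(ann, "gene_annotation"))
  L <- if (is.null(promoter_length)) ann$promoter_length else promoter_length
  g <- ann$genes
  if (!nrow(g)) {
    return(data.table(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer()))
  }
  len <- ann$contigs$length[match(g$chrom, ann$contigs$chrom)]
  ps <- ifelse(g$strand == "+", pmax(0, g$start - L), g$end)
  pe <- ifelse(g$strand == "+", g$start, pmin(len, g$end + L))
  data.table(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             start = as.integer(ps), end = as.integer(pe))
}

#' Intron intervals of an annotation
#'
#' Exactly the gaps between consecutive exons of each gene; single-exon
#' genes contribute nothing.
#'
#' @param ann A [gene_annotation()].
#' @return data.table `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @export
introns_of <- function(ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  ex <- copy(ann$exons)
  if (!nrow(ex)) {
    return(data.table(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer()))
  }
  data.table::setorder(ex, gene_id, start)
  intr <- ex[, if (.N > 1L) list(start = end[-.N], end = start[-1L]),
             by = gene_id]
  if (!nrow(intr) || !"end" %in% names(intr)) {
    return(data.table(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer()))
  }
  intr <- intr[end > start]
  g <- ann$genes
  intr[, chrom := g$chrom[match(gene_id, g$gene_id)]]
  intr[, strand := g$strand[match(gene_id, g$gene_id)]]
  intr[, .(gene_id, chrom, strand, start, end)]
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 files must carry `gene` features (with `ID` and optionally a
#' `biotype` attribute) and `exon` features pointing at their gene via
#' `Parent`. Contig lengths are taken from `##sequence-region` pragmas.
#' BED12 input derives exons from the block structure; names containing
#' "pseudo" are flagged as pseudogenes.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @param promoter_length Promoter size used when deriving promoters
#'   (default 2000 bp; the upstream regulatory window assumed by the
#'   pipeline, configurable because annotations rarely state one).
#' @param plastid Contig name(s) to flag as the unmethylated plastid
#'   (default `"plastid"`).
#' @return A [gene_annotation()].
#' @export
read_annotation <- function(path, promoter_length = 2000,
                            plastid = "plastid") {
  if (!file.exists(path)) stop("read_annotation: no such file: ", path)
  gr <- rtracklayer::import(path)
  # sequence-region pragmas carry contig lengths (incl. gene-free
  # contigs); the importer does not surface them, so read them directly
  hdr <- grep("^##sequence-region", readLines(path, n = 1000L),
              value = TRUE)
  if (length(hdr)) {
    parts <- strsplit(trimws(hdr), "\\s+")
    contigs <- data.table(
      chrom = vapply(parts, `[`, character(1), 2L),
      length = as.numeric(vapply(parts, `[`, character(1), 4L))
    )
  } else {
    si <- GenomicRanges::seqinfo(gr)
    contigs <- data.table(
      chrom = as.character(GenomeInfoDb::seqnames(si)),
      length = as.numeric(GenomeInfoDb::seqlengths(si)))
  }
  mc <- S4Vectors::mcols(gr)

  if ("blocks" %in% names(mc)) {                      # BED12
    genes <- data.table(
      gene_id = as.character(mc$name),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      biotype = ifelse(grepl("pseudo", mc$name, ignore.case = TRUE),
                       "pseudogene", "protein_coding")
    )
    bl <- mc$blocks
    exons <- data.table(
      gene_id = rep(genes$gene_id, S4Vectors::elementNROWS(bl)),
      start = unlist(IRanges::start(bl)) - 1L,
      end = unlist(IRanges::end(bl))
    )
    # BED block starts are relative to the feature start
    exons[, start := start + genes$start[match(gene_id, genes$gene_id)]]
    exons[, end := end + genes$start[match(gene_id, genes$gene_id)]]
  } else {                                            # GFF3
    type <- as.character(mc$type)
    if (!any(type == "gene")) {
      stop("read_annotation: no 'gene' features found in ", path)
    }
    gidx <- type == "gene"
    biot <- if ("biotype" %in% names(mc)) as.character(mc$biotype[gidx])
            else rep(NA_character_, sum(gidx))
    biot[is.na(biot)] <- "protein_coding"
    genes <- data.table(
      gene_id = as.character(mc$ID[gidx]),
      chrom = as.character(GenomicRanges::seqnames(gr)[gidx]),
      strand = as.character(GenomicRanges::strand(gr)[gidx]),
      start = GenomicRanges::start(gr)[gidx] - 1L,
      end = GenomicRanges::end(gr)[gidx],
      biotype = biot
    )
    eidx <- type == "exon"
    parent <- as.character(S4Vectors::unstrsplit(mc$Parent[eidx], ","))
    exons <- data.table(
      gene_id = parent,
      start = GenomicRanges::start(gr)[eidx] - 1L,
      end = GenomicRanges::end(gr)[eidx]
    )
  }
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("read_annotation: unknown strand for gene ",
         genes$gene_id[!genes$strand %in% c("+", "-")][1L])
  }
  if (anyNA(contigs$length)) {
    # no sequence-region pragmas: fall back to feature extents
    ext <- genes[, .(length = max(end) + promoter_length), by = chrom]
    contigs <- merge(contigs, ext, by = "chrom", all.x = TRUE,
                     suffixes = c("", ".ext"))
    contigs[is.na(length), length := length.ext]
    contigs[, length.ext := NULL]
    contigs <- contigs[!is.na(length)]
  }
  contigs[, is_plastid := chrom %in% plastid]
  gene_annotation(genes, exons, contigs, promoter_length = promoter_length)
}

#' Write an annotation to GFF3
#'
#' Genes carry `ID` and `biotype` attributes, exons carry `Parent`; contig
#' lengths are emitted as `##sequence-region` pragmas so round-tripping
#' through [read_annotation()] preserves the contig table (including
#' gene-free contigs such as the plastid).
#'
#' @param ann A [gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "gene_annotation"))
  g <- ann$genes
  ex <- merge(ann$exons, g[, .(gene_id, chrom, strand)], by = "gene_id")
  data.table::setorder(ex, chrom, start)
  seqlen <- stats::setNames(ann$contigs$length, ann$contigs$chrom)
  ggr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id, biotype = g$biotype
  )
  egr <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end), strand = ex$strand,
    type = "exon",
    ID = paste0(ex$gene_id, ".exon", seq_len(nrow(ex))),
    Parent = as.character(ex$gene_id)
  )
  all <- suppressWarnings(c(ggr, egr))
  GenomeInfoDb::seqlevels(all) <- names(seqlen)
  GenomeInfoDb::seqlengths(all) <- seqlen
  rtracklayer::export(all, path, format = "gff3")
  # rtracklayer omits sequence-region pragmas (and stamps a date, which
  # breaks byte-reproducibility); rewrite the header so contig lengths --
  # including gene-free contigs -- round-trip
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##date") &
                   !startsWith(lines, "##source-version") &
                   !startsWith(lines, "##sequence-region")]
  pragmas <- sprintf("##sequence-region %s 1 %d", names(seqlen),
                     as.integer(seqlen))
  writeLines(c(lines[1L], pragmas, lines[-1L]), path)
  invisible(path)
}
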