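#' Read a Bismark cytosine report (CX format)
#'
#' Parses the 7-column tab-separated per-cytosine report written by
#' \code{bismark2bedGraph}/\code{coverage2cytosine}: chromosome, 1-based
#' position, strand, count methylated, count unmethylated, context
#' (CG/CHG/CHH) and trinucleotide. Positions are converted to the
#' package-internal 0-based convention on input; [write_cx_report()]
#' converts back, so write-then-read is an identity.
#'
#' Rows with zero coverage are retained -- coverage filtering is a later,
#' explicit stage ([pair_sites()]). Lines starting with \code{#} are
#' skipped. Any malformed row aborts the read with its line number and the
#' offending column; rows are never silently dropped.
#'
#' @param path Path to the report.
#' @return A `data.table` with columns `chrom`, `pos` (0-based), `strand`,
#'   `n_meth`, `n_unmeth`, `context`, `trinucleotide`.
#' @export
read_cx_report <- function(path) {
  if (!file.exists(path)) stop("read_cx_report: no such file: ", path)
  lines <- readLines(path)
  line_no <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  line_no <- line_no[keep]
  if (!length(lines)) return(empty_sites())
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "",
                          strip.white = FALSE, fill = TRUE)
  if (ncol(dt) != 7L) {
    stop("read_cx_report: expected 7 tab-separated columns, found ",
         ncol(dt))
  }
  if (nrow(dt) != length(lines)) {
    stop("read_cx_report: parsed row count (", nrow(dt),
         ") does not reconcile with input line count (", length(lines),
         ")")
  }
  data.table::setnames(dt, c("chrom", "pos", "strand", "n_meth",
                             "n_unmeth", "context", "trinucleotide"))

  fail <- function(col, rows) {
    stop("read_cx_report: malformed ", col, " at line ", line_no[rows[1L]],
         " (column ", match(col, names(dt)), "): '",
         dt[[col]][rows[1L]], "'")
  }
  pos <- suppressWarnings(as.numeric(dt$pos))
  bad <- which(is.na(pos) | pos != floor(pos) | pos < 1)
  if (length(bad)) fail("pos", bad)
  for (col in c("n_meth", "n_unmeth")) {
    v <- suppressWarnings(as.numeric(dt[[col]]))
    bad <- which(is.na(v) | v != floor(v) | v < 0)
    if (length(bad)) fail(col, bad)
  }
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad)) fail("strand", bad)
  bad <- which(!dt$context %in% c("CG", "CHG", "CHH"))
  if (length(bad)) fail("context", bad)

  out <- data.table(
    chrom = dt$chrom,
    pos = as.integer(pos) - 1L,           # to 0-based
    strand = dt$strand,
    n_meth = as.integer(dt$n_meth),
    n_unmeth = as.integer(dt$n_unmeth),
    context = dt$context,
    trinucleotide = dt$trinucleotide
  )
  out[]
}

#' Write a Bismark-style cytosine report
#'
#' Inverse of [read_cx_report()]; internal 0-based positions are written
#' 1-based. No header line is emitted (the CX dialect has none).
#'
#' @param sites Site table as returned by [read_cx_report()] or
#'   [simulate_methylome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(sites, path) {
  need <- c("chrom", "pos", "strand", "n_meth", "n_unmeth", "context",
            "trinucleotide")
  miss <- setdiff(need, names(sites))
  if (length(miss)) {
    stop("write_cx_report: missing columns: ", paste(miss, collapse = ", "))
  }
  out <- data.table(
    chrom = sites$chrom,
    pos = as.integer(sites$pos) + 1L,
    strand = sites$strand,
    n_meth = sites$n_meth,
    n_unmeth = sites$n_unmeth,
    context = sites$context,
    trinucleotide = sites$trinucleotide
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

empty_sites <- function() {
  data.table(chrom = character(), pos = integer(), strand = character(),
             n_meth = integer(), n_unmeth = integer(), context = character(),
             trinucleotide = character())
}
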