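#' Read a per-gene expression table
#'
#' Tab-separated with header columns `gene_id`, `fpkm_control`,
#' `fpkm_treated`, `p_value`, `q_value`. The p/q columns are the
#' externally computed differential-expression statistics consumed by
#' [select_degs()]; this package does not re-test expression. FPKM of
#' exactly 0 is legal here -- pseudocounting happens downstream, at the
#' log-transform, never at I/O time.
#'
#' @param path Path to the TSV (lines starting with `#` are skipped).
#' @return data.table with the five validated columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("read_expression: no such file: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  need <- c("gene_id", "fpkm_control", "fpkm_treated", "p_value", "q_value")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("read_expression: missing columns: ", paste(miss, collapse = ", "))
  }
  dt <- dt[, ..need]
  if (anyDuplicated(dt$gene_id)) {
    stop("read_expression: duplicate gene_id: ",
         dt$gene_id[duplicated(dt$gene_id)][1L])
  }
  for (col in c("fpkm_control", "fpkm_treated")) {
    v <- dt[[col]]
    if (anyNA(v) || any(v < 0)) {
      stop("read_expression: ", col, " must be non-negative (gene ",
           dt$gene_id[which(is.na(v) | v < 0)[1L]], ")")
    }
  }
  for (col in c("p_value", "q_value")) {
    v <- dt[[col]]
    if (anyNA(v) || any(v < 0 | v > 1)) {
      stop("read_expression: ", col, " must lie in [0, 1] (gene ",
           dt$gene_id[which(is.na(v) | v < 0 | v > 1)[1L]], ")")
    }
  }
  dt[]
}

#' Write a per-gene expression table
#'
#' @param expr Expression table ([read_expression()] /
#'   [simulate_expression()] layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  need <- c("gene_id", "fpkm_control", "fpkm_treated", "p_value", "q_value")
  miss <- setdiff(need, names(expr))
  if (length(miss)) {
    stop("write_expression: missing columns: ", paste(miss, collapse = ", "))
  }
  data.table::fwrite(as.data.table(expr)[, ..need], path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}
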