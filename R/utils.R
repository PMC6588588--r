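#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows distinct n pull rename across group_modify
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_chr map_lgl map_int imap pmap keep
#' @importFrom stats cor rexp runif rnorm rbinom pchisq t.test wilcox.test
#'   setNames quantile median sd
NULL

# internal: sign() with the convention that exact zero stays zero
.sgn <- function(x) sign(x)

# stop with a classed condition so tests can target specific failures
pd_abort <- function(msg, class, ...) {
  abort(msg, class = c(class, "pathdistill_error"), ...)
}

# coerce a gene-by-subject expression table to a numeric matrix.
# Accepts a data frame with a `gene` column (first) plus one numeric column
# per subject, or an already-formed matrix with gene rownames.
as_expr_matrix <- function(expr) {
  if (is.matrix(expr)) {
    if (is.null(rownames(expr))) {
      pd_abort("expression matrix must have gene rownames", "pd_expr_error")
    }
    storage.mode(expr) <- "double"
    return(expr)
  }
  if (!is.data.frame(expr)) {
    pd_abort("`expr` must be a data frame or matrix of log2 ratios",
             "pd_expr_error")
  }
  gene_col <- if ("gene" %in% names(expr)) "gene" else names(expr)[1]
  genes <- as.character(expr[[gene_col]])
  if (anyDuplicated(genes)) {
    pd_abort("duplicate gene identifiers in expression table", "pd_expr_error")
  }
  m <- as.matrix(expr[setdiff(names(expr), gene_col)])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

# expression matrix back to the tidy wide tibble used across the package
expr_as_tibble <- function(m) {
  out <- as_tibble(m, rownames = "gene")
  out
}

check_threshold <- function(x, name, lo = -1, hi = 1, open_lo = FALSE,
                            open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    pd_abort(sprintf("`%s` must be a single number", name), "pd_threshold_error")
  }
  ok <- (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) {
    pd_abort(sprintf("`%s` = %g outside its domain [%g, %g]", name, x, lo, hi),
             "pd_threshold_error")
  }
  invisible(x)
}
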