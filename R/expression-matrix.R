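#' Two-group expression matrix
#'
#' Bundle a genes-by-samples matrix of log2 intensities with a two-group
#' sample annotation (control vs case). All downstream differential
#' expression works on this container.
#'
#' @param values Numeric matrix, genes in rows (unique rownames = gene
#'   symbols), samples in columns (colnames = sample IDs). Values are
#'   assumed already normalized and log2 transformed.
#' @param groups Factor or character vector named by sample ID (or in
#'   column order) with exactly the levels `"control"` and `"case"`.
#' @return An object of class `"expression_matrix"`: a list with elements
#'   `values` and `groups`.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("G", 1:4), paste0("S", 1:5)))
#' expression_matrix(m, c("control", "control", "case", "case", "case"))
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols in 'values' rownames", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs in 'values' colnames", call. = FALSE)
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-finite expression value for gene '%s', sample '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]),
         call. = FALSE)
  }
  groups <- as.character(groups)
  if (is.null(names(groups))) {
    if (length(groups) != ncol(values))
      stop("'groups' must be named by sample or match the column count",
           call. = FALSE)
    names(groups) <- colnames(values)
  }
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing) > 0)
    stop(sprintf("sample '%s' has no group label", missing[1]), call. = FALSE)
  groups <- factor(groups[colnames(values)], levels = c("control", "case"))
  if (anyNA(groups))
    stop("group labels must be 'control' or 'case'", call. = FALSE)
  if (any(table(groups) == 0))
    stop("both groups must be non-empty", call. = FALSE)
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d control, %d case)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "control"), sum(x$groups == "case")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)
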