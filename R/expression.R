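#' Construct an expression matrix with condition labels
#'
#' Bundles a genes-by-samples matrix of (log2-scale) expression values with a
#' sample-to-condition assignment. This is the raw input of every
#' differential co-expression comparison.
#'
#' @param values Numeric matrix, genes in rows (unique rownames required),
#'   samples in columns (unique colnames required). No missing values.
#' @param conditions Named character vector mapping sample id to condition
#'   label; names must cover exactly the columns of `values`. An unnamed
#'   vector of length `ncol(values)` is taken in column order.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` and `conditions`.
#' @examples
#' m <- matrix(rnorm(20, 8), 5, 4,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' expression_matrix(m, c(s1 = "a", s2 = "a", s3 = "b", s4 = "b"))
#' @export
expression_matrix <- function(values, conditions) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("gene ids (rownames) must be present and unique")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("sample ids (colnames) must be present and unique")
  if (anyNA(values)) stop("expression values must not contain missing values")
  conditions <- as.character(structure(conditions, names = names(conditions)))
  if (is.null(names(conditions))) {
    if (length(conditions) != ncol(values))
      stop("unnamed `conditions` must have one entry per sample")
    names(conditions) <- colnames(values)
  }
  if (!setequal(names(conditions), colnames(values)))
    stop("`conditions` names must match the sample ids exactly")
  conditions <- conditions[colnames(values)]
  structure(list(values = values, conditions = conditions),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  tab <- table(x$conditions)
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("conditions:", paste(sprintf("%s (n=%d)", names(tab), tab),
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Samples belonging to one condition
#'
#' @param expr An [expression_matrix()].
#' @param condition Condition label.
#' @param min_n Minimum number of samples required (correlation needs at
#'   least 3).
#' @return Character vector of sample ids.
#' @keywords internal
condition_samples <- function(expr, condition, min_n = 3L) {
  ids <- names(expr$conditions)[expr$conditions == condition]
  if (length(ids) == 0L)
    stop(sprintf("condition '%s' has no samples", condition))
  if (length(ids) < min_n)
    stop(sprintf("condition '%s' has %d samples; at least %d are required",
                 condition, length(ids), min_n))
  ids
}
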