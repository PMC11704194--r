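#' Construct an omics abundance matrix
#'
#' A thin S3 wrapper around a numeric features x samples matrix carrying the
#' omics layer tag (`"mrna"`, `"protein"`, `"phosphosite"`, ...), a
#' normalization-state flag and, after imputation, a logical mask marking
#' imputed cells so downstream rank statistics can exclude them.
#'
#' @param x Numeric matrix, features in rows, samples in columns; dimnames
#'   required.
#' @param layer Character layer tag.
#' @param normalized Logical; `TRUE` once columns are on the FOT scale.
#' @param imputed Optional logical matrix of the same shape marking imputed
#'   cells.
#' @return An `omics_matrix` object (a matrix with extra attributes).
#' @export
omics_matrix <- function(x, layer = "protein", normalized = FALSE,
                         imputed = NULL) {
  if (!is.matrix(x) || !is.numeric(x)) stopf("x must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("x must have row (feature) and column (sample) names")
  if (!is.null(imputed)) {
    if (!identical(dim(imputed), dim(x)))
      stopf("imputation mask must match the matrix dimensions")
    imputed <- array(as.logical(imputed), dim = dim(x), dimnames = dimnames(x))
  }
  structure(x, layer = layer, normalized = normalized, imputed = imputed,
            class = c("omics_matrix", class(x)))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> layer=%s  %d features x %d samples%s%s\n",
              attr(x, "layer"), nrow(x), ncol(x),
              if (isTRUE(attr(x, "normalized"))) "  (FOT-normalized)" else "",
              if (!is.null(attr(x, "imputed")))
                sprintf("  %d imputed cells", sum(attr(x, "imputed"))) else ""))
  invisible(x)
}

#' Logical mask of imputed cells
#'
#' Returns the imputation mask attached to an [omics_matrix()] (an all-`FALSE`
#' matrix when none is attached), so rank- and correlation-based statistics
#' can exclude imputed cells.
#'
#' @param x An [omics_matrix()].
#' @return Logical matrix of the same shape as `x`.
#' @export
imputed_mask <- function(x) {
  m <- attr(x, "imputed")
  if (is.null(m)) array(FALSE, dim = dim(x), dimnames = dimnames(x)) else m
}

# Drop the omics_matrix attributes, returning a bare numeric matrix.
as_bare_matrix <- function(x) {
  attr(x, "layer") <- NULL
  attr(x, "normalized") <- NULL
  attr(x, "imputed") <- NULL
  class(x) <- setdiff(class(x), "omics_matrix")
  x
}
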