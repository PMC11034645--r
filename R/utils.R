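#' Logistic (sigmoid) function
#'
#' @param x numeric vector or matrix.
#' @return values of \eqn{1 / (1 + e^{-x})}, same shape as `x`.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Row-wise Euclidean normalization
#'
#' Scales each row of a matrix to unit Euclidean norm; all-zero rows are
#' left at zero. This is the normalization used both for aggregation
#' adjacencies and for node embeddings.
#'
#' @param x numeric matrix.
#' @return matrix of the same shape with unit-norm (or zero) rows.
#' @export
row_normalize <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nz <- nrm > 0
  x[nz, ] <- x[nz, , drop = FALSE] / nrm[nz]
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_probkg <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# full-precision numeric formatting for bit-exact text round trips
format_full <- function(x) sprintf("%.17g", x)
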