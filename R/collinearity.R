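#' Condition number of a design matrix (eigensystem collinearity diagnostic)
#'
#' Quantifies multicollinearity of a multivariable design. The default
#' Belsley convention scales each column of the design (intercept included)
#' to unit Euclidean length and returns the square root of the ratio of the
#' largest to the smallest eigenvalue of the scaled cross-product matrix —
#' equivalently the ratio of the largest to smallest singular value of the
#' scaled design. Condition numbers below ~30 are conventionally read as
#' little or no collinearity concern. The alternative `"correlation"`
#' convention uses the eigenvalues of the correlation matrix of the
#' non-constant columns.
#'
#' @param x A numeric design matrix (>= 2 columns), or an `np_fit` whose
#'   design is used.
#' @param method `"belsley"` (default) or `"correlation"`.
#' @return A single number; `Inf` for an exactly singular design. The
#'   convention used is attached as attribute `method`.
#' @examples
#' condition_number(cbind(1, c(-1, 0, 1), c(1, -2, 1)))  # orthogonal: 1
#' @export
condition_number <- function(x, method = c("belsley", "correlation")) {
  method <- match.arg(method)
  X <- if (inherits(x, "np_fit")) x$X else as.matrix(x)
  if (ncol(X) < 2L) stop("Design must have at least 2 columns", call. = FALSE)
  if (method == "correlation") {
    keep <- apply(X, 2, function(v) stats::sd(v) > 0)
    X <- scale(X[, keep, drop = FALSE])
  } else {
    len <- sqrt(colSums(X^2))
    if (any(len == 0)) return(structure(Inf, method = method))
    X <- sweep(X, 2, len, "/")
  }
  ev <- eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  if (min(ev) <= max(ev) * .Machine$double.eps * nrow(X)) {
    return(structure(Inf, method = method))
  }
  structure(sqrt(max(ev) / min(ev)), method = method)
}
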