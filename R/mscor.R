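#' Partial correlation given a conditioning set
#'
#' Correlation between \code{a} and \code{b} after removing the linear effect
#' of the conditioning vectors in \code{M}. The default route inverts the
#' joint correlation matrix of \code{[a, b, M]} and reads the partial
#' correlation off the precision matrix
#' (\code{-P[1,2] / sqrt(P[1,1] P[2,2])}); \code{method = "residual"}
#' regresses \code{a} and \code{b} on \code{M} and correlates the residuals.
#' The two routes agree to numerical precision and serve as mutual checks.
#' With an empty \code{M} the Pearson correlation is returned.
#'
#' @param a,b aligned numeric sample vectors.
#' @param M matrix of conditioning vectors (samples in rows), or \code{NULL}.
#' @param method \code{"inverse"} (default) or \code{"residual"}.
#' @param strict if \code{TRUE}, a rank-deficient conditioning set is an
#'   error; otherwise the Moore-Penrose pseudo-inverse is used with a
#'   warning.
#' @return The partial correlation, in \code{[-1, 1]}.
#' @export
partial_correlation <- function(a, b, M = NULL,
                                method = c("inverse", "residual"),
                                strict = FALSE) {
  method <- match.arg(method)
  if (is.null(M) || NCOL(M) == 0L) return(stats::cor(a, b))
  if (is.vector(M)) M <- matrix(M, ncol = 1L)
  n <- length(a)
  if (length(b) != n || nrow(M) != n) stop("a, b and rows of M must align")
  if (n <= ncol(M) + 2L) stop("need more samples than conditioning vectors + 2")
  if (method == "residual") {
    X <- cbind(1, M)
    ra <- stats::lm.fit(X, a)$residuals
    rb <- stats::lm.fit(X, b)$residuals
    return(stats::cor(ra, rb))
  }
  R <- stats::cor(cbind(a, b, M))
  P <- tryCatch(solve(R), error = function(e) {
    if (strict) stop("conditioning set is rank-deficient")
    warning("correlation matrix singular; using pseudo-inverse")
    MASS::ginv(R)
  })
  -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
}

#' Multiple sensitivity correlation (mscor)
#'
#' The drop from Pearson to partial correlation of a gene pair when the
#' shared miRNA set \code{M} is controlled for:
#' \deqn{mscor(g_a, g_b, M) = cor(g_a, g_b) - pcor(g_a, g_b \mid M).}
#' A value near zero means the gene-gene correlation survives conditioning —
#' the pair interacts directly, insensitive to the miRNAs. A value near
#' \code{cor(g_a, g_b)} means the correlation is explained away by the
#' shared miRNAs, i.e. miRNA-mediated competition (the ceRNA signature).
#' Symmetric in \code{(a, b)} and invariant under positive affine rescaling
#' of any input.
#'
#' @inheritParams partial_correlation
#' @return \code{cor(a, b) - pcor(a, b | M)}; bounded by 2 in magnitude.
#' @export
mscor <- function(a, b, M = NULL, method = c("inverse", "residual")) {
  stats::cor(a, b) - partial_correlation(a, b, M, method = match.arg(method))
}

# Fast internal mscor for null simulation: columns 1:2 are the gene pair,
# the rest the miRNAs.
mscor_from_matrix <- function(X) {
  R <- stats::cor(X)
  P <- tryCatch(solve(R), error = function(e) MASS::ginv(R))
  R[1L, 2L] + P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
}
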