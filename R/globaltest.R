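#' Score-type global test of association with permutation p-value
#'
#' Tests whether a response expression profile \code{y} is associated with a
#' set of covariate profiles (here: one or more miRNAs), using the
#' score-type statistic of the global test for groups of covariates:
#' with \code{y} and the columns of \code{X} mean-centred,
#' \deqn{Q = \frac{\| X_c^\top y_c \|^2}{p \cdot \mathrm{var}(y_c)},}
#' where \code{p} is the number of covariates. \code{Q} is large when the
#' covariates jointly explain variation in \code{y}; it is direction-free, so
#' the negative-correlation requirement of the pipeline is enforced
#' separately via the Pearson sign. Significance is assessed by permuting the
#' sample labels of \code{y}.
#'
#' @param y numeric response vector (target gene expression).
#' @param X numeric matrix of covariates, samples in rows (a vector is taken
#'   as a single covariate).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed; permutations are reproducible given the seed.
#' @return List with \code{Q} (statistic) and \code{p} (permutation p-value,
#'   \code{(1 + #[Q_perm >= Q]) / (n_perm + 1)}).
#' @export
global_test <- function(y, X, n_perm = 1000L, seed = 1L) {
  if (is.vector(X)) X <- matrix(X, ncol = 1L)
  n <- length(y)
  if (nrow(X) != n) stop("X rows must align with y")
  if (n < 3L) stop("need at least 3 samples")
  if (n_perm < 99L) stop("n_perm must be >= 99")
  if (stats::var(y) == 0) stop("y has zero variance")
  csd <- apply(X, 2L, stats::sd)
  if (any(csd == 0)) stop("constant covariate column(s)")
  yc <- y - mean(y)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  p <- ncol(Xc)
  vy <- stats::var(y)
  Q <- sum(crossprod(Xc, yc)^2) / (p * vy)
  # permute y jointly against all covariates; var(y) is permutation-invariant
  perm_idx <- with_seed(seed, replicate(n_perm, sample.int(n)))
  Yp <- matrix(yc[perm_idx], nrow = n)
  Qp <- colSums(crossprod(Xc, Yp)^2) / (p * vy)
  list(Q = Q, p = (1 + sum(Qp >= Q)) / (n_perm + 1))
}

#' Filter miRNA-target edges for significant negative correlation
#'
#' Step B of the pipeline: a miRNA-target interaction is kept only if the two
#' expression profiles are anti-correlated (Pearson r < 0) and their
#' association is significant under the permutation global test. By default
#' each edge is tested with its single miRNA as covariate
#' (\code{mode = "per_edge"}); \code{mode = "per_target"} tests each target
#' once against all its miRNAs jointly and shares that p-value across the
#' target's edges.
#'
#' @param dataset a \code{cerna_dataset}.
#' @param edges optional data.frame with columns \code{mirna_id},
#'   \code{target_id} restricting which catalog edges are tested; defaults to
#'   all catalog edges. Edges whose miRNA or target is absent from the
#'   expression matrices are dropped with a warning.
#' @param alpha significance level for the global-test p-value.
#' @param n_perm permutations per test.
#' @param seed master seed; per-test seeds are derived deterministically so
#'   the output table is byte-identical across runs.
#' @param mode \code{"per_edge"} or \code{"per_target"} (see above).
#' @return data.frame with one row per tested edge: \code{mirna_id},
#'   \code{target_id}, \code{r}, \code{Q}, \code{p_gt}, \code{retained}.
#' @export
filter_negative_edges <- function(dataset, edges = NULL, alpha = 0.05,
                                  n_perm = 1000L, seed = 1L,
                                  mode = c("per_edge", "per_target")) {
  mode <- match.arg(mode)
  if (is.null(edges)) {
    edges <- dataset$catalog$edges[, c("mirna_id", "target_id")]
  }
  edges <- unique(as.data.frame(edges,
                                stringsAsFactors = FALSE)[, c("mirna_id",
                                                              "target_id")])
  ok <- edges$mirna_id %in% rownames(dataset$mirna_expr) &
    edges$target_id %in% rownames(dataset$gene_expr)
  if (any(!ok)) {
    warning(sprintf("dropping %d edge(s) absent from the expression matrices",
                    sum(!ok)))
    edges <- edges[ok, , drop = FALSE]
  }
  edges <- edges[order(edges$mirna_id, edges$target_id), , drop = FALSE]
  n_edge <- nrow(edges)
  out <- data.frame(edges, r = numeric(n_edge), Q = numeric(n_edge),
                    p_gt = numeric(n_edge), retained = logical(n_edge),
                    stringsAsFactors = FALSE)
  if (n_edge == 0L) return(out)

  if (mode == "per_edge") {
    for (i in seq_len(n_edge)) {
      m <- dataset$mirna_expr[edges$mirna_id[i], ]
      g <- dataset$gene_expr[edges$target_id[i], ]
      gt <- global_test(g, m, n_perm = n_perm,
                        seed = stage_seed(seed, paste0("edge", i)))
      out$r[i] <- stats::cor(m, g)
      out$Q[i] <- gt$Q
      out$p_gt[i] <- gt$p
    }
  } else {
    by_target <- split(seq_len(n_edge), edges$target_id)
    for (tid in names(by_target)) {
      idx <- by_target[[tid]]
      X <- t(dataset$mirna_expr[edges$mirna_id[idx], , drop = FALSE])
      g <- dataset$gene_expr[tid, ]
      gt <- global_test(g, X, n_perm = n_perm,
                        seed = stage_seed(seed, paste0("target", tid)))
      out$r[idx] <- stats::cor(X, g)[, 1L]
      out$Q[idx] <- gt$Q
      out$p_gt[idx] <- gt$p
    }
  }
  out$retained <- out$r < 0 & out$p_gt <= alpha
  rownames(out) <- NULL
  out
}
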