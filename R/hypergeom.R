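#' Upper-tail hypergeometric p-value for a shared-miRNA overlap
#'
#' Given \code{N} available miRNAs of which \code{K} interact with ceRNA-A
#' and \code{O} with ceRNA-B, the probability that the two regulator sets
#' share at least \code{x} miRNAs by chance:
#' \deqn{p = 1 - \sum_{i=0}^{x-1} \binom{K}{i}\binom{N-K}{O-i} / \binom{N}{O}
#'         = P(X \ge x),\quad X \sim \mathrm{Hypergeom}(N, K, O).}
#' The tail sum is evaluated directly in log-space (log-binomials with a
#' log-sum-exp reduction), which stays accurate for catalogs of thousands of
#' miRNAs where raw binomial coefficients overflow.
#'
#' @param N total number of available miRNAs.
#' @param K number of miRNAs interacting with ceRNA-A.
#' @param O number of miRNAs interacting with ceRNA-B.
#' @param x number of miRNAs shared by both.
#' @return The upper-tail probability, in \code{[0, 1]}.
#' @export
hypergeom_pvalue <- function(N, K, O, x) {
  for (v in list(N = N, K = K, O = O, x = x)) {
    if (length(v) != 1L || is.na(v) || v < 0 || v != round(v)) {
      stop("N, K, O, x must be single non-negative integers")
    }
  }
  if (K > N || O > N) stop("K and O must not exceed N")
  if (x > min(K, O)) stop("x must not exceed min(K, O)")
  if (x < max(0, K + O - N)) stop("x below the minimum feasible overlap")
  if (x == 0L) return(1)          # empty sum: P(X >= 0) = 1
  i <- x:min(K, O)
  logterms <- lchoose(K, i) + lchoose(N - K, O - i) - lchoose(N, O)
  mx <- max(logterms)
  p <- exp(mx) * sum(exp(logterms - mx))
  min(max(p, 0), 1)
}

#' Enumerate candidate ceRNA pairs by shared-miRNA significance
#'
#' Step A of the pipeline. Every pair of a protein-coding gene (ceRNA-A) and
#' a sponge-eligible partner (ceRNA-B: protein-coding, lncRNA or pseudogene)
#' present in both the catalog and the gene expression matrix is tested for a
#' larger-than-chance overlap of miRNA regulators with
#' \code{\link{hypergeom_pvalue}}. \code{N} counts the catalog miRNAs that
#' are also present in the miRNA expression matrix (only expressed miRNAs can
#' participate downstream), and the per-target regulator sets are restricted
#' accordingly. Each unordered pair is tested once, oriented with the
#' protein-coding gene as ceRNA-A (lexicographic for coding-coding pairs).
#'
#' @param dataset a \code{cerna_dataset}.
#' @param min_shared minimum number of shared miRNAs for a pair to be tested.
#' @param alpha significance level applied to the (adjusted) p-value.
#' @param adjust multiplicity adjustment across all tested pairs:
#'   \code{"none"} (default; the pipeline thresholds raw p-values) or
#'   \code{"BH"}.
#' @return data.frame of retained candidates: \code{cerna_a}, \code{cerna_b},
#'   \code{n_shared}, \code{shared_mirnas} (\code{"; "}-joined), \code{N},
#'   \code{K}, \code{O}, \code{p_hyper}, \code{p_hyper_adj}; ordered by
#'   adjusted p, then lexicographically.
#' @export
enumerate_candidates <- function(dataset, min_shared = 1L, alpha = 0.05,
                                 adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (min_shared < 1L) stop("min_shared must be >= 1")
  catalog <- dataset$catalog
  expressed_mirnas <- intersect(catalog$mirna_universe,
                                rownames(dataset$mirna_expr))
  N <- length(expressed_mirnas)
  empty <- data.frame(cerna_a = character(), cerna_b = character(),
                      n_shared = integer(), shared_mirnas = character(),
                      N = integer(), K = integer(), O = integer(),
                      p_hyper = numeric(), p_hyper_adj = numeric(),
                      stringsAsFactors = FALSE)
  if (N == 0L) return(empty)
  keep <- catalog$edges$mirna_id %in% expressed_mirnas &
    catalog$edges$target_id %in% rownames(dataset$gene_expr)
  edges <- catalog$edges[keep, , drop = FALSE]
  if (nrow(edges) == 0L) return(empty)
  map <- lapply(split(edges$mirna_id, edges$target_id), unique)
  targets <- names(map)
  bt <- catalog$target_biotype[targets]
  coding <- targets[bt == "protein_coding"]
  eligible <- targets[bt %in% SPONGE_BIOTYPES]
  if (length(coding) == 0L) return(empty)

  rows <- list()
  seen <- character()
  for (a in coding) {
    mir_a <- map[[a]]
    for (b in eligible) {
      if (a == b) next
      # canonical orientation: coding partner first; coding-coding pairs
      # lexicographic, tested once
      if (bt[[b]] == "protein_coding" && b < a) next
      key <- pair_key(a, b)
      if (key %in% seen) next
      seen <- c(seen, key)
      shared <- sort(intersect(mir_a, map[[b]]))
      x <- length(shared)
      if (x < min_shared) next
      rows[[length(rows) + 1L]] <- data.frame(
        cerna_a = a, cerna_b = b, n_shared = x,
        shared_mirnas = paste(shared, collapse = "; "),
        N = N, K = length(mir_a), O = length(map[[b]]),
        p_hyper = hypergeom_pvalue(N, length(mir_a), length(map[[b]]), x),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out$p_hyper_adj <- if (adjust == "BH") {
    stats::p.adjust(out$p_hyper, method = "BH")
  } else {
    out$p_hyper
  }
  out <- out[out$p_hyper_adj <= alpha, , drop = FALSE]
  out <- out[order(out$p_hyper_adj, out$cerna_a, out$cerna_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
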