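#' Score candidate ceRNA pairs with mscor and empirical p-values
#'
#' Step C of the pipeline. Each candidate pair's shared miRNA set is first
#' intersected with the step-B survivors: a miRNA counts only if its edges to
#' both ceRNA-A and ceRNA-B were retained as significantly anti-correlated.
#' Candidates whose intersected set is empty are dropped. The survivors are
#' scored with \code{\link{mscor}} over the intersected miRNA set and
#' assigned a one-sided empirical p-value from the stratified null. A
#' reported interaction must additionally show positive gene-gene correlation
#' (the competing partners of a sponge rise and fall together).
#'
#' @param dataset a \code{cerna_dataset}.
#' @param candidates data.frame from \code{\link{enumerate_candidates}}.
#' @param edge_tests data.frame from \code{\link{filter_negative_edges}}.
#' @param null_model a \code{cerna_null} covering the queried
#'   (m, correlation) strata.
#' @param alpha significance level on the empirical p-value.
#' @param adjust \code{"none"} (default: raw empirical p-values are
#'   reported) or \code{"BH"}.
#' @return data.frame of significant interactions, sorted by p-value then
#'   mscor descending: \code{cerna_a}, \code{cerna_b},
#'   \code{n_shared_mirnas}, \code{shared_mirnas} (\code{"; "}-joined),
#'   \code{cor}, \code{pcor}, \code{mscor}, \code{p_value}.
#' @export
score_candidates <- function(dataset, candidates, edge_tests, null_model,
                             alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  empty <- data.frame(cerna_a = character(), cerna_b = character(),
                      n_shared_mirnas = integer(), shared_mirnas = character(),
                      cor = numeric(), pcor = numeric(), mscor = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L) return(empty)
  retained <- edge_tests[edge_tests$retained, , drop = FALSE]
  retained_key <- paste(retained$mirna_id, retained$target_id, sep = "\r")

  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    a <- candidates$cerna_a[i]
    b <- candidates$cerna_b[i]
    shared <- strsplit(candidates$shared_mirnas[i], "; ", fixed = TRUE)[[1L]]
    ok <- paste(shared, a, sep = "\r") %in% retained_key &
      paste(shared, b, sep = "\r") %in% retained_key
    shared <- shared[ok]
    if (length(shared) == 0L) next
    ea <- dataset$gene_expr[a, ]
    eb <- dataset$gene_expr[b, ]
    M <- t(dataset$mirna_expr[shared, , drop = FALSE])
    cor_ab <- stats::cor(ea, eb)
    if (cor_ab <= 0) next
    pcor_ab <- partial_correlation(ea, eb, M)
    ms <- cor_ab - pcor_ab
    rows[[length(rows) + 1L]] <- data.frame(
      cerna_a = a, cerna_b = b,
      n_shared_mirnas = length(shared),
      shared_mirnas = paste(shared, collapse = "; "),
      cor = cor_ab, pcor = pcor_ab, mscor = ms,
      p_value = empirical_pvalue(null_model, ms, length(shared), cor_ab),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out <- out[out$p_value <= alpha, , drop = FALSE]
  out <- out[order(out$p_value, -out$mscor, out$cerna_a, out$cerna_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Strata actually needed to score a candidate set: the (m, cor-bin) pairs the
# surviving candidates will query. Used by run_pipeline to avoid simulating
# the full default grid.
needed_strata <- function(dataset, candidates, edge_tests, m_levels,
                          cor_bin_edges) {
  if (nrow(candidates) == 0L) return(NULL)
  retained <- edge_tests[edge_tests$retained, , drop = FALSE]
  retained_key <- paste(retained$mirna_id, retained$target_id, sep = "\r")
  n_bins <- length(cor_bin_edges) - 1L
  out <- list()
  for (i in seq_len(nrow(candidates))) {
    a <- candidates$cerna_a[i]
    b <- candidates$cerna_b[i]
    shared <- strsplit(candidates$shared_mirnas[i], "; ", fixed = TRUE)[[1L]]
    ok <- paste(shared, a, sep = "\r") %in% retained_key &
      paste(shared, b, sep = "\r") %in% retained_key
    m <- sum(ok)
    if (m == 0L) next
    cor_ab <- stats::cor(dataset$gene_expr[a, ], dataset$gene_expr[b, ])
    if (cor_ab <= 0 || cor_ab > cor_bin_edges[length(cor_bin_edges)]) next
    bin <- findInterval(cor_ab, cor_bin_edges, left.open = TRUE,
                        rightmost.closed = TRUE)
    m_bin <- if (m >= max(m_levels)) max(m_levels) else
      m_levels[m_levels >= m][1L]
    out[[length(out) + 1L]] <- c(m = m_bin, cor_bin = bin)
  }
  if (length(out) == 0L) return(NULL)
  unique(as.data.frame(do.call(rbind, out)))
}
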