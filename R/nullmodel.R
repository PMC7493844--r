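#' Build a stratified empirical null distribution for mscor
#'
#' Simulates the sampling distribution of \code{\link{mscor}} under the null
#' of no miRNA-mediated sensitivity: the gene pair is drawn bivariate normal
#' with correlation \code{k}, and the \code{m} miRNA vectors are independent
#' of both genes. Under this null the population partial correlation equals
#' the population correlation, so mscor fluctuates around zero with a spread
#' that depends on the sample size, the number of conditioning miRNAs
#' \code{m} and the gene-gene correlation \code{k} — hence the stratification
#' by (\code{m} bin, \code{cor} bin). Each stratum is simulated at the centre
#' of its correlation bin.
#'
#' @param n_samples samples per simulated dataset; must match the sample
#'   count of the data the null is applied to.
#' @param m_levels shared-miRNA counts to stratify over; observed counts
#'   above the maximum are mapped to the last level.
#' @param cor_bin_edges increasing bin edges over (0, 1] for the gene-gene
#'   correlation.
#' @param n_draws null draws per stratum (>= 100).
#' @param seed integer seed; the model is reproducible given the seed.
#' @param strata optional data.frame with columns \code{m}, \code{cor_bin}
#'   (bin index into \code{cor_bin_edges}) restricting which strata are
#'   simulated; defaults to the full grid.
#' @return An object of class \code{cerna_null}: per-stratum numeric vectors
#'   of null mscor draws plus the bin definitions and metadata.
#' @export
build_null_model <- function(n_samples, m_levels = 1:8,
                             cor_bin_edges = seq(0, 1, by = 0.1),
                             n_draws = 10000L, seed = 1L, strata = NULL) {
  if (n_draws < 100L) stop("n_draws must be >= 100 per stratum")
  if (length(m_levels) == 0L || length(cor_bin_edges) < 2L) {
    stop("empty stratum specification")
  }
  m_levels <- sort(unique(as.integer(m_levels)))
  n_bins <- length(cor_bin_edges) - 1L
  if (is.null(strata)) {
    strata <- expand.grid(m = m_levels, cor_bin = seq_len(n_bins))
  }
  draws <- vector("list", nrow(strata))
  names(draws) <- paste0("m", strata$m, "_k", strata$cor_bin)
  for (s in seq_len(nrow(strata))) {
    m <- strata$m[s]
    k <- (cor_bin_edges[strata$cor_bin[s]] +
            cor_bin_edges[strata$cor_bin[s] + 1L]) / 2
    sk <- stage_seed(seed, names(draws)[s])
    draws[[s]] <- with_seed(sk, {
      vapply(seq_len(n_draws), function(d) {
        z0 <- stats::rnorm(n_samples)
        ga <- sqrt(k) * z0 + sqrt(1 - k) * stats::rnorm(n_samples)
        gb <- sqrt(k) * z0 + sqrt(1 - k) * stats::rnorm(n_samples)
        M <- matrix(stats::rnorm(n_samples * m), ncol = m)
        mscor_from_matrix(cbind(ga, gb, M))
      }, numeric(1L))
    })
  }
  structure(list(draws = draws, m_levels = m_levels,
                 cor_bin_edges = cor_bin_edges, n_samples = n_samples,
                 n_draws = n_draws, seed = seed),
            class = "cerna_null")
}

#' @export
print.cerna_null <- function(x, ...) {
  cat(sprintf(
    "<cerna_null> %d strata x %d draws (n_samples = %d, seed = %d)\n",
    length(x$draws), x$n_draws, x$n_samples, x$seed))
  invisible(x)
}

# Map an observed (m, cor) to its stratum key; NULL if no such stratum.
# m above the largest level falls into the top (">max") bin; m between
# levels maps to the nearest level from above.
null_stratum_key <- function(null_model, m, cor_ab) {
  if (m < min(null_model$m_levels)) return(NULL)
  m_bin <- if (m >= max(null_model$m_levels)) {
    max(null_model$m_levels)
  } else {
    null_model$m_levels[null_model$m_levels >= m][1L]
  }
  edges <- null_model$cor_bin_edges
  if (cor_ab <= edges[1L] || cor_ab > edges[length(edges)]) return(NULL)
  bin <- findInterval(cor_ab, edges, left.open = TRUE, rightmost.closed = TRUE)
  paste0("m", m_bin, "_k", bin)
}

#' Empirical p-value of an observed mscor against the stratified null
#'
#' One-sided upper-tail p-value with the add-one convention:
#' \code{p = (1 + #[null >= mscor_obs]) / (n_draws + 1)}. Only positive
#' mscor indicates miRNA-mediated (indirect) correlation, hence the upper
#' tail.
#'
#' @param null_model a \code{cerna_null}.
#' @param mscor_obs observed mscor value.
#' @param m number of shared (conditioning) miRNAs.
#' @param cor_ab observed gene-gene Pearson correlation (selects the
#'   correlation stratum).
#' @return The empirical p-value in \code{(0, 1]}.
#' @export
empirical_pvalue <- function(null_model, mscor_obs, m, cor_ab) {
  key <- null_stratum_key(null_model, m, cor_ab)
  if (is.null(key) || is.null(null_model$draws[[key]])) {
    stop(sprintf("no null stratum for m = %d, cor = %.3f", m, cor_ab))
  }
  draws <- null_model$draws[[key]]
  (1 + sum(draws >= mscor_obs)) / (length(draws) + 1)
}

#' Serialize / restore a null model as JSON
#'
#' Plain-text round-trip of a \code{cerna_null} with its metadata (seed,
#' bins, draw counts) for reuse across runs.
#'
#' @param null_model a \code{cerna_null}.
#' @param path file path.
#' @return \code{write_null_model}: \code{path}, invisibly;
#'   \code{read_null_model}: the restored \code{cerna_null}.
#' @export
write_null_model <- function(null_model, path) {
  jsonlite::write_json(unclass(null_model), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_null_model
#' @export
read_null_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$draws <- as.list(x$draws)
  structure(x, class = "cerna_null")
}
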