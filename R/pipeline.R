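#' Run configuration for the ceRNA pipeline
#'
#' One object holding every tunable of the three stages plus the master
#' seed. Stage seeds are derived deterministically from the master seed so
#' each stage is individually reproducible.
#'
#' @param alpha_hyper significance level of the hypergeometric stage.
#' @param adjust_hyper multiplicity adjustment at the hypergeometric stage
#'   (\code{"BH"} or \code{"none"}).
#' @param min_shared minimum shared miRNAs per candidate pair.
#' @param alpha_gt significance level of the global-test stage.
#' @param n_perm permutations per global test.
#' @param gt_mode \code{"per_edge"} or \code{"per_target"}.
#' @param alpha_mscor significance level on the empirical mscor p-value.
#' @param adjust_mscor adjustment at the scoring stage (\code{"none"}
#'   default; raw empirical p-values are reported).
#' @param null_draws null draws per stratum.
#' @param m_levels,cor_bin_edges null-model stratification.
#' @param seed master seed.
#' @return A \code{cerna_config} (validated list).
#' @export
cerna_config <- function(alpha_hyper = 0.05, adjust_hyper = "none",
                         min_shared = 1L, alpha_gt = 0.05, n_perm = 1000L,
                         gt_mode = "per_edge", alpha_mscor = 0.05,
                         adjust_mscor = "none", null_draws = 10000L,
                         m_levels = 1:8,
                         cor_bin_edges = seq(0, 1, by = 0.1),
                         seed = 1L) {
  cfg <- list(alpha_hyper = alpha_hyper, adjust_hyper = adjust_hyper,
              min_shared = as.integer(min_shared), alpha_gt = alpha_gt,
              n_perm = as.integer(n_perm), gt_mode = gt_mode,
              alpha_mscor = alpha_mscor, adjust_mscor = adjust_mscor,
              null_draws = as.integer(null_draws),
              m_levels = as.integer(m_levels),
              cor_bin_edges = cor_bin_edges, seed = as.integer(seed))
  for (a in c("alpha_hyper", "alpha_gt", "alpha_mscor")) {
    if (cfg[[a]] <= 0 || cfg[[a]] > 1) stop(a, " must be in (0, 1]")
  }
  structure(cfg, class = "cerna_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of \code{\link{cerna_config}}; entries in
#' \code{overrides} (e.g. command-line flags) take precedence over file
#' values.
#'
#' @param path YAML file, or \code{NULL} for defaults.
#' @param overrides named list of values overriding the file.
#' @return A \code{cerna_config}.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(cerna_config, vals)
}

#' Run the full three-step ceRNA inference pipeline
#'
#' Executes, in order: (A) hypergeometric enumeration of candidate pairs
#' sharing a significant miRNA set; (B) the permutation global test keeping
#' only significantly anti-correlated miRNA-target edges — computed just for
#' the edges incident to some step-A candidate, which is result-equivalent to
#' testing all edges; (C) mscor scoring against the stratified empirical
#' null. The null model is built on demand for exactly the strata the
#' candidates query, unless one is supplied.
#'
#' @param dataset a \code{cerna_dataset}.
#' @param config a \code{cerna_config}.
#' @param out_dir optional directory; when given, writes
#'   \code{candidates.tsv}, \code{edge_tests.tsv}, \code{interactions.tsv}
#'   (exactly the six result columns: ceRNA-A, ceRNA-B, shared miRNAs, list
#'   of shared miRNAs, mscor, p-value), \code{report.json} and
#'   \code{config.lock}. On a stage failure, partial outputs are removed.
#' @param null_model optional pre-built \code{cerna_null}.
#' @param extended_columns also write cor, pcor, tissue and condition columns
#'   in \code{interactions.tsv}.
#' @return An object of class \code{cerna_run}: the three stage tables, the
#'   run report and the configuration.
#' @export
run_pipeline <- function(dataset, config = cerna_config(), out_dir = NULL,
                         null_model = NULL, extended_columns = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        unlink(file.path(out_dir, c("candidates.tsv", "edge_tests.tsv",
                                    "interactions.tsv", "report.json",
                                    "config.lock")))
      }
      stop(sprintf("%s failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  candidates <- stage("step A (hypergeometric filter)",
    enumerate_candidates(dataset, min_shared = config$min_shared,
                         alpha = config$alpha_hyper,
                         adjust = config$adjust_hyper))

  # step B only needs the edges between candidate genes and their shared
  # miRNAs; all other edges cannot reach step C
  edge_df <- data.frame(mirna_id = character(), target_id = character(),
                        stringsAsFactors = FALSE)
  if (nrow(candidates) > 0L) {
    el <- lapply(seq_len(nrow(candidates)), function(i) {
      mirs <- strsplit(candidates$shared_mirnas[i], "; ", fixed = TRUE)[[1L]]
      expand.grid(mirna_id = mirs,
                  target_id = c(candidates$cerna_a[i],
                                candidates$cerna_b[i]),
                  stringsAsFactors = FALSE)
    })
    edge_df <- unique(do.call(rbind, el))
  }
  edge_tests <- stage("step B (global-test negative-correlation filter)",
    filter_negative_edges(dataset, edges = edge_df, alpha = config$alpha_gt,
                          n_perm = config$n_perm,
                          seed = stage_seed(config$seed, "stepB"),
                          mode = config$gt_mode))

  interactions <- stage("step C (mscor scoring)", {
    if (is.null(null_model)) {
      strata <- needed_strata(dataset, candidates, edge_tests,
                              config$m_levels, config$cor_bin_edges)
      null_model <- if (is.null(strata)) {
        NULL
      } else {
        build_null_model(n_samples = ncol(dataset$gene_expr),
                         m_levels = config$m_levels,
                         cor_bin_edges = config$cor_bin_edges,
                         n_draws = config$null_draws,
                         seed = stage_seed(config$seed, "stepC"),
                         strata = strata)
      }
    }
    if (is.null(null_model)) {
      score_candidates(dataset, candidates[0L, , drop = FALSE], edge_tests,
                       build_null_model(ncol(dataset$gene_expr),
                                        m_levels = 1L,
                                        cor_bin_edges = c(0, 1),
                                        n_draws = 100L, seed = 1L))
    } else {
      score_candidates(dataset, candidates, edge_tests, null_model,
                       alpha = config$alpha_mscor,
                       adjust = config$adjust_mscor)
    }
  })

  report <- list(
    tissue = dataset$tissue_label, condition = dataset$condition,
    n_samples = ncol(dataset$gene_expr),
    n_candidates = nrow(candidates),
    n_edges_tested = nrow(edge_tests),
    n_edges_retained = sum(edge_tests$retained),
    n_interactions = nrow(interactions),
    seed = config$seed)

  run <- structure(list(candidates = candidates, edge_tests = edge_tests,
                        interactions = interactions, report = report,
                        config = config,
                        tissue_label = dataset$tissue_label,
                        condition = dataset$condition),
                   class = "cerna_run")
  if (!is.null(out_dir)) write_run(run, out_dir,
                                   extended_columns = extended_columns)
  run
}

# Final result header, exactly the six columns of the output table.
RESULT_COLUMNS <- c("ceRNA-A", "ceRNA-B", "shared miRNAs",
                    "list of shared miRNAs", "mscor", "p-value")

interactions_table <- function(interactions, run = NULL,
                               extended_columns = FALSE) {
  out <- data.frame(interactions$cerna_a, interactions$cerna_b,
                    interactions$n_shared_mirnas,
                    interactions$shared_mirnas,
                    interactions$mscor, interactions$p_value,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- RESULT_COLUMNS
  if (extended_columns) {
    out$cor <- interactions$cor
    out$pcor <- interactions$pcor
    out$tissue <- run$tissue_label
    out$condition <- run$condition
  }
  out
}

#' Write a pipeline run to an output directory
#'
#' @param run a \code{cerna_run}.
#' @param out_dir output directory (created if needed).
#' @param extended_columns see \code{\link{run_pipeline}}.
#' @return \code{out_dir}, invisibly.
#' @export
write_run <- function(run, out_dir, extended_columns = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(run$candidates, file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$edge_tests, file.path(out_dir, "edge_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(interactions_table(run$interactions, run,
                                        extended_columns),
                     file.path(out_dir, "interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- run$config
  lock <- vapply(names(cfg), function(k)
    paste0(k, "=", paste(cfg[[k]], collapse = ",")), character(1L))
  writeLines(lock, file.path(out_dir, "config.lock"))
  invisible(out_dir)
}

#' @export
print.cerna_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("<cerna_run> %s / %s (n = %d samples, seed = %d)\n",
              r$tissue, r$condition, r$n_samples, r$seed))
  cat(sprintf("  step A candidates: %d\n", r$n_candidates))
  cat(sprintf("  step B edges retained: %d / %d tested\n",
              r$n_edges_retained, r$n_edges_tested))
  cat(sprintf("  step C interactions: %d\n", r$n_interactions))
  invisible(x)
}

#' @export
summary.cerna_run <- function(object, ...) {
  print(object)
  if (nrow(object$interactions)) {
    cat("\nTop interactions:\n")
    print(utils::head(interactions_table(object$interactions), 10L),
          row.names = FALSE)
  }
  invisible(object)
}
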