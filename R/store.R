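#' Collect pipeline runs into a multi-tissue result store
#'
#' Mirrors the service workflow of browsing ceRNA interactions across
#' tissues: runs are keyed by tissue label and condition and can be queried
#' per pair or per miRNA.
#'
#' @param ... \code{cerna_run} objects (or a single list of them).
#' @return An object of class \code{cerna_store}.
#' @export
result_store <- function(...) {
  runs <- list(...)
  if (length(runs) == 1L && !inherits(runs[[1L]], "cerna_run")) {
    runs <- runs[[1L]]
  }
  if (!all(vapply(runs, inherits, logical(1L), "cerna_run"))) {
    stop("all elements must be cerna_run objects")
  }
  names(runs) <- vapply(runs, function(r)
    paste(r$tissue_label, r$condition, sep = "/"), character(1L))
  if (anyDuplicated(names(runs))) stop("duplicate tissue/condition runs")
  structure(list(runs = runs), class = "cerna_store")
}

#' @export
print.cerna_store <- function(x, ...) {
  cat(sprintf("<cerna_store> %d run(s): %s\n", length(x$runs),
              paste(names(x$runs), collapse = ", ")))
  invisible(x)
}

# Which pipeline stage eliminated a pair in a given run?
pair_stage <- function(run, a, b) {
  key <- pair_key(a, b)
  if (key %in% pair_key(run$interactions$cerna_a, run$interactions$cerna_b)) {
    return("present")
  }
  cand <- run$candidates
  hit <- which(pair_key(cand$cerna_a, cand$cerna_b) == key)
  if (length(hit) == 0L) return("removed_step_A")
  retained <- run$edge_tests[run$edge_tests$retained, , drop = FALSE]
  rk <- paste(retained$mirna_id, retained$target_id, sep = "\r")
  shared <- strsplit(cand$shared_mirnas[hit[1L]], "; ", fixed = TRUE)[[1L]]
  both <- paste(shared, cand$cerna_a[hit[1L]], sep = "\r") %in% rk &
    paste(shared, cand$cerna_b[hit[1L]], sep = "\r") %in% rk
  if (!any(both)) "removed_step_B" else "removed_step_C"
}

#' Query stored results for ceRNA pairs across tissues
#'
#' For each requested tissue, returns the matching interaction rows, or an
#' explicit absence marker annotated with the stage that removed the pair.
#' The cross-tissue count of a pair (in how many stored runs it appears)
#' comes as an attribute.
#'
#' @param store a \code{cerna_store}.
#' @param cerna_a gene id (or vector of ids).
#' @param cerna_b optional partner id(s); \code{NULL} matches any partner.
#' @param tissues run keys (\code{"<tissue>/<condition>"} or tissue labels);
#'   \code{NULL} queries all.
#' @return data.frame with one row per (tissue, pair): run key, pair ids,
#'   shared miRNAs, mscor, p-value, \code{present} flag and \code{stage};
#'   attribute \code{cross_tissue_count} maps each pair to the number of
#'   runs where it is present.
#' @export
query_pair <- function(store, cerna_a, cerna_b = NULL, tissues = NULL) {
  keys <- names(store$runs)
  if (!is.null(tissues)) {
    sel <- keys %in% tissues |
      vapply(strsplit(keys, "/", fixed = TRUE), `[[`, "", 1L) %in% tissues
    if (!any(sel)) {
      stop("unknown tissue(s); available: ", paste(keys, collapse = ", "))
    }
    keys <- keys[sel]
  }
  rows <- list()
  for (k in keys) {
    run <- store$runs[[k]]
    tab <- run$interactions
    hit <- tab[tab$cerna_a %in% cerna_a | tab$cerna_b %in% cerna_a, ,
               drop = FALSE]
    if (!is.null(cerna_b)) {
      hit <- hit[hit$cerna_a %in% cerna_b | hit$cerna_b %in% cerna_b, ,
                 drop = FALSE]
      hit <- hit[pair_key(hit$cerna_a, hit$cerna_b) %in%
                   pair_key(rep(cerna_a, each = length(cerna_b)),
                            rep(cerna_b, times = length(cerna_a))), ,
                 drop = FALSE]
    }
    if (nrow(hit)) {
      hit <- hit[order(hit$p_value), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        run = k, hit[, c("cerna_a", "cerna_b", "n_shared_mirnas",
                         "shared_mirnas", "mscor", "p_value")],
        present = TRUE, stage = "present", stringsAsFactors = FALSE)
    } else if (!is.null(cerna_b) && length(cerna_a) == 1L &&
                 length(cerna_b) == 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        run = k, cerna_a = cerna_a, cerna_b = cerna_b,
        n_shared_mirnas = NA_integer_, shared_mirnas = NA_character_,
        mscor = NA_real_, p_value = NA_real_, present = FALSE,
        stage = pair_stage(run, cerna_a, cerna_b),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(run = character(), cerna_a = character(),
               cerna_b = character(), n_shared_mirnas = integer(),
               shared_mirnas = character(), mscor = numeric(),
               p_value = numeric(), present = logical(), stage = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  present <- out[out$present, , drop = FALSE]
  attr(out, "cross_tissue_count") <-
    table(pair_key(present$cerna_a, present$cerna_b))
  out
}

#' Retained targets of a miRNA in one tissue
#'
#' Lists the step-B-retained targets of a miRNA (significantly
#' anti-correlated edges) in a stored run, with their correlation and
#' global-test p-value.
#'
#' @param store a \code{cerna_store}.
#' @param mirna_id miRNA identifier.
#' @param tissue run key or tissue label.
#' @return data.frame with \code{target_id}, \code{r}, \code{p_gt}; empty
#'   (with a warning) for a miRNA with no retained edges.
#' @export
annotate_mirna_targets <- function(store, mirna_id, tissue) {
  keys <- names(store$runs)
  sel <- keys == tissue |
    vapply(strsplit(keys, "/", fixed = TRUE), `[[`, "", 1L) == tissue
  if (!any(sel)) {
    stop("unknown tissue '", tissue, "'; available: ",
         paste(keys, collapse = ", "))
  }
  run <- store$runs[[which(sel)[1L]]]
  et <- run$edge_tests
  hit <- et[et$mirna_id == mirna_id & et$retained, , drop = FALSE]
  if (nrow(hit) == 0L) {
    warning("no retained targets for miRNA '", mirna_id, "' in ", tissue)
  }
  out <- hit[, c("target_id", "r", "p_gt")]
  rownames(out) <- NULL
  out
}
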