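#' Construct a miRNA-target interaction catalog
#'
#' A bipartite edge set from miRNAs to target RNAs (mRNAs, lncRNAs,
#' pseudogene transcripts), emulating the union of validated/predicted
#' interaction databases. Duplicate edges are collapsed and their evidence
#' tags merged. The catalog's miRNA universe carries the total count of
#' available miRNAs used by the hypergeometric test.
#'
#' @param edges data.frame with columns \code{mirna_id}, \code{target_id},
#'   \code{target_biotype}, \code{source}.
#' @return An object of class \code{cerna_catalog}: a list with the
#'   deduplicated \code{edges} data.frame, the named \code{target_biotype}
#'   vector and the \code{mirna_universe} character vector.
#' @export
interaction_catalog <- function(edges) {
  req <- c("mirna_id", "target_id", "target_biotype", "source")
  missing <- setdiff(req, colnames(edges))
  if (length(missing)) {
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "))
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  bad <- setdiff(unique(edges$target_biotype), SPONGE_BIOTYPES)
  if (length(bad)) {
    stop("unsupported target biotype(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(SPONGE_BIOTYPES, collapse = ", "), ")")
  }
  # A target must carry a single biotype across all its edges.
  bt <- tapply(edges$target_biotype, edges$target_id,
               function(b) unique(b), simplify = FALSE)
  multi <- names(bt)[lengths(bt) > 1L]
  if (length(multi)) {
    stop("conflicting biotypes for target(s): ", paste(multi, collapse = ", "))
  }
  key <- paste(edges$mirna_id, edges$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    src <- tapply(edges$source, key, function(s)
      paste(sort(unique(s)), collapse = ";"))
    first <- !duplicated(key)
    edges <- edges[first, , drop = FALSE]
    edges$source <- as.character(src[paste(edges$mirna_id, edges$target_id,
                                           sep = "\r")])
  }
  edges <- edges[order(edges$mirna_id, edges$target_id), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    edges = edges[, req, drop = FALSE],
    target_biotype = vapply(bt, identity, character(1L)),
    mirna_universe = sort(unique(edges$mirna_id))
  ), class = "cerna_catalog")
}

#' @export
print.cerna_catalog <- function(x, ...) {
  cat(sprintf("<cerna_catalog> %d edges, %d miRNAs, %d targets\n",
              nrow(x$edges), length(x$mirna_universe),
              length(x$target_biotype)))
  invisible(x)
}

#' Read a miRNA-target catalog from TSV
#'
#' Columns: \code{mirna_id}, \code{target_id}, \code{target_biotype},
#' \code{source}. Target biotypes outside the sponge-eligible set
#' (\code{protein_coding}, \code{lncRNA}, \code{pseudogene}) are rejected.
#'
#' @param path catalog TSV.
#' @return A \code{\link{interaction_catalog}}.
#' @export
read_catalog <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "")
  interaction_catalog(tab)
}

#' Write a catalog to TSV
#' @param x a \code{cerna_catalog}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_catalog <- function(x, path) {
  utils::write.table(x$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# target id -> character vector of interacting miRNAs
target_mirna_map <- function(catalog) {
  split(catalog$edges$mirna_id, catalog$edges$target_id)
}

#' Shared miRNA regulators of two targets
#'
#' The exact intersection of the miRNA neighborhoods of targets \code{a} and
#' \code{b} in the catalog; the core set operation behind the shared-miRNA
#' triplet (ceRNA-A, miRNA set, ceRNA-B).
#'
#' @param catalog a \code{cerna_catalog}.
#' @param a,b target identifiers present in the catalog.
#' @return Sorted character vector of shared miRNA ids (possibly empty).
#' @export
shared_mirnas <- function(catalog, a, b) {
  map <- target_mirna_map(catalog)
  for (id in c(a, b)) {
    if (is.null(map[[id]])) stop("unknown target id: ", id)
  }
  sort(intersect(map[[a]], map[[b]]))
}
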