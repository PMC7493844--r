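#' Construct an expression matrix with per-feature biotypes
#'
#' The container used throughout the pipeline for log-scale, normalized
#' expression: a numeric features x samples matrix plus one biotype label
#' per feature (one of \code{protein_coding}, \code{lncRNA},
#' \code{pseudogene}, \code{miRNA}).
#'
#' @param values numeric matrix, features in rows, samples in columns; both
#'   dimensions must carry unique names.
#' @param biotype character vector of biotype labels, either named by feature
#'   or in row order.
#' @return An object of class \code{cerna_expression}: the matrix with a
#'   \code{biotype} attribute.
#' @export
expression_matrix <- function(values, biotype) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("expression matrix is empty")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    stop("expression matrix must have feature (row) and sample (column) names")
  }
  dup <- fid[duplicated(fid)]
  if (length(dup)) {
    stop("duplicate feature identifier(s): ", paste(unique(dup), collapse = ", "))
  }
  dup <- sid[duplicated(sid)]
  if (length(dup)) {
    stop("duplicate sample identifier(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at feature '%s', sample '%s'",
                 fid[bad[1L]], sid[bad[2L]]))
  }
  if (!is.null(names(biotype))) {
    missing <- setdiff(fid, names(biotype))
    if (length(missing)) {
      stop("no biotype for feature(s): ", paste(missing, collapse = ", "))
    }
    biotype <- unname(biotype[fid])
  }
  if (length(biotype) != nrow(values)) {
    stop("`biotype` must provide exactly one label per feature")
  }
  bad <- setdiff(unique(biotype), CERNA_BIOTYPES)
  if (length(bad)) {
    stop("unsupported biotype(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(CERNA_BIOTYPES, collapse = ", "), ")")
  }
  structure(values, biotype = stats::setNames(biotype, fid),
            class = c("cerna_expression", "matrix", "array"))
}

#' @export
print.cerna_expression <- function(x, ...) {
  bt <- table(attr(x, "biotype"))
  cat(sprintf("<cerna_expression> %d features x %d samples\n", nrow(x), ncol(x)))
  cat("  biotypes:", paste(sprintf("%s=%d", names(bt), bt), collapse = ", "), "\n")
  invisible(x)
}

#' Biotype labels of an expression matrix
#' @param x a \code{cerna_expression}.
#' @return Named character vector, one label per feature.
#' @export
biotypes <- function(x) attr(x, "biotype")

#' Read an expression matrix from TSV
#'
#' Expects a UTF-8 tab-separated file whose header row is
#' \code{feature_id <tab> <sample ids...>} and whose remaining cells are
#' numeric. Biotypes come either from a two-column map file
#' (\code{feature_id <tab> biotype}) or from a single label applied to all
#' features (e.g. a miRNA matrix).
#'
#' @param path expression TSV.
#' @param biotype_map optional path to a feature/biotype map TSV.
#' @param biotype optional single biotype applied to every feature; exactly
#'   one of \code{biotype_map}/\code{biotype} must be given.
#' @param log2_transform if \code{TRUE}, apply \code{log2(x + 1)} to the
#'   values; off by default because inputs are assumed already log-scale.
#' @return A \code{\link{expression_matrix}}.
#' @export
read_expression <- function(path, biotype_map = NULL, biotype = NULL,
                            log2_transform = FALSE) {
  if (is.null(biotype_map) == is.null(biotype)) {
    stop("supply exactly one of `biotype_map` or `biotype`")
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "")
  if (nrow(tab) == 0L || ncol(tab) < 2L) {
    stop("empty expression matrix in '", path, "'")
  }
  fid <- tab[[1L]]
  dup <- unique(fid[duplicated(fid)])
  if (length(dup)) {
    stop("duplicate feature identifier(s) in '", path, "': ",
         paste(dup, collapse = ", "))
  }
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf(
        "non-numeric cell in '%s': feature '%s', sample '%s' (value '%s')",
        path, fid[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]],
        vals[bad[1L, 1L], bad[1L, 2L]]))
    }
    stop("missing values in '", path, "'")
  }
  dimnames(num) <- list(fid, colnames(vals))
  if (log2_transform) num <- log2(num + 1)
  if (!is.null(biotype_map)) {
    bm <- utils::read.delim(biotype_map, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character")
    if (!all(c("feature_id", "biotype") %in% colnames(bm))) {
      stop("biotype map must have columns feature_id and biotype")
    }
    biotype <- stats::setNames(bm$biotype, bm$feature_id)
  } else {
    biotype <- rep(biotype, nrow(num))
  }
  expression_matrix(num, biotype)
}

#' Write an expression matrix to TSV
#'
#' Full-precision inverse of \code{\link{read_expression}}; round-trips are
#' lossless.
#'
#' @param x a \code{cerna_expression}.
#' @param path output file.
#' @param biotype_path optional path for the companion biotype map TSV.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(x, path, biotype_path = NULL) {
  vals <- matrix(sprintf("%.17g", unclass(x)), nrow = nrow(x))
  df <- data.frame(feature_id = rownames(x), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(biotype_path)) {
    bm <- data.frame(feature_id = rownames(x),
                     biotype = unname(biotypes(x)),
                     stringsAsFactors = FALSE)
    utils::write.table(bm, biotype_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Drop features with zero variance across samples
#'
#' Correlations are undefined for constant features, so they are removed
#' before any correlation stage, with a warning naming how many were dropped.
#'
#' @param x a \code{cerna_expression}.
#' @return The matrix restricted to non-constant features.
#' @export
drop_zero_variance <- function(x) {
  v <- apply(x, 1L, stats::var)
  keep <- v > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance feature(s): %s",
                    sum(!keep),
                    paste(utils::head(rownames(x)[!keep], 5L), collapse = ", ")))
    if (!any(keep)) stop("all features have zero variance")
    x <- expression_matrix(unclass(x)[keep, , drop = FALSE],
                           biotypes(x)[keep])
  }
  x
}

#' Restrict two expression matrices to their common samples
#'
#' Both matrices are reduced to the intersection of their sample identifiers,
#' in the gene-matrix order (deterministic and symmetric in content). The
#' operation is idempotent.
#'
#' @param gene_expr,mirna_expr \code{cerna_expression} objects.
#' @return List with aligned \code{gene_expr}, \code{mirna_expr} and
#'   \code{n_common}, the intersection size.
#' @export
align_samples <- function(gene_expr, mirna_expr) {
  common <- intersect(colnames(gene_expr), colnames(mirna_expr))
  if (length(common) == 0L) {
    stop("no samples in common between gene and miRNA expression matrices")
  }
  g <- expression_matrix(unclass(gene_expr)[, common, drop = FALSE],
                         biotypes(gene_expr))
  m <- expression_matrix(unclass(mirna_expr)[, common, drop = FALSE],
                         biotypes(mirna_expr))
  list(gene_expr = g, mirna_expr = m, n_common = length(common))
}
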