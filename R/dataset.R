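#' Bundle the inputs for one tissue/condition run
#'
#' Holds aligned gene and miRNA expression matrices plus the interaction
#' catalog for one tissue and condition. Samples are aligned by identifier
#' intersection (gene-matrix order); zero-variance features are dropped with
#' a warning because every downstream stage is correlation-based.
#'
#' @param gene_expr \code{cerna_expression} of non-miRNA biotypes.
#' @param mirna_expr \code{cerna_expression} of biotype \code{miRNA}.
#' @param catalog a \code{cerna_catalog}.
#' @param tissue_label free-text tissue name.
#' @param condition \code{"normal"} or \code{"tumour"}.
#' @return An object of class \code{cerna_dataset}.
#' @export
tissue_dataset <- function(gene_expr, mirna_expr, catalog,
                           tissue_label = "tissue",
                           condition = c("tumour", "normal")) {
  condition <- match.arg(condition)
  if (any(biotypes(gene_expr) == "miRNA")) {
    stop("gene_expr must not contain miRNA features")
  }
  if (!all(biotypes(mirna_expr) == "miRNA")) {
    stop("mirna_expr must contain only miRNA features")
  }
  al <- align_samples(gene_expr, mirna_expr)
  g <- drop_zero_variance(al$gene_expr)
  m <- drop_zero_variance(al$mirna_expr)
  if (length(intersect(names(catalog$target_biotype), rownames(g))) == 0L) {
    warning("no catalog target is present in the gene expression matrix; ",
            "the pipeline will produce empty results")
  }
  structure(list(gene_expr = g, mirna_expr = m, catalog = catalog,
                 tissue_label = tissue_label, condition = condition),
            class = "cerna_dataset")
}

#' @export
print.cerna_dataset <- function(x, ...) {
  cat(sprintf("<cerna_dataset> %s / %s\n", x$tissue_label, x$condition))
  cat(sprintf("  genes: %d, miRNAs: %d, samples: %d, catalog edges: %d\n",
              nrow(x$gene_expr), nrow(x$mirna_expr), ncol(x$gene_expr),
              nrow(x$catalog$edges)))
  invisible(x)
}
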