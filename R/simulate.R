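#' Specification for the synthetic ceRNA data generator
#'
#' Collects the parameters of the Gaussian linear generator: miRNA profiles
#' are i.i.d. normal per sample; each planted ("true") sponge triplet picks
#' \code{shared_per_triplet} miRNAs and builds both partner genes as
#' \code{baseline - beta * sum(miRNAs) + noise} with independent noise, so
#' the pair is positively correlated purely through shared miRNA repression;
#' decoy pairs share catalog edges to miRNAs but their expression is pure
#' noise (no coupling); background genes are noise and the catalog is
#' sprinkled with random background edges so the hypergeometric stage has
#' non-trivial rejection behaviour.
#'
#' @param n_samples samples per matrix.
#' @param n_mirnas number of miRNAs.
#' @param n_coding,n_lncrna,n_pseudo gene counts per biotype.
#' @param n_true_triplets planted sponge pairs.
#' @param n_decoy_pairs catalog-only decoy pairs.
#' @param beta repression effect size (positive regression coefficient of
#'   each shared miRNA on its targets).
#' @param noise_sd residual standard deviation of gene expression.
#' @param mirna_mean,mirna_sd miRNA expression distribution parameters.
#' @param shared_per_triplet shared miRNAs per planted/decoy pair.
#' @param background_edge_density probability of a random background catalog
#'   edge between any (miRNA, gene) not already connected.
#' @param seed integer seed; generation is fully reproducible.
#' @return A \code{cerna_generator_spec} (validated list).
#' @export
generator_spec <- function(n_samples = 200L, n_mirnas = 150L,
                           n_coding = 60L, n_lncrna = 30L, n_pseudo = 10L,
                           n_true_triplets = 5L, n_decoy_pairs = 20L,
                           beta = 0.8, noise_sd = 1,
                           mirna_mean = 0, mirna_sd = 1,
                           shared_per_triplet = 2L,
                           background_edge_density = 0.01,
                           seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples),
               n_mirnas = as.integer(n_mirnas),
               n_coding = as.integer(n_coding),
               n_lncrna = as.integer(n_lncrna),
               n_pseudo = as.integer(n_pseudo),
               n_true_triplets = as.integer(n_true_triplets),
               n_decoy_pairs = as.integer(n_decoy_pairs),
               beta = beta, noise_sd = noise_sd,
               mirna_mean = mirna_mean, mirna_sd = mirna_sd,
               shared_per_triplet = as.integer(shared_per_triplet),
               background_edge_density = background_edge_density,
               seed = as.integer(seed))
  counts <- spec[c("n_samples", "n_mirnas", "n_coding", "n_lncrna",
                   "n_pseudo", "n_true_triplets", "n_decoy_pairs")]
  if (any(unlist(counts) < 0L)) stop("counts must be non-negative")
  if (spec$beta < 0) stop("beta must be non-negative")
  if (spec$noise_sd <= 0) stop("noise_sd must be positive")
  if (spec$shared_per_triplet < 1L) stop("shared_per_triplet must be >= 1")
  if (spec$background_edge_density < 0 || spec$background_edge_density > 1) {
    stop("background_edge_density must be in [0, 1]")
  }
  structure(spec, class = "cerna_generator_spec")
}

#' Generate a synthetic tissue dataset with known ground truth
#'
#' Draws expression matrices and an interaction catalog with planted
#' miRNA-sponge structure per the \code{\link{generator_spec}}; see there for
#' the model. ceRNA-B biotypes cycle through lncRNA, pseudogene and
#' protein-coding so all sponge-eligibility branches are exercised. Each
#' planted or decoy pair uses its own disjoint miRNA block, keeping the
#' ground truth unambiguous.
#'
#' @param spec a \code{cerna_generator_spec}.
#' @param tissue_label,condition passed through to the dataset.
#' @return List with \code{dataset} (a \code{cerna_dataset}) and
#'   \code{truth}: \code{true_pairs} and \code{decoy_pairs} data.frames
#'   (\code{cerna_a}, \code{cerna_b}) and \code{true_repressive_edges}
#'   (\code{mirna_id}, \code{target_id}).
#' @export
generate_dataset <- function(spec = generator_spec(),
                             tissue_label = "synthetic",
                             condition = "tumour") {
  s <- spec
  n_pairs <- s$n_true_triplets + s$n_decoy_pairs
  if (2L * n_pairs > s$n_coding + s$n_lncrna + s$n_pseudo) {
    stop("not enough genes for the requested triplets and decoys")
  }
  if (n_pairs * s$shared_per_triplet > s$n_mirnas) {
    stop("not enough miRNAs for disjoint shared sets")
  }
  # each pair needs a protein-coding ceRNA-A
  if (n_pairs > s$n_coding) stop("not enough protein-coding genes for ceRNA-A")

  mir_ids <- sprintf("mir-%03d", seq_len(s$n_mirnas))
  gene_ids <- c(sprintf("CG%03d", seq_len(s$n_coding)),
                sprintf("LNC%03d", seq_len(s$n_lncrna)),
                sprintf("PSG%03d", seq_len(s$n_pseudo)))
  gene_bt <- stats::setNames(
    rep(c("protein_coding", "lncRNA", "pseudogene"),
        c(s$n_coding, s$n_lncrna, s$n_pseudo)), gene_ids)

  with_seed(s$seed, {
    mirna <- matrix(stats::rnorm(s$n_mirnas * s$n_samples,
                                 s$mirna_mean, s$mirna_sd),
                    nrow = s$n_mirnas,
                    dimnames = list(mir_ids, sprintf("s%04d",
                                                     seq_len(s$n_samples))))
    genes <- matrix(0, nrow = length(gene_ids), ncol = s$n_samples,
                    dimnames = list(gene_ids, colnames(mirna)))
    baseline <- stats::rnorm(length(gene_ids), mean = 8, sd = 2)

    # assign partners: ceRNA-A from the coding pool, ceRNA-B cycling
    # through the biotype pools
    pool_a <- gene_ids[gene_bt == "protein_coding"]
    pool_b_by_bt <- split(gene_ids, gene_bt[gene_ids])
    bt_cycle <- rep(c("lncRNA", "pseudogene", "protein_coding"),
                    length.out = n_pairs)
    used <- character()
    mir_cursor <- 0L
    pairs <- vector("list", n_pairs)
    for (p in seq_len(n_pairs)) {
      a <- setdiff(pool_a, used)[1L]
      used <- c(used, a)
      b <- NA_character_
      for (bt in unique(c(bt_cycle[p], "lncRNA", "pseudogene",
                          "protein_coding"))) {
        cand <- setdiff(pool_b_by_bt[[bt]], used)
        if (length(cand)) { b <- cand[1L]; break }
      }
      used <- c(used, b)
      mirs <- mir_ids[mir_cursor + seq_len(s$shared_per_triplet)]
      mir_cursor <- mir_cursor + s$shared_per_triplet
      pairs[[p]] <- list(a = a, b = b, mirs = mirs,
                         planted = p <= s$n_true_triplets)
    }

    edges <- list()
    for (p in pairs) {
      repression <- if (p$planted) {
        s$beta * colSums(mirna[p$mirs, , drop = FALSE])
      } else 0
      for (g in c(p$a, p$b)) {
        genes[g, ] <- baseline[match(g, gene_ids)] - repression +
          stats::rnorm(s$n_samples, 0, s$noise_sd)
        edges[[length(edges) + 1L]] <- data.frame(
          mirna_id = p$mirs, target_id = g,
          target_biotype = unname(gene_bt[g]),
          source = if (p$planted) "planted" else "decoy",
          stringsAsFactors = FALSE)
      }
    }
    background <- setdiff(gene_ids, used)
    genes[background, ] <- baseline[match(background, gene_ids)] +
      matrix(stats::rnorm(length(background) * s$n_samples, 0, s$noise_sd),
             nrow = length(background))

    # random background edges over not-yet-connected (miRNA, gene) cells
    if (s$background_edge_density > 0) {
      existing <- do.call(rbind, edges)
      ex_key <- paste(existing$mirna_id, existing$target_id)
      grid_m <- rep(mir_ids, times = length(gene_ids))
      grid_g <- rep(gene_ids, each = length(mir_ids))
      free <- !(paste(grid_m, grid_g) %in% ex_key)
      pick <- free & stats::runif(length(grid_m)) < s$background_edge_density
      if (any(pick)) {
        edges[[length(edges) + 1L]] <- data.frame(
          mirna_id = grid_m[pick], target_id = grid_g[pick],
          target_biotype = unname(gene_bt[grid_g[pick]]),
          source = "background", stringsAsFactors = FALSE)
      }
    }

    catalog <- interaction_catalog(do.call(rbind, edges))
    gene_expr <- expression_matrix(genes, gene_bt)
    mirna_expr <- expression_matrix(
      mirna, stats::setNames(rep("miRNA", s$n_mirnas), mir_ids))

    truth_rows <- function(keep) {
      kept <- Filter(function(p) p$planted == keep, pairs)
      if (length(kept) == 0L) {
        return(data.frame(cerna_a = character(), cerna_b = character(),
                          stringsAsFactors = FALSE))
      }
      data.frame(cerna_a = vapply(kept, `[[`, "", "a"),
                 cerna_b = vapply(kept, `[[`, "", "b"),
                 stringsAsFactors = FALSE)
    }
    rep_edges <- do.call(rbind, lapply(Filter(function(p) p$planted, pairs),
                                       function(p)
                                         expand.grid(mirna_id = p$mirs,
                                                     target_id = c(p$a, p$b),
                                                     stringsAsFactors = FALSE)))
    if (is.null(rep_edges)) {
      rep_edges <- data.frame(mirna_id = character(),
                              target_id = character(),
                              stringsAsFactors = FALSE)
    }
    ds <- suppressWarnings(
      tissue_dataset(gene_expr, mirna_expr, catalog,
                     tissue_label = tissue_label, condition = condition))
    list(dataset = ds,
         truth = list(true_pairs = truth_rows(TRUE),
                      decoy_pairs = truth_rows(FALSE),
                      true_repressive_edges = rep_edges))
  })
}

#' Precision and recall of predicted ceRNA pairs against ground truth
#'
#' Pair matching is orientation-insensitive. Precision is defined as 1 when
#' nothing is predicted (no false positives were made).
#'
#' @param predicted data.frame with columns \code{cerna_a}, \code{cerna_b}
#'   (e.g. a pipeline interaction table).
#' @param truth ground-truth list from \code{\link{generate_dataset}}.
#' @return List with \code{precision}, \code{recall}, \code{n_true_positive}.
#' @export
evaluate_recovery <- function(predicted, truth) {
  true_keys <- pair_key(truth$true_pairs$cerna_a, truth$true_pairs$cerna_b)
  pred_keys <- unique(pair_key(predicted$cerna_a, predicted$cerna_b))
  tp <- sum(pred_keys %in% true_keys)
  list(precision = if (length(pred_keys) == 0L) 1 else tp / length(pred_keys),
       recall = if (length(true_keys) == 0L) 1 else tp / length(true_keys),
       n_true_positive = tp)
}

#' Write a dataset (and optional truth) as plain-text files
#'
#' Writes \code{gene_expr.tsv}, \code{gene_biotypes.tsv},
#' \code{mirna_expr.tsv}, \code{catalog.tsv} and, when truth is supplied,
#' \code{truth.json} into \code{dir}.
#'
#' @param dataset a \code{cerna_dataset}.
#' @param dir output directory (created if needed).
#' @param truth optional ground-truth list.
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(dataset$gene_expr, file.path(dir, "gene_expr.tsv"),
                   file.path(dir, "gene_biotypes.tsv"))
  write_expression(dataset$mirna_expr, file.path(dir, "mirna_expr.tsv"))
  write_catalog(dataset$catalog, file.path(dir, "catalog.tsv"))
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
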