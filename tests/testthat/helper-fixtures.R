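# Small in-code fixtures shared across test files.

# expression matrix with given ids and deterministic random values
make_expr <- function(feature_ids, sample_ids, biotype, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(length(feature_ids) * length(sample_ids), 8, 2),
                 nrow = length(feature_ids),
                 dimnames = list(feature_ids, sample_ids))
  expression_matrix(vals, setNames(rep_len(biotype, length(feature_ids)),
                                   feature_ids))
}

# catalog from a bare (mirna, target) edge list; coding targets by default
make_catalog <- function(mirna_id, target_id,
                         biotype = "protein_coding", source = "validated") {
  interaction_catalog(data.frame(
    mirna_id = mirna_id, target_id = target_id,
    target_biotype = rep_len(biotype, length(target_id)),
    source = rep_len(source, length(target_id)),
    stringsAsFactors = FALSE))
}

# random catalog over n_mirnas x n_targets with edge probability p
random_catalog <- function(n_mirnas, n_targets, p, seed,
                           biotype = "protein_coding") {
  set.seed(seed)
  mir <- sprintf("m%02d", seq_len(n_mirnas))
  tgt <- sprintf("t%02d", seq_len(n_targets))
  grid <- expand.grid(mirna_id = mir, target_id = tgt,
                      stringsAsFactors = FALSE)
  grid <- grid[runif(nrow(grid)) < p, , drop = FALSE]
  # ensure every target keeps at least one edge
  orphan <- setdiff(tgt, grid$target_id)
  if (length(orphan)) {
    grid <- rbind(grid, data.frame(mirna_id = sample(mir, length(orphan),
                                                     replace = TRUE),
                                   target_id = orphan,
                                   stringsAsFactors = FALSE))
  }
  make_catalog(grid$mirna_id, grid$target_id, biotype = biotype)
}

# independent oracle for the upper-tail hypergeometric probability:
# explicit ratio-of-binomials enumeration with choose() (safe for small N)
hyper_tail_oracle <- function(N, K, O, x) {
  if (x == 0) return(1)
  i <- x:min(K, O)
  sum(choose(K, i) * choose(N - K, O - i)) / choose(N, O)
}

# simulate a correlated gene pair plus m independent miRNAs (the mscor null)
simulate_null_pair <- function(n, k, m) {
  z0 <- rnorm(n)
  list(a = sqrt(k) * z0 + sqrt(1 - k) * rnorm(n),
       b = sqrt(k) * z0 + sqrt(1 - k) * rnorm(n),
       M = matrix(rnorm(n * m), ncol = m))
}
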