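#' @keywords internal
"_PACKAGE"

# Biotypes handled by the pipeline; anything else in an input file is rejected.
CERNA_BIOTYPES <- c("protein_coding", "lncRNA", "pseudogene", "miRNA")
# Biotypes eligible to act as a sponge (ceRNA-B).
SPONGE_BIOTYPES <- c("protein_coding", "lncRNA", "pseudogene")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic per-stage seed derived from a master seed: stages are
# individually reproducible without sharing an RNG stream. Kept inside the
# 32-bit integer range.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587L) + 1L
}

# Canonical unordered-pair key, used when comparing predicted and true pairs.
pair_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
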