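# Internal helpers: seeded RNG streams and small numerics.

# Deterministic 31-bit hash of a string (polynomial rolling hash).
.str_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 131 + x) %% 2147483629
  as.integer(h)
}

# Derive an independent sub-seed from a master seed and a stream name, so each
# named stream (e.g. one per cell type) is unaffected by the presence of other
# streams.
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.numeric(seed) %% 2147483629 + .str_hash(as.character(name))) %% 2147483629)
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483629))
  expr
}

# sample() without the length-1 surprise.
sample_safe <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size = size, replace = replace)]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Pearson correlation that maps undefined (zero-variance) cases to 0.
cor0 <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

# Rank-based AUC for scores of positives vs negatives (probability that a
# random positive scores higher than a random negative; ties count 1/2).
rank_auc <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos)
  n2 <- length(scores_neg)
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
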