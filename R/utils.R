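# internal helpers shared across modules

# Run `expr` with a private RNG stream seeded by `seed`, restoring the caller's
# .Random.seed afterwards so package functions never disturb user RNG state.
with_private_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      suppressWarnings(rm(".Random.seed", envir = env))
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Row-standardize a voxels x subjects matrix: mean 0, sd 1 per voxel.
# Constant rows (sd = 0) are mapped to all-zero rows rather than NaN.
standardize_rows <- function(X) {
  mu <- rowMeans(X)
  Xc <- X - mu
  s <- sqrt(rowSums(Xc^2) / (ncol(X) - 1L))
  s[s < .Machine$double.eps] <- Inf
  Xc / s
}

# Rank-based AUC: probability that a positive scores above a negative,
# ties counted 1/2 (Mann-Whitney).
auc_rank <- function(scores, positive) {
  np <- sum(positive)
  nn <- sum(!positive)
  if (np == 0L || nn == 0L) abort("AUC undefined: one class absent")
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

assert_labels <- function(labels, n = NULL) {
  f <- as.factor(labels)
  if (!is.null(n) && length(f) != n)
    abort(sprintf("label length (%d) does not match subject count (%d)",
                  length(f), n))
  f <- droplevels(f)
  if (nlevels(f) < 2L) abort("labels required: at least two classes")
  if (any(table(f) < 1L)) abort("every class must be non-empty")
  f
}
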