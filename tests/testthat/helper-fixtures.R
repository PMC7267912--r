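# Shared fixture builders and independent oracles. Everything is generated in
# code at test time; no stored data.

# random dataset on a full-box grid: returns grid, X, labels
toy_data <- function(shape = c(4, 4, 3), n = 20, seed = 1, effect = NULL,
                     connectivity = 26L) {
  grid <- voxel_grid(array(TRUE, shape), connectivity = connectivity)
  withr::with_seed(seed, {
    X <- matrix(rnorm(grid$p * n), grid$p, n)
    labels <- factor(rep(c("a", "b"), length.out = n))
    if (!is.null(effect))
      X[effect$voxels, labels == "b"] <-
        X[effect$voxels, labels == "b"] + effect$amplitude
    list(grid = grid, X = X, labels = labels)
  })
}

# a spectral_cache-shaped object with prescribed per-voxel scores, for tests
# that exercise score arithmetic directly
mock_cache <- function(b, w) {
  structure(list(b = b, w = w, p = length(b), n = NA_integer_,
                 X = NULL, affinity = NULL, standardized = FALSE),
            class = "spectral_cache")
}

# brute-force neighbourhood scan: all in-space voxels adjacent to the member
# set under the grid's connectivity, from raw coordinates
brute_neighbors <- function(grid, members, excluded = integer(0)) {
  res <- integer(0)
  for (v in seq_len(grid$p)) {
    if (v %in% members || v %in% excluded) next
    d <- abs(grid$coords[rep(v, length(members)), , drop = FALSE] -
               grid$coords[members, , drop = FALSE])
    adj <- switch(as.character(grid$connectivity),
                  "6"  = rowSums(d) == 1,
                  "18" = apply(d, 1, max) == 1 & rowSums(d) <= 2,
                  "26" = apply(d, 1, max) == 1)
    if (any(adj)) res <- c(res, v)
  }
  res
}

# quadratic form via the explicit pairwise identity
# x' (D - S) x = 1/2 * sum_jk S[j,k] (x_j - x_k)^2
brute_quadform <- function(x, S) {
  n <- length(x)
  acc <- 0
  for (j in seq_len(n)) for (k in seq_len(n))
    acc <- acc + S[j, k] * (x[j] - x[k])^2
  acc / 2
}

# independent reimplementation of the pruning rules with no caches: fresh MI
# and fresh explicit scores at every step
brute_prune <- function(members, protected, X, affinity, bins = 8L) {
  score <- function(m) {
    Xm <- X[m, , drop = FALSE]
    B <- sum(diag(Xm %*% affinity$L_b %*% t(Xm)))
    W <- sum(diag(Xm %*% affinity$L_w %*% t(Xm)))
    if (W < 1e-12) Inf else B / W
  }
  members <- sort(members)
  removed <- integer(0)
  repeat {
    if (length(members) < 3L) break
    free <- setdiff(members, protected)
    if (!length(free)) break
    J <- vapply(free, function(v) {
      mean(vapply(setdiff(members, v), function(k)
        mutual_information(X[v, ], X[k, ], bins), numeric(1)))
    }, numeric(1))
    s0 <- score(members)
    did <- FALSE
    for (v in free[order(-J, free)]) {
      s1 <- score(setdiff(members, v))
      ok <- if (is.infinite(s0)) is.infinite(s1) else
        s1 >= s0 - 1e-12 * max(1, abs(s0))
      if (ok) {
        members <- setdiff(members, v); removed <- c(removed, v); did <- TRUE
        break
      }
    }
    if (!did) break
  }
  list(members = members, removed = sort(removed))
}
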