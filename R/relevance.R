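#' Precompute per-voxel spectral scores
#'
#' The trace-ratio score of any voxel set decomposes into sums of per-voxel
#' quadratic forms: `b_i = x_i' L_b x_i` and `w_i = x_i' L_w x_i`, where `x_i`
#' is voxel `i`'s row of the activation matrix. Both are computed once, before
#' the search starts; every later cluster score is a ratio of cached sums.
#'
#' @param X Voxels x subjects activation matrix.
#' @param affinity An [build_affinity()] model (or labels, which are passed to
#'   `build_affinity()`).
#' @param standardize Standardize each voxel (zero mean, unit variance across
#'   subjects) before computing the quadratic forms (default TRUE). The trace
#'   ratio is scale-sensitive per voxel; standardization makes scores
#'   comparable across voxels.
#' @return A `spectral_cache` with fields `b`, `w` (length-p numeric), the
#'   (standardized) matrix `X` and the `affinity` model.
#' @export
spectral_cache <- function(X, affinity, standardize = TRUE) {
  if (!inherits(affinity, "affinity_model")) affinity <- build_affinity(affinity)
  X <- as.matrix(X)
  if (ncol(X) != affinity$n)
    abort(sprintf("X has %d columns but the affinity model has %d subjects",
                  ncol(X), affinity$n))
  Xs <- if (standardize) standardize_rows(X) else X
  b <- rowSums((Xs %*% affinity$L_b) * Xs)
  w <- rowSums((Xs %*% affinity$L_w) * Xs)
  # quadratic forms of PSD matrices; clamp the numerical dust below zero
  b <- pmax(b, 0)
  w <- pmax(w, 0)
  structure(list(b = b, w = w, p = nrow(Xs), n = ncol(Xs),
                 X = Xs, affinity = affinity, standardized = standardize),
            class = "spectral_cache")
}

#' @export
print.spectral_cache <- function(x, ...) {
  cat(sprintf("<spectral_cache> %d voxels, %d subjects (%s)\n",
              x$p, x$n, x$affinity$mode))
  invisible(x)
}

#' Trace-ratio relevance score of a voxel set
#'
#' `sum(b[members]) / sum(w[members])`, which equals the trace ratio
#' `tr(W' X L_b X' W) / tr(W' X L_w X' W)` for the 0/1 selection matrix `W`
#' of the member set (never materialized). `method = "explicit"` computes the
#' score by materializing the selection and taking traces; it is the slow
#' independent route used for verification.
#'
#' A within-class scatter below `1e-12` is degenerate (e.g. a cluster of
#' voxels constant within every class); the score is then `+Inf` with a
#' warning, treating the cluster as maximally informative.
#'
#' @param cache A [spectral_cache()].
#' @param members Non-empty integer vector of voxel linear indices.
#' @param method `"cached"` (default) or `"explicit"`.
#' @return Nonnegative score (possibly `Inf`).
#' @export
cluster_score <- function(cache, members, method = c("cached", "explicit")) {
  method <- match.arg(method)
  members <- as.integer(members)
  if (length(members) == 0L) abort("members must be non-empty")
  if (method == "cached") {
    B <- sum(cache$b[members]); W <- sum(cache$w[members])
  } else {
    Xm <- cache$X[members, , drop = FALSE]
    B <- sum(diag(Xm %*% cache$affinity$L_b %*% t(Xm)))
    W <- sum(diag(Xm %*% cache$affinity$L_w %*% t(Xm)))
    B <- max(B, 0); W <- max(W, 0)
  }
  if (W < 1e-12) {
    warn("degenerate within-class scatter; returning +Inf relevance")
    return(Inf)
  }
  B / W
}

#' Admission rule for an arriving voxel
#'
#' Computes `dif = score(members + candidate) - score(members)`; the candidate
#' is admitted iff `dif > 0` (strict: ties reject, so score-neutral growth is
#' impossible and every expansion strictly increases the cluster score).
#'
#' @param cache A [spectral_cache()].
#' @param members Current member set (non-empty).
#' @param candidate A single voxel index not in `members`.
#' @return List with `admit` (logical) and `dif` (score delta).
#' @export
admission_test <- function(cache, members, candidate) {
  candidate <- as.integer(candidate)
  if (length(candidate) != 1L) abort("candidate must be a single voxel")
  if (candidate %in% members) abort("candidate already in the cluster")
  s0 <- cluster_score(cache, members)
  s1 <- cluster_score(cache, c(members, candidate))
  dif <- if (is.infinite(s0) && is.infinite(s1)) 0 else s1 - s0
  list(admit = isTRUE(dif > 0), dif = dif)
}
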