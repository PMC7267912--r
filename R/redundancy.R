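# equal-frequency (quantile) discretization; ties may merge bins, a constant
# vector collapses to a single bin
bin_equal_freq <- function(x, bins) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                        names = FALSE, type = 7))
  if (length(br) < 2L) return(rep(1L, length(x)))
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Mutual information between two voxels
#'
#' Both vectors are discretized by equal-frequency binning into `bins` levels
#' and the mutual information of the joint histogram is returned in nats
#' (`0 log 0 := 0`). A constant vector occupies a single bin and yields 0.
#'
#' @param x,y Per-subject activation values of the two voxels; equal lengths,
#'   at least `2 * bins`.
#' @param bins Discretization level (default 8).
#' @return Nonnegative mutual information in nats.
#' @examples
#' x <- rnorm(64)
#' mutual_information(x, x, bins = 4)  # = entropy of the binned marginal
#' @export
mutual_information <- function(x, y, bins = 8L) {
  bins <- as.integer(bins)
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2L * bins)
    abort(sprintf("need at least 2*bins = %d observations", 2L * bins))
  mi_binned(bin_equal_freq(x, bins), bin_equal_freq(y, bins), length(x))
}

mi_binned <- function(bx, by, n) {
  nbx <- max(bx); nby <- max(by)
  joint <- tabulate(bx + nbx * (by - 1L), nbx * nby) / n
  px <- tabulate(bx, nbx) / n
  py <- tabulate(by, nby) / n
  pp <- outer(px, py)
  nz <- joint > 0
  max(sum(joint[nz] * log(joint[nz] / pp[nz])), 0)
}

#' Lazily-filled pairwise mutual-information cache
#'
#' Voxel values are discretized once; pairwise MI entries are computed only
#' for pairs actually requested during the search and stored in a hash table,
#' so the interaction matrix stays sparse (the search only ever needs a
#' voxel's interaction with members of its current cluster, not with the whole
#' search space).
#'
#' @param X Voxels x subjects activation matrix.
#' @param bins Discretization level (default 8). When there are fewer than
#'   `2 * bins` subjects the level is lowered to `floor(n/2)` (minimum 2) so
#'   every bin can hold at least two observations.
#' @return A `redundancy_cache` environment.
#' @export
redundancy_cache <- function(X, bins = 8L) {
  X <- as.matrix(X)
  bins <- as.integer(bins)
  if (ncol(X) < 4L)
    abort("need at least 4 subjects for mutual-information binning")
  bins <- min(bins, max(2L, ncol(X) %/% 2L))
  binned <- t(apply(X, 1L, bin_equal_freq, bins = bins))
  e <- new.env(parent = emptyenv())
  e$binned <- binned
  e$bins <- bins
  e$n <- ncol(X)
  e$mi <- new.env(parent = emptyenv(), size = 4096L)
  class(e) <- "redundancy_cache"
  e
}

#' @export
print.redundancy_cache <- function(x, ...) {
  cat(sprintf("<redundancy_cache> %d voxels, %d bins, %d pairs computed\n",
              nrow(x$binned), x$bins, length(ls(x$mi))))
  invisible(x)
}

# compute-once / look-up-thereafter pairwise MI
mi_pair <- function(cache, i, j) {
  if (i == j) abort("mutual information of a voxel with itself is its entropy; pairs must differ")
  key <- if (i < j) paste0(i, ":", j) else paste0(j, ":", i)
  val <- get0(key, envir = cache$mi, inherits = FALSE)
  if (!is.null(val)) return(val)
  val <- mi_binned(cache$binned[i, ], cache$binned[j, ], cache$n)
  assign(key, val, envir = cache$mi)
  val
}

#' Export the computed interaction pairs
#'
#' @param cache A [redundancy_cache()].
#' @return Tibble `(voxel_i, voxel_j, mi)` of all pairs computed so far
#'   (`voxel_i < voxel_j`).
#' @export
mi_table <- function(cache) {
  keys <- ls(cache$mi)
  if (length(keys) == 0L)
    return(tibble(voxel_i = integer(0), voxel_j = integer(0), mi = numeric(0)))
  ij <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  out <- tibble(voxel_i = as.integer(ij[, 1]), voxel_j = as.integer(ij[, 2]),
                mi = vapply(keys, get, numeric(1), envir = cache$mi))
  dplyr::arrange(out, .data$voxel_i, .data$voxel_j)
}

#' Group redundancy score of a cluster member
#'
#' The redundancy of `target` within `members` is its mean mutual information
#' with the other members: `J = mean_k MI(target, k)`. Large `J` means the
#' voxel carries little information beyond what the rest of the cluster
#' already has.
#'
#' @param cache A [redundancy_cache()].
#' @param members Cluster member indices (at least 2).
#' @param target A member of `members`.
#' @return Nonnegative redundancy score in nats.
#' @export
redundancy_score <- function(cache, members, target) {
  members <- as.integer(members); target <- as.integer(target)
  if (length(members) < 2L) abort("redundancy undefined for singleton")
  if (!target %in% members) abort("target must belong to the cluster")
  others <- members[members != target]
  mean(vapply(others, function(k) mi_pair(cache, target, k), numeric(1)))
}

#' Prune redundant voxels from a cluster
#'
#' Reference (pure-R) implementation of the pruning step. Members are scanned
#' in order of decreasing redundancy `J` (ties broken by lowest linear index)
#' and a member is removed when (a) it is not protected, (b) at least two
#' members remain afterwards, and (c) removal does not decrease the cluster's
#' relevance score. After each removal the scan restarts with recomputed `J`;
#' pruning stops when no removal qualifies. There is no magic threshold: the
#' relevance gate alone decides, so the cluster score never decreases.
#'
#' @param members Cluster member indices.
#' @param protected Members that may not be removed (the origin voxel and the
#'   voxels admitted by the immediately preceding expansion).
#' @param scache A [spectral_cache()].
#' @param rcache A [redundancy_cache()].
#' @return List with sorted `members` (the pruned cluster) and `removed`.
#' @export
prune_cluster <- function(members, protected, scache, rcache) {
  members <- sort(as.integer(members))
  protected <- as.integer(protected)
  if (!all(protected %in% members)) abort("protected must be a subset of members")
  removed <- integer(0)
  # relative tolerance: removal of an exact duplicate must count as score-neutral
  tol <- function(s) 1e-12 * max(1, abs(s))
  repeat {
    if (length(members) < 3L) break  # removal must leave >= 2 members
    free <- setdiff(members, protected)
    if (length(free) == 0L) break
    J <- vapply(free, function(v) redundancy_score(rcache, members, v),
                numeric(1))
    ord <- free[order(-J, free)]
    s0 <- cluster_score(scache, members)
    did <- FALSE
    for (v in ord) {
      s1 <- cluster_score(scache, setdiff(members, v))
      ok <- if (is.infinite(s0)) is.infinite(s1) else s1 >= s0 - tol(s0)
      if (ok) {
        members <- setdiff(members, v)
        removed <- c(removed, v)
        did <- TRUE
        break
      }
    }
    if (!did) break
  }
  list(members = members, removed = sort(removed))
}
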