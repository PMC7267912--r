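#' Grow an information cluster from one origin voxel
#'
#' Implements the per-origin search: the origin's immediate neighbours are
#' tested one-by-one with the admission rule and every passing neighbour joins
#' jointly; thereafter expansion (over the neighbourhood of the whole cluster)
#' and pruning alternate until an expansion admits nothing. Two one-phase
#' exclusion windows prevent oscillation: voxels removed by a prune are not
#' re-examined by the immediately following expansion, and voxels admitted by
#' an expansion are protected from the immediately following prune. The origin
#' is permanently protected.
#'
#' @param origin In-space voxel linear index.
#' @param grid A [voxel_grid()].
#' @param scache A [spectral_cache()].
#' @param rcache A [redundancy_cache()] (shared across origins during a full
#'   run).
#' @param max_steps Safety cap on expansion+prune steps (default `4 * p`).
#' @param engine `"cpp"` (default) or `"r"`, the slow readable reference
#'   implementation used for verification.
#' @return An `information_cluster`: `origin`, `members` (sorted), `relevance`,
#'   `steps`, `capped`, `connected`.
#' @export
grow_cluster <- function(origin, grid, scache, rcache,
                         max_steps = 4L * grid$p, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  origin <- as.integer(origin)
  if (origin < 1L || origin > grid$p) abort("origin outside the search space")
  if (engine == "r") {
    res <- grow_cluster_ref(origin, grid, scache, rcache, max_steps)
  } else {
    eng <- .ics_engine(scache$X, scache$affinity$L_b, scache$affinity$L_w,
                       rcache$binned, apply(rcache$binned, 1L, max),
                       grid$adj, origin, TRUE, as.integer(max_steps), FALSE)
    res <- list(members = eng$members[[1]], relevance = eng$relevance[[1]],
                steps = eng$steps[[1]], capped = eng$capped[[1]])
  }
  structure(
    list(origin = origin, members = res$members, relevance = res$relevance,
         steps = res$steps, capped = res$capped,
         connected = is_connected_set(grid, res$members)),
    class = "information_cluster")
}

#' @export
print.information_cluster <- function(x, ...) {
  cat(sprintf("<information_cluster> origin %d, %d members, relevance %.4g%s\n",
              x$origin, length(x$members), x$relevance,
              if (x$connected) "" else " (disconnected)"))
  invisible(x)
}

# Pure-R reference engine: same admission/prune/anti-loop rules as the C++
# engine, written for readability. Used as the independent route in tests.
grow_cluster_ref <- function(origin, grid, scache, rcache, max_steps) {
  members <- origin
  last_removed <- integer(0)
  steps <- 0L
  capped <- FALSE
  repeat {
    cand <- cluster_neighbors(grid, members, excluded = last_removed)
    s0 <- cluster_score(scache, members)
    admit <- cand[vapply(cand, function(cc)
      cluster_score(scache, c(members, cc)) > s0, logical(1))]
    steps <- steps + 1L
    if (length(admit) == 0L) break
    members <- sort(c(members, admit))
    if (steps >= max_steps) { capped <- TRUE; break }
    pr <- prune_cluster(members, protected = c(origin, admit), scache, rcache)
    members <- pr$members
    last_removed <- pr$removed
    steps <- steps + 1L
    if (steps >= max_steps) { capped <- TRUE; break }
  }
  list(members = members, relevance = cluster_score(scache, members),
       steps = steps, capped = capped)
}

#' Run the full information cluster search
#'
#' Grows one information cluster from every in-space voxel (in linear-index
#' order). The per-voxel spectral scores are computed once before the loop and
#' the pairwise mutual-information table is filled lazily and shared across
#' origins, so repeated visits to the same voxels cost a hash lookup. The
#' search itself contains no randomness: identical inputs give identical
#' output.
#'
#' @param X Voxels x subjects activation matrix (rows aligned with the grid's
#'   linear indices).
#' @param labels Per-subject class labels, or an [build_affinity()] model
#'   (pass [build_affinity_unsupervised()] output for label-free mapping).
#' @param grid A [voxel_grid()] with `p == nrow(X)`.
#' @param bins Mutual-information discretization level (default 8).
#' @param standardize Standardize each voxel across subjects first (default
#'   TRUE).
#' @param memoize Use the memoized caches (default TRUE). `FALSE` recomputes
#'   every spectral quadratic form and every MI value on demand; results are
#'   identical, only slower (kept as a verification mode).
#' @param max_steps Per-origin safety cap (default `4 * p`).
#' @param verbose Print progress every 100 origins.
#' @return An `ics_result`: tibble `clusters` with one row per origin
#'   (`origin`, `x`, `y`, `z`, `size`, `relevance`, `connected`, `steps`,
#'   `capped`, `members` list-column), plus `config`, `mi_pairs` (the computed
#'   interaction pairs) and the `grid`.
#' @examples
#' d <- generate_dataset(synthetic_spec(shape = c(4, 4, 3),
#'   n_per_class = c(20, 20), planted = list(planted_block(c(4, 4, 3), 1:2, 1:2, 1:2, 1.5)),
#'   seed = 1))
#' fit <- run_ics(d$X, d$labels, d$grid)
#' fit
#' @export
run_ics <- function(X, labels, grid, bins = 8L, standardize = TRUE,
                    memoize = TRUE, max_steps = 4L * grid$p, verbose = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) != grid$p)
    abort(sprintf("X has %d rows but the grid has %d in-space voxels",
                  nrow(X), grid$p))
  affinity <- if (inherits(labels, "affinity_model")) labels else
    build_affinity(assert_labels(labels, ncol(X)))
  scache <- spectral_cache(X, affinity, standardize = standardize)
  rcache <- redundancy_cache(X, bins = bins)

  eng <- .ics_engine(scache$X, affinity$L_b, affinity$L_w,
                     rcache$binned, apply(rcache$binned, 1L, max),
                     grid$adj, seq_len(grid$p), isTRUE(memoize),
                     as.integer(max_steps), isTRUE(verbose))

  clusters <- tibble(
    origin = seq_len(grid$p),
    x = grid$coords[, 1], y = grid$coords[, 2], z = grid$coords[, 3],
    size = lengths(eng$members),
    relevance = eng$relevance,
    connected = vapply(eng$members, is_connected_set, logical(1), grid = grid),
    steps = eng$steps,
    capped = eng$capped,
    members = eng$members)

  structure(
    list(clusters = clusters,
         config = list(bins = as.integer(bins), standardize = standardize,
                       memoize = memoize, max_steps = as.integer(max_steps),
                       connectivity = grid$connectivity, mode = affinity$mode),
         mi_pairs = eng$mi_pairs,
         grid = grid),
    class = "ics_result")
}

#' @export
print.ics_result <- function(x, ...) {
  cl <- x$clusters
  cat(sprintf("<ics_result> %d clusters (one per origin)\n", nrow(cl)))
  cat(sprintf("  sizes: median %d, max %d; whole-space clusters: %d\n",
              as.integer(median(cl$size)), max(cl$size),
              sum(cl$size == x$grid$p)))
  cat(sprintf("  MI pairs computed: %d of %d possible (%.1f%%)\n",
              nrow(x$mi_pairs), x$grid$p * (x$grid$p - 1) / 2,
              100 * nrow(x$mi_pairs) / (x$grid$p * (x$grid$p - 1) / 2)))
  if ("information" %in% names(cl))
    cat(sprintf("  information: mean %.3f, max %.3f\n",
                mean(cl$information), max(cl$information)))
  invisible(x)
}

#' @rdname run_ics
#' @param x An `ics_result`.
#' @param ... Unused.
#' @export
tidy.ics_result <- function(x, ...) {
  dplyr::select(x$clusters, -"members")
}

#' @rdname run_ics
#' @export
glance.ics_result <- function(x, ...) {
  cl <- x$clusters
  tibble(
    n_clusters = nrow(cl),
    median_size = median(cl$size),
    max_size = max(cl$size),
    frac_whole_space = mean(cl$size == x$grid$p),
    frac_singleton = mean(cl$size == 1L),
    mean_relevance = mean(cl$relevance[is.finite(cl$relevance)]),
    mi_pairs_computed = nrow(x$mi_pairs),
    mi_pair_fraction = nrow(x$mi_pairs) / (x$grid$p * (x$grid$p - 1) / 2))
}
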