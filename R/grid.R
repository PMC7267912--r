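#' Build a voxel grid over a search-space mask
#'
#' Defines the 3D search space the cluster search operates on: which voxels
#' are inside the mask, their linear indexing, and the neighbourhood relation.
#' Linear indices `1..p` are assigned in array (column-major) coordinate
#' order; this order is also the deterministic tie-break used throughout the
#' search.
#'
#' @param mask A 3D array (logical or numeric; any nonzero voxel is in-space)
#'   or the path to a NIfTI file containing such a volume.
#' @param connectivity Neighbourhood definition: 6 (faces), 18 (faces+edges)
#'   or 26 (faces+edges+corners, the default).
#' @return A `voxel_grid` object: fields `shape`, `in_space` (logical array),
#'   `lin` (integer array mapping coordinates to linear index, NA outside),
#'   `coords` (p x 3 integer matrix, 1-based), `adj` (adjacency list of
#'   in-space linear indices), `connectivity`, `p`, and -- when the mask came
#'   from a file -- `ref` (the NIfTI header, preserved so outputs can be
#'   written back in the same space).
#' @examples
#' g <- voxel_grid(array(TRUE, c(3, 3, 3)), connectivity = 6)
#' g$p
#' length(g$adj[[14]])  # centre voxel has 6 face neighbours
#' @export
voxel_grid <- function(mask, connectivity = 26L) {
  ref <- NULL
  if (is.character(mask)) {
    ref <- RNifti::readNifti(mask)
    mask <- as.array(ref)
    if (length(dim(mask)) == 4L && dim(mask)[4] == 1L)
      mask <- array(mask, dim(mask)[1:3])
  }
  if (length(dim(mask)) != 3L) abort("mask must be a 3D volume")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    abort("connectivity must be one of 6, 18, 26")
  in_space <- array(as.logical(mask != 0), dim(mask))
  in_space[is.na(in_space)] <- FALSE
  p <- sum(in_space)
  if (p == 0L) abort("empty search space: mask has no nonzero voxel")

  shape <- dim(in_space)
  lin <- array(NA_integer_, shape)
  lin[in_space] <- seq_len(p)
  coords <- arrayInd(which(in_space), shape)

  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ord <- rowSums(abs(off))
  off <- off[ord > 0 & ord <= switch(as.character(connectivity),
                                     "6" = 1L, "18" = 2L, "26" = 3L), ,
             drop = FALSE]

  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(off))) {
    nb <- coords + matrix(off[r, ], nrow = p, ncol = 3, byrow = TRUE)
    ok <- nb[, 1] >= 1L & nb[, 1] <= shape[1] &
          nb[, 2] >= 1L & nb[, 2] <= shape[2] &
          nb[, 3] >= 1L & nb[, 3] <= shape[3]
    tgt <- rep(NA_integer_, p)
    tgt[ok] <- lin[nb[ok, , drop = FALSE]]
    keep <- !is.na(tgt)
    from <- c(from, which(keep))
    to <- c(to, tgt[keep])
  }
  adj <- split(to, factor(from, levels = seq_len(p)))
  adj <- lapply(adj, function(v) sort(as.integer(v)))
  names(adj) <- NULL

  structure(
    list(shape = shape, in_space = in_space, lin = lin,
         coords = coords, connectivity = connectivity,
         adj = adj, p = p, ref = ref),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d, %d in-space voxels, %d-connectivity\n",
              x$shape[1], x$shape[2], x$shape[3], x$p, x$connectivity))
  invisible(x)
}

#' @export
tidy.voxel_grid <- function(x, ...) {
  tibble(voxel = seq_len(x$p),
         x = x$coords[, 1], y = x$coords[, 2], z = x$coords[, 3])
}

#' Neighbours of a cluster
#'
#' All in-space voxels adjacent to at least one member of `members`, minus the
#' members themselves and minus an exclusion set (used by the search for the
#' anti-loop rule: voxels removed by the immediately preceding prune are not
#' re-examined in the following expansion).
#'
#' @param grid A [voxel_grid()].
#' @param members Integer vector of member linear indices.
#' @param excluded Integer vector of linear indices to leave out.
#' @return Sorted integer vector of candidate linear indices.
#' @export
cluster_neighbors <- function(grid, members, excluded = integer(0)) {
  stopifnot(inherits(grid, "voxel_grid"))
  members <- as.integer(members)
  if (length(members) == 0L) return(integer(0))
  if (any(members < 1L | members > grid$p))
    abort("members outside the search space")
  nb <- unique(unlist(grid$adj[members], use.names = FALSE))
  sort(setdiff(nb, c(members, as.integer(excluded))))
}

# connectivity check used to flag clusters that pruning disconnected
is_connected_set <- function(grid, members) {
  m <- as.integer(members)
  if (length(m) <= 1L) return(TRUE)
  inset <- logical(grid$p); inset[m] <- TRUE
  seen <- logical(grid$p)
  stack <- m[1]; seen[m[1]] <- TRUE; count <- 1L
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (u in grid$adj[[v]]) {
      if (inset[u] && !seen[u]) {
        seen[u] <- TRUE; count <- count + 1L
        stack <- c(stack, u)
      }
    }
  }
  count == length(m)
}

# Euclidean ball membership used by the searchlight: offsets with |d| <= radius
sphere_offsets <- function(radius) {
  r <- as.integer(radius)
  if (r < 1L) abort("radius must be >= 1")
  g <- as.matrix(expand.grid(di = -r:r, dj = -r:r, dk = -r:r))
  g[rowSums(g^2) <= r^2 & rowSums(abs(g)) > 0, , drop = FALSE]
}
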