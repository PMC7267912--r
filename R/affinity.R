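#' Class-affinity matrices and their Laplacians
#'
#' Builds the supervised (Fisher-score) affinity model over subjects. With
#' `n` subjects and class sizes `n_l`, the between-class affinity is
#' `S_b[i,j] = 1/n - 1/n_l` when `i` and `j` share class `l` (including
#' `i = j`) and `1/n` otherwise; the within-class affinity is
#' `S_w[i,j] = 1/n_l` for same-class pairs and 0 otherwise. Laplacians use the
#' row-sum degree, `L = D - S`; rows of `S_b` sum to 0 and rows of `S_w` sum
#' to 1, so `L_b = -S_b` and `L_w = I - S_w`, both positive semidefinite.
#'
#' @param labels Per-subject class labels (factor or coercible), at least two
#'   non-empty classes.
#' @return An `affinity_model`: `S_b`, `S_w`, `L_b`, `L_w`, `labels` (factor),
#'   `n`, `mode`.
#' @examples
#' m <- build_affinity(c("A", "A", "B", "B"))
#' m$S_b[1, 2]  # 1/4 - 1/2 = -0.25
#' m$S_w[1, 2]  # 1/2
#' @export
build_affinity <- function(labels) {
  f <- assert_labels(labels)
  n <- length(f)
  nl <- as.numeric(table(f))[as.integer(f)]  # class size of each subject
  same <- outer(as.integer(f), as.integer(f), "==")
  S_w <- ifelse(same, 1 / nl, 0)            # symmetric: same class => same n_l
  S_b <- ifelse(same, 1 / n - 1 / nl, 1 / n)
  new_affinity(S_b, S_w, mode = "fisher_supervised", labels = f)
}

#' Unsupervised affinity model (Laplacian-score construction)
#'
#' When class labels are unavailable the two affinity graphs are built from
#' the data instead: the within graph is a symmetrised k-nearest-neighbour
#' graph over subjects with heat-kernel weights
#' `exp(-d_ij^2 / (2 * kernel_width^2))`, and the between graph is the
#' complete graph with uniform weight `1/n`.
#'
#' @param X Voxels x subjects activation matrix.
#' @param k_neighbors Number of nearest neighbours (default 5).
#' @param kernel_width Heat-kernel bandwidth; defaults to the median pairwise
#'   subject distance.
#' @return An `affinity_model` with `mode = "laplacian_unsupervised"`.
#' @export
build_affinity_unsupervised <- function(X, k_neighbors = 5L, kernel_width = NULL) {
  n <- ncol(X)
  k <- as.integer(k_neighbors)
  if (n < k + 1L) abort("need at least k_neighbors + 1 subjects")
  d <- as.matrix(dist(t(X)))
  if (is.null(kernel_width)) {
    kernel_width <- median(d[upper.tri(d)])
    if (!is.finite(kernel_width) || kernel_width <= 0) kernel_width <- 1
  }
  if (!is.finite(kernel_width) || kernel_width <= 0)
    abort("kernel_width must be a finite positive number")
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[-1][seq_len(k)]
    W[i, nb] <- exp(-d[i, nb]^2 / (2 * kernel_width^2))
  }
  S_w <- pmax(W, t(W))                       # symmetrize: edge if kNN either way
  S_b <- matrix(1 / n, n, n); diag(S_b) <- 0 # self-loops cancel in L anyway
  new_affinity(S_b, S_w, mode = "laplacian_unsupervised", labels = NULL,
               params = list(k_neighbors = k, kernel_width = kernel_width))
}

new_affinity <- function(S_b, S_w, mode, labels, params = NULL) {
  L_b <- diag(rowSums(S_b)) - S_b
  L_w <- diag(rowSums(S_w)) - S_w
  structure(
    list(S_b = S_b, S_w = S_w, L_b = L_b, L_w = L_w,
         mode = mode, labels = labels, n = nrow(S_b), params = params),
    class = "affinity_model")
}

#' @export
print.affinity_model <- function(x, ...) {
  cat(sprintf("<affinity_model> %s, %d subjects", x$mode, x$n))
  if (!is.null(x$labels))
    cat(sprintf(", classes: %s",
                paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                      collapse = ", ")))
  cat("\n")
  invisible(x)
}
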