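#' Hemodynamic-like temporal envelope
#'
#' A canonical double-gamma response curve (peak ~5 s, undershoot ~15 s)
#' sampled at `t_points` over `duration` seconds and peak-normalized to 1, so
#' planted amplitudes stay interpretable in baseline-SD units. This is the
#' default fade-in/fade-out weighting of planted spatial patterns.
#'
#' @param t_points Number of time points.
#' @param duration Seconds spanned by the sampling grid (default 32, the
#'   support of a single evoked response).
#' @return Numeric vector of length `t_points` with `max == 1`.
#' @export
hrf_envelope <- function(t_points, duration = 32) {
  t <- seq(0, duration, length.out = t_points)
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Specification of a synthetic BOLD dataset
#'
#' Describes a two-condition population with Gaussian voxel time courses,
#' adjacent-voxel noise correlation, and condition-locked spatial patterns
#' weighted by a hemodynamic-like envelope. Defaults follow the study
#' conditions the generator emulates: a population of 1,000 subjects split
#' evenly between conditions, 120 time points, unit per-timepoint noise SD.
#'
#' @param shape Grid shape (3 integers); all voxels are in-space unless `mask`
#'   is given.
#' @param n_per_class Subjects per class `c(control, case)` (default 500/500).
#' @param t_points Time points per subject (default 120).
#' @param baseline_mean Mean signal level in arbitrary BOLD units (default 1);
#'   nonzero so that proportional signal loss (atrophy) is expressible.
#' @param baseline_sd Per-timepoint noise SD (default 1).
#' @param spatial_rho Target Pearson correlation of adjacent-voxel noise, in
#'   `[0, 1/sqrt(6))` (default 0.3); induced by mixing each voxel's series
#'   with the mean of its 6-connected neighbours' series at an analytically
#'   calibrated weight.
#' @param planted List of planted patterns, each a list with integer `voxels`
#'   and `amplitude` (in units of `baseline_sd`); see [planted_block()]. The
#'   pattern `amplitude * envelope(t)` is added to case subjects only.
#' @param envelope Temporal weighting curve (length `t_points`, peak 1);
#'   default [hrf_envelope()].
#' @param mask Optional 3D logical array restricting the search space.
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(shape = c(5, 5, 4), n_per_class = c(500, 500),
                           t_points = 120, baseline_mean = 1, baseline_sd = 1,
                           spatial_rho = 0.3, planted = list(),
                           envelope = NULL, mask = NULL, seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), length(n_per_class) == 2L)
  if (baseline_sd <= 0) abort("baseline_sd must be positive")
  if (spatial_rho < 0 || spatial_rho >= 1) abort("spatial_rho must be in [0, 1)")
  if (spatial_rho > 0 && spatial_rho^2 * 6 > 1)
    abort(sprintf(
      "spatial_rho above the neighbour-mean mixing range (max %.3f under 6-connectivity)",
      1 / sqrt(6)))
  if (is.null(envelope)) envelope <- hrf_envelope(t_points)
  if (length(envelope) != t_points) abort("envelope length must equal t_points")
  envelope <- envelope / max(envelope)  # amplitudes are in baseline-SD units
  if (length(planted) && !is.null(planted$voxels)) planted <- list(planted)
  for (pl in planted) {
    if (is.null(pl$voxels) || is.null(pl$amplitude) || !is.finite(pl$amplitude))
      abort("each planted entry needs `voxels` and a finite `amplitude`")
  }
  structure(list(shape = shape, n_per_class = as.integer(n_per_class),
                 t_points = as.integer(t_points),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 spatial_rho = spatial_rho, planted = planted,
                 envelope = envelope, mask = mask, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Preset search-space sizes
#'
#' Grid shapes matching the four synthetic search-space sizes used for
#' benchmarking: 100, 500, 10,000 and 30,000 voxels.
#'
#' @param name One of `"p100"`, `"p500"`, `"p10k"`, `"p30k"`.
#' @param ... Overrides passed to [synthetic_spec()].
#' @export
synthetic_preset <- function(name = c("p100", "p500", "p10k", "p30k"), ...) {
  shape <- switch(match.arg(name),
                  p100 = c(5L, 5L, 4L), p500 = c(10L, 10L, 5L),
                  p10k = c(25L, 20L, 20L), p30k = c(30L, 50L, 20L))
  synthetic_spec(shape = shape, ...)
}

#' A rectangular planted pattern
#'
#' Convenience constructor: the set of in-space voxels of an axis-aligned
#' block, as linear indices of the full-box grid of the given shape.
#'
#' @param shape Grid shape.
#' @param ix,iy,iz Integer coordinate ranges of the block.
#' @param amplitude Effect size in baseline-SD units.
#' @export
planted_block <- function(shape, ix, iy, iz, amplitude) {
  lin <- array(seq_len(prod(shape)), shape)
  list(voxels = as.integer(lin[ix, iy, iz]), amplitude = amplitude)
}

# Mixing weight for z_i = x_i + lam * mean(x_neighbours(i)). For an edge (i,j)
# with degrees k_i, k_j (no shared neighbours under 6-connectivity):
#   cor(z_i, z_j) = lam*(1/k_i + 1/k_j) / sqrt((1 + lam^2/k_i)(1 + lam^2/k_j))
# The weight is solved so that the MEAN correlation over the grid's actual
# edges hits the target, which keeps boundary voxels (lower degree, higher
# local correlation) from inflating the average.
mixing_weight <- function(rho, grid6 = NULL) {
  if (rho <= 0) return(0)
  if (is.null(grid6)) return((1 - sqrt(1 - rho^2 * 6)) / rho)  # interior-only
  deg <- lengths(grid6$adj)
  from <- rep.int(seq_len(grid6$p), deg)
  to <- unlist(grid6$adj, use.names = FALSE)
  ki <- deg[from[to > from]]; kj <- deg[to[to > from]]
  mean_rho <- function(lam)
    mean(lam * (1 / ki + 1 / kj) /
           sqrt((1 + lam^2 / ki) * (1 + lam^2 / kj))) - rho
  upper <- sqrt(min(deg))  # correlation is increasing in lam on (0, sqrt(k_min))
  if (mean_rho(upper) < 0)
    abort("spatial_rho is not reachable by neighbour-mean mixing on this grid")
  stats::uniroot(mean_rho, c(0, upper), tol = 1e-10)$root
}

# sparse row-normalized 6-connectivity neighbour-mean operator for the grid
neighbor_mean_op <- function(grid6) {
  deg <- lengths(grid6$adj)
  from <- rep.int(seq_len(grid6$p), deg)
  to <- unlist(grid6$adj, use.names = FALSE)
  Matrix::sparseMatrix(i = from, j = to, x = 1 / pmax(deg[from], 1L),
                       dims = c(grid6$p, grid6$p))
}

# one subject's voxels x time course (noise + planted patterns + baseline)
subject_timecourse <- function(spec, grid, M, lam, is_case) {
  E <- matrix(rnorm(grid$p * spec$t_points, sd = spec$baseline_sd),
              grid$p, spec$t_points)
  Z <- if (lam > 0) E + lam * as.matrix(M %*% E) else E
  if (is_case && length(spec$planted)) {
    for (pl in spec$planted) {
      Z[pl$voxels, ] <- Z[pl$voxels, ] +
        rep(pl$amplitude * spec$baseline_sd * spec$envelope,
            each = length(pl$voxels))
    }
  }
  Z + spec$baseline_mean
}

#' Generate a synthetic two-condition dataset
#'
#' Per subject, a voxels x time Gaussian noise matrix is drawn, spatial
#' correlation is induced by mixing each voxel's series with the mean of its
#' 6-connected neighbours' series (weight calibrated analytically for the
#' target adjacent correlation), the planted patterns (times the temporal
#' envelope) are added for case subjects, and the series is averaged over
#' time to give the subject's activation vector. Deterministic given the spec.
#'
#' @param spec A [synthetic_spec()].
#' @param connectivity Connectivity of the returned grid (default 26; the
#'   noise-mixing operator always uses 6-connectivity).
#' @return An `ics_dataset`: `X` (voxels x subjects), `labels` (factor
#'   control/case), `grid`, `truth` (planted voxel indices), `spec`.
#' @export
generate_dataset <- function(spec, connectivity = 26L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mask <- spec$mask %||% array(TRUE, spec$shape)
  grid <- voxel_grid(mask, connectivity = connectivity)
  grid6 <- if (connectivity == 6L) grid else voxel_grid(mask, connectivity = 6L)
  truth <- sort(unique(unlist(lapply(spec$planted, `[[`, "voxels"))))
  if (length(truth) && (min(truth) < 1L || max(truth) > grid$p))
    abort("planted voxel outside the search space")
  lam <- mixing_weight(spec$spatial_rho, grid6)
  M <- if (lam > 0) neighbor_mean_op(grid6) else NULL
  n <- sum(spec$n_per_class)
  labels <- factor(rep(c("control", "case"), spec$n_per_class),
                   levels = c("control", "case"))
  X <- with_private_seed(spec$seed, {
    vapply(seq_len(n), function(s) {
      rowMeans(subject_timecourse(spec, grid, M, lam, labels[s] == "case"))
    }, numeric(grid$p))
  })
  X <- matrix(X, nrow = grid$p, ncol = n)  # vapply drops dim when p = 1
  structure(list(X = X, labels = labels, grid = grid,
                 truth = as.integer(truth), spec = spec),
            class = "ics_dataset")
}

#' @export
print.ics_dataset <- function(x, ...) {
  cat(sprintf("<ics_dataset> %d voxels x %d subjects (%s), %d truth voxels\n",
              nrow(x$X), ncol(x$X),
              paste(table(x$labels), collapse = "+"), length(x$truth)))
  invisible(x)
}

#' Impose simulated atrophy on a region
#'
#' Scales the signal of the given voxels by `1 - fraction` for case-group
#' subjects only; controls are untouched. Used to create a known detection
#' target with proportional signal loss.
#'
#' @param X Voxels x subjects activation matrix.
#' @param labels Per-subject class labels; atrophy is applied to
#'   `case_level`.
#' @param mask_voxels Integer voxel indices of the atrophied region.
#' @param fraction Signal loss fraction in (0, 1), e.g. 0.25 for 25% atrophy.
#' @param case_level Label value receiving atrophy (default: `"case"` when
#'   that level exists, otherwise the second factor level).
#' @return The modified matrix.
#' @export
simulate_atrophy <- function(X, labels, mask_voxels, fraction,
                             case_level = NULL) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    abort("fraction must be in (0, 1)")
  X <- as.matrix(X)
  f <- assert_labels(labels, ncol(X))
  case_level <- case_level %||%
    (if ("case" %in% levels(f)) "case" else levels(f)[2])
  if (!case_level %in% levels(f)) abort("case_level not among the labels")
  mask_voxels <- as.integer(mask_voxels)
  if (any(mask_voxels < 1L | mask_voxels > nrow(X)))
    abort("mask voxel outside the search space")
  case <- f == case_level
  X[mask_voxels, case] <- X[mask_voxels, case] * (1 - fraction)
  X
}
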