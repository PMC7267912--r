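new_information_map <- function(tbl, method, params, grid) {
  structure(tbl, class = c("information_map", class(tbl)),
            method = method, params = params, grid = grid)
}

#' @export
print.information_map <- function(x, ...) {
  cat(sprintf("<information_map> method %s, %d voxels\n",
              attr(x, "method"), nrow(x)))
  NextMethod()
}

#' Searchlight information map
#'
#' The classical moving-sphere baseline, sharing the ICS spectral score: for
#' every in-space voxel, the trace-ratio score of all in-space voxels within
#' Euclidean distance `radius` (sphere truncated at the mask boundary) is
#' assigned to the centre voxel.
#'
#' @param X Voxels x subjects activation matrix.
#' @param labels Class labels or an affinity model.
#' @param grid A [voxel_grid()].
#' @param radius Sphere radius in voxel units (integer >= 1, default 3).
#' @param cache Optional precomputed [spectral_cache()] (built if missing).
#' @param standardize Passed to [spectral_cache()] when building it.
#' @return An `information_map` tibble: `voxel`, `x`, `y`, `z`, `score`
#'   (trace ratio of the sphere) and a `members` list-column with each
#'   sphere's voxel set.
#' @export
searchlight_map <- function(X, labels, grid, radius = 3L, cache = NULL,
                            standardize = TRUE) {
  if (is.null(cache)) cache <- spectral_cache(X, labels, standardize)
  off <- sphere_offsets(radius)
  p <- grid$p
  # accumulate sphere sums of b and w by shifting the whole coordinate table
  B <- cache$b; W <- cache$w
  nb_ids <- matrix(NA_integer_, p, nrow(off))
  for (r in seq_len(nrow(off))) {
    nb <- grid$coords + matrix(off[r, ], p, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1L & nb[, 1] <= grid$shape[1] &
          nb[, 2] >= 1L & nb[, 2] <= grid$shape[2] &
          nb[, 3] >= 1L & nb[, 3] <= grid$shape[3]
    ids <- rep(NA_integer_, p)
    ids[ok] <- grid$lin[nb[ok, , drop = FALSE]]
    nb_ids[, r] <- ids
    got <- !is.na(ids)
    B[got] <- B[got] + cache$b[ids[got]]
    W[got] <- W[got] + cache$w[ids[got]]
  }
  score <- ifelse(W < 1e-12, Inf, B / W)
  members <- lapply(seq_len(p), function(v) {
    ids <- nb_ids[v, ]
    sort(c(v, ids[!is.na(ids)]))
  })
  tbl <- tibble(voxel = seq_len(p),
                x = grid$coords[, 1], y = grid$coords[, 2], z = grid$coords[, 3],
                score = score, members = members)
  new_information_map(tbl, "searchlight", list(radius = as.integer(radius)), grid)
}

#' L1-regularized linear baseline map
#'
#' Fits an L1-penalized logistic regression of the labels on all voxels at a
#' single penalty `lambda` and scores each voxel by the absolute value of its
#' coefficient; unselected voxels score 0.
#'
#' @param X Voxels x subjects activation matrix (standardized internally by
#'   default).
#' @param labels Two-class labels.
#' @param grid A [voxel_grid()].
#' @param lambda Penalty (default 0.001).
#' @param standardize Standardize voxels before fitting (default TRUE).
#' @return An `information_map` tibble with `score = |coefficient|` and a
#'   logical `selected` column.
#' @export
l1_baseline_map <- function(X, labels, grid, lambda = 0.001,
                            standardize = TRUE) {
  if (!is.numeric(lambda) || lambda <= 0) abort("lambda must be positive")
  f <- assert_labels(labels, ncol(X))
  if (nlevels(f) != 2L) abort("the L1 baseline is two-class")
  Xs <- if (standardize) standardize_rows(as.matrix(X)) else as.matrix(X)
  fit <- tryCatch(
    glmnet::glmnet(t(Xs), f, family = "binomial", alpha = 1,
                   lambda = lambda, standardize = FALSE, maxit = 1e6),
    error = function(e) abort(sprintf("L1 baseline did not converge: %s",
                                      conditionMessage(e))))
  beta <- as.numeric(fit$beta[, 1])
  if (anyNA(beta)) abort("L1 baseline did not converge: NA coefficients")
  tbl <- tibble(voxel = seq_len(grid$p),
                x = grid$coords[, 1], y = grid$coords[, 2], z = grid$coords[, 3],
                score = abs(beta), selected = beta != 0)
  new_information_map(tbl, "l1", list(lambda = lambda), grid)
}

#' Stratified train/test split
#'
#' Deterministic stratified split used by the evaluation protocol: information
#' mapping runs on the training portion and cluster information is scored on
#' the held-out portion, so that feature sets selected on the training data
#' are evaluated without optimism.
#'
#' @param labels Per-subject class labels.
#' @param train_frac Fraction assigned to training (default 0.8).
#' @param seed Seed for the assignment.
#' @return List with sorted integer vectors `train` and `test`.
#' @export
train_test_split <- function(labels, train_frac = 0.8, seed = 1L) {
  f <- as.factor(labels)
  if (train_frac <= 0 || train_frac >= 1) abort("train_frac must be in (0, 1)")
  train <- with_private_seed(seed, {
    unlist(lapply(levels(f), function(lv) {
      idx <- which(f == lv)
      sample(idx, round(train_frac * length(idx)))
    }))
  })
  list(train = sort(train), test = sort(setdiff(seq_along(f), train)))
}

# deterministic stratified fold assignment; every fold must see both classes
stratified_folds <- function(labels, folds, seed) {
  f <- as.factor(labels)
  assign <- integer(length(f))
  with_private_seed(seed, {
    for (lv in levels(f)) {
      idx <- sample(which(f == lv))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  for (k in seq_len(folds)) {
    if (nlevels(droplevels(f[assign != k])) < 2L ||
        nlevels(droplevels(f[assign == k])) < 2L)
      abort("stratification failed: a fold lacks both classes")
  }
  assign
}

# decision values of a fitted linear SVM, oriented so that larger means
# "more like `positive`" by construction (never flipped after looking at AUC)
svm_decision <- function(model, Xtest, positive) {
  dv <- as.numeric(Xtest %*% crossprod(model$SV, model$coefs)) - model$rho
  if (model$levels[model$labels[1]] == positive) dv else -dv
}

#' Cross-validated information of a voxel set
#'
#' The reported "information" of a cluster: stratified k-fold cross-validated
#' AUC of a linear maximum-margin classifier (SVM) that uses only the member
#' voxels as features. AUC has the 0.5 chance anchor that the above-chance
#' selection rule relies on.
#'
#' @param X Voxels x subjects activation matrix.
#' @param labels Two-class labels.
#' @param members Voxel indices forming the feature set (>= 1).
#' @param folds Number of folds (default 5).
#' @param seed Seed for the fold assignment (default 1).
#' @return Mean per-fold AUC in `[0, 1]`.
#' @export
cluster_information <- function(X, labels, members, folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  f <- assert_labels(labels, ncol(X))
  members <- as.integer(members)
  if (length(members) < 1L) abort("members must be non-empty")
  folds <- as.integer(folds)
  if (folds < 2L) abort("folds must be >= 2")
  assign <- stratified_folds(f, folds, seed)
  positive <- levels(f)[2]
  Xt <- t(X[members, , drop = FALSE])
  aucs <- vapply(seq_len(folds), function(k) {
    tr <- assign != k
    model <- e1071::svm(Xt[tr, , drop = FALSE], f[tr],
                        kernel = "linear", scale = FALSE, fitted = FALSE)
    dv <- svm_decision(model, Xt[!tr, , drop = FALSE], positive)
    auc_rank(dv, f[!tr] == positive)
  }, numeric(1))
  mean(aucs)
}

#' Attach cross-validated information scores to a result
#'
#' For an `ics_result`, scores each cluster's member set; for a searchlight
#' `information_map`, scores each sphere. Identical member sets are scored
#' once. Following the train/test protocol, pass the held-out subjects as
#' `X_eval`/`labels_eval` to score feature sets discovered on the training
#' portion without optimism.
#'
#' @param x An `ics_result` or searchlight `information_map`.
#' @param X,labels Data used for scoring.
#' @param folds,seed Passed to [cluster_information()].
#' @return `x` with an `information` column added.
#' @export
score_information <- function(x, X, labels, folds = 5L, seed = 1L) {
  memo <- new.env(parent = emptyenv())
  info_of <- function(members) {
    key <- paste(members, collapse = ",")
    val <- get0(key, envir = memo, inherits = FALSE)
    if (is.null(val)) {
      val <- cluster_information(X, labels, members, folds, seed)
      assign(key, val, envir = memo)
    }
    val
  }
  if (inherits(x, "ics_result")) {
    x$clusters$information <-
      vapply(x$clusters$members, info_of, numeric(1))
  } else if (inherits(x, "information_map") &&
             !is.null(x[["members"]])) {
    x$information <- vapply(x$members, info_of, numeric(1))
  } else {
    abort("x must be an ics_result or a searchlight information_map")
  }
  x
}

#' Select informative feature sets
#'
#' `above_chance` keeps entries with information strictly greater than 0.5;
#' `top_k` keeps the `k` highest-information entries (ties broken by the
#' origin/centre linear index).
#'
#' @param x An `ics_result` or `information_map` whose information scores are
#'   populated (see [score_information()]).
#' @param rule `"above_chance"` or `"top_k"`.
#' @param k Number kept under `top_k` (default 50).
#' @return A tibble of the selected rows (possibly empty).
#' @export
select_features <- function(x, rule = c("above_chance", "top_k"), k = 50L) {
  rule <- match.arg(rule)
  tbl <- if (inherits(x, "ics_result")) x$clusters else as_tibble(x)
  if (!"information" %in% names(tbl))
    abort("information scores not populated; run score_information() first")
  id <- if ("origin" %in% names(tbl)) "origin" else "voxel"
  if (rule == "above_chance") {
    dplyr::filter(tbl, .data$information > 0.5)
  } else {
    head(dplyr::arrange(tbl, dplyr::desc(.data$information), .data[[id]]),
         as.integer(k))
  }
}

#' Detection metrics against ground truth
#'
#' @param detected Integer voxel set declared informative.
#' @param truth Non-empty integer set of truly informative voxels.
#' @param grid A [voxel_grid()] (defines the negatives as the remaining
#'   in-space voxels).
#' @return Tibble with `tpr`, `fpr`, `fnr` and the raw counts.
#' @export
detection_metrics <- function(detected, truth, grid) {
  detected <- unique(as.integer(detected))
  truth <- unique(as.integer(truth))
  if (length(truth) == 0L) abort("truth must be non-empty")
  if (length(detected) && any(detected < 1L | detected > grid$p))
    abort("detected voxels outside the search space")
  tp <- length(intersect(detected, truth))
  fp <- length(setdiff(detected, truth))
  neg <- grid$p - length(truth)
  tibble(tpr = tp / length(truth),
         fpr = if (neg > 0) fp / neg else 0,
         fnr = 1 - tp / length(truth),
         tp = tp, fp = fp, fn = length(truth) - tp, n_negative = neg)
}

#' F1 score of a detected voxel set
#'
#' @inheritParams detection_metrics
#' @return Harmonic mean of precision and recall (0 when the detected set is
#'   empty).
#' @export
detection_f1 <- function(detected, truth) {
  detected <- unique(as.integer(detected))
  truth <- unique(as.integer(truth))
  if (length(truth) == 0L) abort("truth must be non-empty")
  tp <- length(intersect(detected, truth))
  if (tp == 0L) return(0)
  prec <- tp / length(detected)
  rec <- tp / length(truth)
  2 * prec * rec / (prec + rec)
}

#' Jaccard overlap of two voxel sets
#' @param a,b Integer voxel sets.
#' @export
jaccard <- function(a, b) {
  a <- unique(as.integer(a)); b <- unique(as.integer(b))
  if (length(a) == 0L && length(b) == 0L) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Per-voxel overlay map from overlapping clusters
#'
#' ICS clusters may overlap; every voxel displays the highest score among the
#' clusters containing it (higher-quality clusters overshadow lower ones).
#' `value = "information"` uses the cross-validated AUC (requires
#' [score_information()]); `value = "relevance"` uses the raw trace-ratio
#' score and needs no scoring pass.
#'
#' @param result An `ics_result`.
#' @param value `"information"` or `"relevance"`.
#' @return An `information_map` tibble with the overlay `score`.
#' @export
ics_overlay_map <- function(result, value = c("information", "relevance")) {
  stopifnot(inherits(result, "ics_result"))
  value <- match.arg(value)
  cl <- result$clusters
  if (value == "information" && !"information" %in% names(cl))
    abort("information scores not populated; run score_information() first")
  vals <- cl[[value]]
  grid <- result$grid
  score <- rep(NA_real_, grid$p)
  for (i in order(vals)) score[cl$members[[i]]] <- vals[i]  # higher overwrites
  tbl <- tibble(voxel = seq_len(grid$p),
                x = grid$coords[, 1], y = grid$coords[, 2], z = grid$coords[, 3],
                score = score)
  new_information_map(tbl, paste0("ics_overlay_", value), list(), grid)
}

#' The best cluster of a search result
#'
#' Clusters are ranked by information (cross-validated AUC, descending), then
#' by size (descending), then by origin linear index. The size tie-break
#' matters whenever the AUC saturates: among clusters of equal information
#' the most extensive one is the most complete map of the informative region,
#' which is what a mapping method should report.
#'
#' @param result An `ics_result` with information scores populated.
#' @return The one-row tibble of the top-ranked cluster.
#' @export
best_cluster <- function(result) {
  stopifnot(inherits(result, "ics_result"))
  cl <- result$clusters
  if (!"information" %in% names(cl))
    abort("information scores not populated; run score_information() first")
  cl[order(-cl$information, -cl$size, cl$origin)[1], , drop = FALSE]
}

#' Matched-size voxel detection from an information map
#'
#' Ranks voxels by a method's map and returns the top `k` as the detected
#' set, so that methods are compared at equal detected-set size. Rankings:
#' an `ics_result` uses the relevance overlay (each voxel scored by the best
#' cluster containing it); a searchlight map uses the sphere score; an L1 map
#' uses `|coefficient|` restricted to selected (nonzero) voxels -- the L1
#' detected set is therefore at most the number of nonzero coefficients.
#' Ties break by voxel linear index.
#'
#' @param x An `ics_result` or `information_map`.
#' @param k Number of voxels to detect.
#' @return Integer vector of detected voxel linear indices (length <= k).
#' @export
detect_voxels <- function(x, k) {
  k <- as.integer(k)
  if (inherits(x, "ics_result")) {
    ov <- ics_overlay_map(x, value = "relevance")
    sc <- ifelse(is.na(ov$score), -Inf, ov$score)
    return(sort(order(-sc, ov$voxel)[seq_len(min(k, length(sc)))]))
  }
  if (!inherits(x, "information_map")) abort("x must be an ics_result or information_map")
  if (identical(attr(x, "method"), "l1")) {
    sel <- which(x$selected)
    sel <- sel[order(-x$score[sel], x$voxel[sel])]
    return(sort(x$voxel[head(sel, k)]))
  }
  sc <- ifelse(is.finite(x$score), x$score, max(x$score[is.finite(x$score)], 0) + 1)
  sort(x$voxel[order(-sc, x$voxel)[seq_len(min(k, nrow(x)))]])
}
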