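test_that("a whole-space searchlight is a constant map", {
  d <- toy_data(shape = c(3, 3, 2), n = 12, seed = 2)
  cache <- spectral_cache(d$X, d$labels)
  m <- searchlight_map(d$X, d$labels, d$grid, radius = 10, cache = cache)
  whole <- cluster_score(cache, seq_len(d$grid$p))
  expect_equal(m$score, rep(whole, d$grid$p), tolerance = 1e-12)
})

test_that("searchlight spheres match a brute-force distance scan", {
  d <- toy_data(shape = c(4, 4, 3), n = 16, seed = 23)
  cache <- spectral_cache(d$X, d$labels)
  for (r in 1:2) {
    m <- searchlight_map(d$X, d$labels, d$grid, radius = r, cache = cache)
    for (v in c(1L, 10L, 25L, 48L)) {
      d2 <- rowSums((d$grid$coords -
                       matrix(d$grid$coords[v, ], d$grid$p, 3, byrow = TRUE))^2)
      want <- which(d2 <= r^2)
      expect_identical(m$members[[v]], sort(as.integer(want)))
      expect_equal(m$score[v], cluster_score(cache, want, method = "explicit"),
                   tolerance = 1e-10)
    }
  }
  # radius 1: centre plus its six face neighbours
  g <- voxel_grid(array(TRUE, c(3, 3, 3)))
  centre <- g$lin[2, 2, 2]
  m1 <- searchlight_map(d$X[1:27, ], d$labels, g, radius = 1)
  expect_length(m1$members[[centre]], 7)
})

test_that("the L1 baseline shrinks fully and finds a strong voxel", {
  d <- toy_data(shape = c(4, 4, 2), n = 40, seed = 15,
                effect = list(voxels = 7L, amplitude = 3))
  big <- l1_baseline_map(d$X, d$labels, d$grid, lambda = 100)
  expect_equal(big$score, rep(0, d$grid$p))
  m <- l1_baseline_map(d$X, d$labels, d$grid, lambda = 0.05)
  expect_equal(which.max(m$score), 7L)
  expect_lte(sum(m$selected), ncol(d$X))
  expect_error(l1_baseline_map(d$X, d$labels, d$grid, lambda = -1), "lambda")
})

test_that("cluster information is at chance for label-independent data", {
  withr::with_seed(1, {
    X <- matrix(rnorm(3 * 60), 3, 60)
    labels <- rep(c("a", "b"), 30)
    aucs <- vapply(1:30, function(s) {
      Xs <- matrix(rnorm(3 * 60), 3, 60)
      cluster_information(Xs, labels, 1:3, folds = 5, seed = s)
    }, numeric(1))
    expect_lt(abs(mean(aucs) - 0.5), 0.05)
  })
})

test_that("a perfectly separating voxel reaches AUC 1", {
  labels <- rep(c("a", "b"), each = 20)
  X <- rbind(c(rnorm(20, -3, 0.1), rnorm(20, 3, 0.1)), rnorm(40))
  expect_equal(cluster_information(X, labels, 1L, folds = 5, seed = 2), 1)
})

test_that("planted clusters outscore random clusters of the same size", {
  d <- generate_dataset(synthetic_spec(shape = c(4, 4, 2), n_per_class = c(40, 40),
                                       t_points = 60,
                                       planted = list(planted_block(c(4, 4, 2), 1:2, 1:2, 1:2, 1.5)),
                                       seed = 8))
  planted_auc <- cluster_information(d$X, d$labels, d$truth, seed = 1)
  rand_auc <- cluster_information(d$X, d$labels, c(20L, 27L, 30L, 18L, 24L,
                                                   31L, 26L, 22L), seed = 1)
  expect_gt(planted_auc, rand_auc)
})

test_that("stratification failure and degenerate folds are caught", {
  X <- matrix(rnorm(2 * 10), 2, 10)
  labels <- c(rep("a", 8), "b", "b")
  expect_error(cluster_information(X, labels, 1L, folds = 5, seed = 1),
               "stratification failed")
})

test_that("our rank AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(33, {
    for (i in 1:5) {
      sc <- rnorm(40)
      y <- sample(rep(c(TRUE, FALSE), 20))
      yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
      want <- as.numeric(pROC::auc(pROC::roc(response = yf, predictor = sc,
                                             quiet = TRUE, direction = "<")))
      got <- icsearch:::auc_rank(sc, y)
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("feature selection rules behave at their boundaries", {
  d <- toy_data(shape = c(3, 3, 1), n = 12, seed = 3)
  fit <- run_ics(d$X, d$labels, d$grid)
  fit$clusters$information <- rep(0.5, d$grid$p)
  expect_equal(nrow(select_features(fit, "above_chance")), 0)
  expect_equal(nrow(select_features(fit, "top_k", k = 100)), d$grid$p)
  fit$clusters$information <- c(0.7, 0.6, 0.4, rep(0.1, 6))
  top2 <- select_features(fit, "top_k", k = 2)
  expect_identical(top2$origin, c(1L, 2L))
  expect_error(select_features(run_ics(d$X, d$labels, d$grid)), "not populated")
})

test_that("detection metrics cover the degenerate corners", {
  g <- voxel_grid(array(TRUE, c(3, 3, 1)))
  truth <- 1:3
  m <- detection_metrics(truth, truth, g)
  expect_equal(c(m$tpr, m$fpr, m$fnr), c(1, 0, 0))
  m0 <- detection_metrics(integer(0), truth, g)
  expect_equal(c(m0$tpr, m0$fpr, m0$fnr), c(0, 0, 1))
  mc <- detection_metrics(4:9, truth, g)
  expect_equal(c(mc$tpr, mc$fpr, mc$fnr), c(0, 1, 1))
  expect_equal(m$tpr + m$fnr, 1)
  expect_error(detection_metrics(1:2, integer(0), g), "non-empty")
  expect_equal(detection_f1(truth, truth), 1)
  expect_equal(detection_f1(integer(0), truth), 0)
  expect_equal(jaccard(1:3, 2:4), 0.5)
})

test_that("train/test split is stratified and deterministic", {
  labels <- factor(rep(c("a", "b"), c(50, 30)))
  s1 <- train_test_split(labels, 0.8, seed = 4)
  s2 <- train_test_split(labels, 0.8, seed = 4)
  expect_identical(s1, s2)
  expect_equal(sum(labels[s1$train] == "a"), 40)
  expect_equal(sum(labels[s1$train] == "b"), 24)
  expect_length(intersect(s1$train, s1$test), 0)
})

test_that("overlay, best cluster and matched-size detection rank as documented", {
  d <- toy_data(shape = c(3, 3, 1), n = 12, seed = 21)
  fit <- run_ics(d$X, d$labels, d$grid)
  # craft overlapping clusters with known information
  fit$clusters$members[1:2] <- list(c(1L, 2L, 4L), c(2L, 5L))
  fit$clusters$size[1:2] <- c(3L, 2L)
  fit$clusters$information <- c(0.7, 0.6, rep(0.2, 7))
  ov <- ics_overlay_map(fit, value = "information")
  expect_equal(ov$score[2], 0.7)  # shared voxel shows the better cluster
  expect_equal(ov$score[5], 0.6)
  bc <- best_cluster(fit)
  expect_equal(bc$origin, 1L)
  # equal information: the more extensive cluster wins
  fit$clusters$information <- c(0.7, 0.7, rep(0.2, 7))
  fit$clusters$size[1:2] <- c(2L, 5L)
  expect_equal(best_cluster(fit)$origin, 2L)
  det <- detect_voxels(fit, 3)
  expect_length(det, 3)
  # l1 detection never exceeds the selected set
  m <- l1_baseline_map(d$X, d$labels, d$grid, lambda = 5)
  expect_length(detect_voxels(m, 4), 0)
})
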