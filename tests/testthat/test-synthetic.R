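test_that("generation is a deterministic function of the spec", {
  spec <- synthetic_spec(shape = c(4, 4, 2), n_per_class = c(8, 8),
                         t_points = 30, seed = 42)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a$X, b$X)
  c <- generate_dataset(synthetic_spec(shape = c(4, 4, 2), n_per_class = c(8, 8),
                                       t_points = 30, seed = 43))
  expect_false(identical(a$X, c$X))
})

test_that("zero amplitude gives exchangeable class distributions", {
  d <- generate_dataset(synthetic_spec(shape = c(5, 5, 2), n_per_class = c(60, 60),
                                       t_points = 40, seed = 7))
  diff <- rowMeans(d$X[, d$labels == "case"]) -
    rowMeans(d$X[, d$labels == "control"])
  se <- sqrt(2 / 60) * sd(d$X[1, ]) * 3  # generous Monte-Carlo band
  expect_lt(max(abs(diff)), 5 * sqrt(2 / 60) * sd(d$X))
  expect_length(d$truth, 0)
})

test_that("a planted pattern shifts the case group by amplitude x mean envelope", {
  spec <- synthetic_spec(shape = c(4, 4, 2), n_per_class = c(150, 150),
                         t_points = 60, spatial_rho = 0,
                         planted = list(planted_block(c(4, 4, 2), 1:2, 1:2, 1, 2)),
                         seed = 3)
  d <- generate_dataset(spec)
  shift <- mean(d$X[d$truth, d$labels == "case"]) -
    mean(d$X[d$truth, d$labels == "control"])
  expect_equal(shift, 2 * mean(spec$envelope), tolerance = 0.05)
  expect_identical(d$truth, sort(spec$planted[[1]]$voxels))
})

test_that("planted voxels must live inside the grid", {
  expect_error(generate_dataset(synthetic_spec(
    shape = c(2, 2, 2), n_per_class = c(4, 4), t_points = 20,
    planted = list(list(voxels = 99L, amplitude = 1)))), "outside")
})

test_that("adjacent-voxel noise correlation is calibrated", {
  d0 <- generate_dataset(synthetic_spec(shape = c(6, 6, 6), n_per_class = c(60, 60),
                                        t_points = 40, spatial_rho = 0, seed = 11))
  g6 <- voxel_grid(array(TRUE, c(6, 6, 6)), connectivity = 6)
  from <- rep(seq_len(g6$p), lengths(g6$adj))
  to <- unlist(g6$adj)
  pairs <- cbind(from, to)[to > from, ]
  corr_of <- function(X) {
    mean(vapply(seq_len(nrow(pairs)), function(r)
      cor(X[pairs[r, 1], ], X[pairs[r, 2], ]), numeric(1)))
  }
  expect_lt(abs(corr_of(d0$X)), 0.05)
  d3 <- generate_dataset(synthetic_spec(shape = c(6, 6, 6), n_per_class = c(60, 60),
                                        t_points = 40, spatial_rho = 0.3, seed = 11))
  expect_equal(corr_of(d3$X), 0.3, tolerance = 0.05)
})

test_that("spatial_rho outside the calibratable range is rejected", {
  expect_error(synthetic_spec(spatial_rho = 0.6), "mixing range")
  expect_error(synthetic_spec(spatial_rho = -0.1), "spatial_rho")
})

test_that("the temporal envelope peaks at one", {
  env <- hrf_envelope(120)
  expect_equal(max(env), 1)
  expect_length(env, 120)
  expect_gt(which.max(env), 1)  # rises then decays
})

test_that("simulated atrophy scales only the case group inside the mask", {
  X <- matrix(1, 4, 6)
  labels <- rep(c("control", "case"), 3)
  Y <- simulate_atrophy(X, labels, mask_voxels = 1:2, fraction = 0.25)
  expect_equal(Y[1, labels == "case"], rep(0.75, 3))
  expect_equal(Y[1, labels == "control"], rep(1, 3))
  expect_equal(Y[3, ], rep(1, 6))
  # tiny fraction approaches the identity
  Y2 <- simulate_atrophy(X, labels, 1:2, fraction = 1e-9)
  expect_equal(Y2, X, tolerance = 1e-8)
  expect_error(simulate_atrophy(X, labels, 1:2, fraction = 1.2), "fraction")
  expect_error(simulate_atrophy(X, labels, 99, fraction = 0.5), "outside")
})

test_that("group mean difference under atrophy matches the imposed fraction", {
  d <- generate_dataset(synthetic_spec(shape = c(4, 4, 2), n_per_class = c(100, 100),
                                       t_points = 60, seed = 19))
  Y <- simulate_atrophy(d$X, d$labels, 1:8, fraction = 0.25)
  ctrl <- mean(Y[1:8, d$labels == "control"])
  cas <- mean(Y[1:8, d$labels == "case"])
  expect_equal(ctrl - cas, 0.25 * ctrl, tolerance = 0.1)
})
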