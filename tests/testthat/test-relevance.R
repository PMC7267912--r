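test_that("per-voxel quadratic forms match the explicit pairwise identity", {
  withr::with_seed(3, {
    X <- matrix(rnorm(20 * 10), 20, 10)
    labels <- rep(c("a", "b"), 5)
    aff <- build_affinity(labels)
    cache <- spectral_cache(X, aff, standardize = FALSE)
    for (i in c(1, 7, 20)) {
      expect_equal(cache$b[i], brute_quadform(X[i, ], aff$S_b), tolerance = 1e-10)
      expect_equal(cache$w[i], brute_quadform(X[i, ], aff$S_w), tolerance = 1e-10)
    }
    expect_true(all(cache$b >= 0))
    expect_true(all(cache$w >= 0))
  })
})

test_that("a voxel constant across subjects has zero scatter and Inf score", {
  X <- matrix(rnorm(5 * 8), 5, 8)
  X[2, ] <- 3.14
  cache <- spectral_cache(X, rep(c("a", "b"), 4), standardize = FALSE)
  expect_equal(cache$b[2], 0)
  expect_equal(cache$w[2], 0)
  expect_warning(s <- cluster_score(cache, 2), "degenerate within-class scatter")
  expect_identical(s, Inf)
})

test_that("duplicating a subject keeps the quadratic forms nonnegative", {
  withr::with_seed(8, {
    X <- matrix(rnorm(6 * 9), 6, 9)
    labels <- c(rep("a", 4), rep("b", 5))
    X2 <- cbind(X, X[, 1])
    cache <- spectral_cache(X2, c(labels, "a"), standardize = FALSE)
    expect_true(all(cache$b >= 0))
    expect_true(all(cache$w >= 0))
  })
})

test_that("cached cluster_score equals the explicit selection-matrix trace", {
  withr::with_seed(21, {
    X <- matrix(rnorm(30 * 12), 30, 12)
    cache <- spectral_cache(X, rep(c("a", "b"), 6))
    for (i in 1:20) {
      m <- sample(30, sample(1:8, 1))
      expect_equal(cluster_score(cache, m),
                   cluster_score(cache, m, method = "explicit"),
                   tolerance = 1e-10)
    }
    # invariant to member enumeration order
    m <- sample(30, 6)
    expect_identical(cluster_score(cache, m), cluster_score(cache, rev(m)))
  })
})

test_that("the score of a set lies between its members' singleton scores", {
  withr::with_seed(13, {
    cache <- mock_cache(b = runif(15, 0, 4), w = runif(15, 0.2, 2))
    for (i in 1:10) {
      m <- sample(15, sample(2:8, 1))
      s <- cluster_score(cache, m)
      r <- cache$b[m] / cache$w[m]
      expect_gte(s, min(r) - 1e-12)
      expect_lte(s, max(r) + 1e-12)
    }
  })
  # worked mediant example: 2/1 with 0/1 combine to 2/2 = 1
  cc <- mock_cache(b = c(2, 0), w = c(1, 1))
  expect_equal(cluster_score(cc, 1:2), 1)
})

test_that("admission requires a strictly positive score delta", {
  # a candidate with zero between-scatter only inflates the denominator
  cc <- mock_cache(b = c(4, 0), w = c(1, 1))
  r <- admission_test(cc, 1, 2)
  expect_false(r$admit)
  expect_lt(r$dif, 0)
  # an exact copy of a singleton leaves the score unchanged: tie rejects
  cc2 <- mock_cache(b = c(4, 4), w = c(1, 1))
  r2 <- admission_test(cc2, 1, 2)
  expect_false(r2$admit)
  expect_equal(r2$dif, 0)
  expect_error(admission_test(cc2, 1:2, 2), "already in the cluster")
})

test_that("admission decisions agree with from-scratch explicit recomputation", {
  withr::with_seed(17, {
    X <- matrix(rnorm(25 * 14), 25, 14)
    cache <- spectral_cache(X, rep(c("a", "b"), 7))
    for (i in 1:15) {
      m <- sample(25, sample(1:6, 1))
      cand <- sample(setdiff(1:25, m), 1)
      r <- admission_test(cache, m, cand)
      dif_explicit <- cluster_score(cache, c(m, cand), method = "explicit") -
        cluster_score(cache, m, method = "explicit")
      expect_equal(r$dif, dif_explicit, tolerance = 1e-10)
      expect_identical(r$admit, dif_explicit > 0)
    }
  })
})
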