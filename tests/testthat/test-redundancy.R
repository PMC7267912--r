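test_that("mutual information closed forms hold", {
  withr::with_seed(2, {
    # self-information of an equal-frequency binning is the marginal entropy
    x <- rnorm(64)
    expect_equal(mutual_information(x, x, bins = 4), log(4), tolerance = 1e-12)
    # independence: MI tends to zero
    a <- runif(1e4); b <- runif(1e4)
    expect_lt(mutual_information(a, b, bins = 4), 0.01)
    # perfectly correlated balanced binary pair
    z <- rep(c(0, 1), each = 50)
    expect_equal(mutual_information(z, z, bins = 4), log(2), tolerance = 1e-12)
    # constant vector collapses to one bin
    expect_equal(mutual_information(rep(1, 32), rnorm(32), bins = 4), 0)
  })
})

test_that("the MI estimator is symmetric and nonnegative", {
  withr::with_seed(9, {
    for (i in 1:20) {
      n <- sample(32:100, 1)
      x <- rnorm(n)
      y <- if (runif(1) < 0.3) round(rnorm(n)) else rnorm(n)  # include ties
      expect_identical(mutual_information(x, y), mutual_information(y, x))
      expect_gte(mutual_information(x, y), 0)
    }
  })
  expect_error(mutual_information(rnorm(10), rnorm(10), bins = 8), "at least")
  expect_error(mutual_information(rnorm(20), rnorm(21)), "equal length")
})

test_that("redundancy score is the mean pairwise MI with the rest", {
  withr::with_seed(4, {
    X <- matrix(rnorm(5 * 64), 5, 64)
    X[2, ] <- X[1, ]; X[3, ] <- X[1, ]  # three copies of the same voxel
    cache <- redundancy_cache(X, bins = 4)
    expect_equal(redundancy_score(cache, 1:3, 1), log(4), tolerance = 1e-12)
    expect_equal(redundancy_score(cache, 1:3, 3), log(4), tolerance = 1e-12)
    # independent voxels: J near zero at large n
    Y <- matrix(rnorm(3 * 4000), 3, 4000)
    c2 <- redundancy_cache(Y, bins = 4)
    expect_lt(redundancy_score(c2, 1:3, 2), 0.02)
    expect_error(redundancy_score(cache, 2, 2), "singleton")
    expect_error(redundancy_score(cache, 1:3, 5), "belong")
  })
})

test_that("cached redundancy equals a cache-free recomputation", {
  withr::with_seed(6, {
    X <- matrix(rnorm(8 * 50), 8, 50)
    cache <- redundancy_cache(X, bins = 8)
    m <- c(1, 3, 4, 6, 8)
    for (t in m) {
      fresh <- mean(vapply(setdiff(m, t), function(k)
        mutual_information(X[t, ], X[k, ], 8), numeric(1)))
      expect_equal(redundancy_score(cache, m, t), fresh, tolerance = 1e-12)
      # second call hits the cache and must agree exactly
      expect_identical(redundancy_score(cache, m, t),
                       redundancy_score(cache, m, t))
    }
    expect_equal(nrow(mi_table(cache)), choose(5, 2))
  })
})

test_that("pruning removes an exact duplicate and spares protected members", {
  withr::with_seed(10, {
    X <- matrix(rnorm(6 * 60), 6, 60)
    labels <- rep(c("a", "b"), 30)
    # voxels 1,3,4,6 carry class signal; voxel 2 is noise and 5 duplicates it,
    # so one copy is both maximally redundant and score-neutral to remove
    X[c(1, 3, 4, 6), labels == "b"] <- X[c(1, 3, 4, 6), labels == "b"] + 1.5
    X[5, ] <- X[2, ]
    scache <- spectral_cache(X, labels)
    rcache <- redundancy_cache(X)
    out <- prune_cluster(1:6, protected = 1, scache, rcache)
    # both redundant noise copies go (each removal is score-neutral or better);
    # the informative members and the protected origin stay
    expect_true(all(c(2L, 5L) %in% out$removed))
    expect_true(1L %in% out$members)  # protected origin survives
    # all members protected: nothing happens
    out2 <- prune_cluster(1:6, protected = 1:6, scache, rcache)
    expect_identical(out2$members, 1:6)
    expect_length(out2$removed, 0)
  })
})

test_that("pruning matches an exhaustive cache-free rerun and never lowers the score", {
  withr::with_seed(14, {
    for (rep in 1:4) {
      X <- matrix(rnorm(8 * 40), 8, 40)
      labels <- rep(c("a", "b"), 20)
      aff <- build_affinity(labels)
      scache <- spectral_cache(X, aff, standardize = FALSE)
      rcache <- redundancy_cache(X)
      protected <- sample(8, 2)
      got <- prune_cluster(1:8, protected, scache, rcache)
      want <- brute_prune(1:8, protected, X, aff)
      expect_identical(got$members, as.integer(want$members))
      expect_identical(got$removed, as.integer(want$removed))
      expect_true(all(protected %in% got$members))
      expect_gte(cluster_score(scache, got$members),
                 cluster_score(scache, 1:8) - 1e-10)
    }
  })
})
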