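test_that("z-scoring standardizes columns and inverts exactly", {
  set.seed(1)
  X <- cbind(onset = rnorm(50, 20, 5), canopy = rnorm(50, 60, 10),
             peaks = rnorm(50, 3, 1))
  Z <- zscore_features(X)
  expect_lt(max(abs(colMeans(Z$values))), 1e-9)
  expect_lt(max(abs(apply(Z$values, 2, sd) - 1)), 1e-9)
  expect_lt(max(abs(unzscore_features(Z) - X)), 1e-9)
  # an already-standardized column passes through unchanged
  X2 <- X
  X2[, 1] <- (X[, 1] - mean(X[, 1])) / sd(X[, 1])
  expect_equal(zscore_features(X2)$values[, 1], unname(X2[, 1]),
               tolerance = 1e-12)
  X3 <- X
  X3[, 2] <- 7
  expect_error(zscore_features(X3), "canopy")
})

test_that("spectral clustering separates well-separated planted groups", {
  set.seed(2)
  X <- rbind(matrix(rnorm(150, 0, 0.5), ncol = 3),
             matrix(rnorm(150, 10, 0.5), ncol = 3))
  truth <- rep(1:2, each = 50)
  lab <- spectral_cluster(X, 2, seed = 1)
  expect_equal(adj_rand(lab, truth), 1)
  # determinism under a fixed seed
  expect_identical(lab, spectral_cluster(X, 2, seed = 1))
  # k = N puts every point in its own cluster
  small <- matrix(rnorm(15), ncol = 3)
  labN <- spectral_cluster(small, 5, seed = 1)
  expect_equal(sort(unique(labN)), 1:5)
  expect_error(spectral_cluster(small, 1), "k must")
  expect_error(spectral_cluster(small, 6), "k must")
})

test_that("spectral clustering agrees with an independent implementation", {
  skip_if_not_installed("kernlab")
  cloud <- generate_feature_cloud(3, 40, 8, seed = 5)
  ours <- spectral_cluster(cloud$features, 3, seed = 1)
  theirs <- withr::with_seed(1, {
    kernlab::specc(cloud$features, centers = 3,
                   kernel = "rbfdot", kpar = list(sigma = 1))
  })
  expect_equal(adj_rand(ours, cloud$labels), 1)
  expect_equal(adj_rand(theirs@.Data, cloud$labels), 1)
})

test_that("pooled dispersion follows the pairwise-distance definition", {
  # one cluster of two points at distance 2: ordered pairs sum 8, W = 2
  X <- matrix(c(0, 0, 0, 2, 0, 0), nrow = 2, byrow = TRUE)
  expect_equal(pooled_dispersion(X, c(1, 1)), 2)
  expect_equal(pooled_dispersion(X[c(1, 1), ], c(1, 1)), 0)
  expect_error(pooled_dispersion(X, c(1, 1), k = 2), "empty cluster")
})

test_that("pooled dispersion equals within-cluster squared distances to centroids", {
  set.seed(3)
  for (i in 1:10) {
    X <- matrix(rnorm(60 * 3), ncol = 3)
    lab <- sample(1:4, 60, replace = TRUE)
    W <- pooled_dispersion(X, lab)
    Wc <- sum(vapply(unique(lab), function(l) {
      Xr <- X[lab == l, , drop = FALSE]
      sum(sweep(Xr, 2, colMeans(Xr))^2)
    }, numeric(1)))
    expect_equal(W, Wc, tolerance = 1e-9)
    # invariance under label permutation and row reordering
    perm <- sample(60)
    expect_equal(pooled_dispersion(X[perm, ], lab[perm]), W,
                 tolerance = 1e-9)
    expect_equal(pooled_dispersion(X, 5 - lab), W, tolerance = 1e-9)
  }
})

test_that("reference samples stay in the rotated range box and reproduce", {
  set.seed(4)
  X <- matrix(rnorm(80 * 3), ncol = 3)
  V <- svd(X)$v
  lo <- apply(X %*% V, 2, min)
  hi <- apply(X %*% V, 2, max)
  r1 <- withr::with_seed(9, reference_sample(X))
  r2 <- withr::with_seed(9, reference_sample(X))
  expect_identical(r1, r2)
  expect_equal(dim(r1), dim(X))
  rot <- r1 %*% V
  for (j in 1:3) {
    expect_true(all(rot[, j] >= lo[j] - 1e-9 & rot[, j] <= hi[j] + 1e-9))
  }
  # marginals in the rotated frame are uniform over the observed range
  pvals <- replicate(10, {
    r <- reference_sample(X) %*% V
    min(vapply(1:3, function(j) {
      suppressWarnings(ks.test(r[, j], "punif", lo[j], hi[j])$p.value)
    }, numeric(1)))
  })
  expect_gt(mean(pvals > 0.01), 0.5)
})

test_that("the gap selection rule picks the smallest adequate k", {
  prof <- data.frame(k = 2:4, logW = c(0, 0, 0),
                     ElogW = c(1, 2, 1.9), G = c(1, 2, 1.9),
                     S = c(0.1, 0.1, 0.1))
  class(prof) <- c("tcd_gap", "data.frame")
  sel <- select_k(prof)
  expect_equal(sel$k, 3)
  expect_false(sel$no_elbow)
  # monotonically increasing gap with tiny dispersion: no elbow
  prof$G <- c(1, 2, 3)
  prof$S <- rep(1e-6, 3)
  sel2 <- select_k(prof)
  expect_equal(sel2$k, 4)
  expect_true(sel2$no_elbow)
})

test_that("gap profiles recover a planted four-cluster structure", {
  cloud <- generate_feature_cloud(4, 40, 6, seed = 10)
  gp <- gap_profile(zscore_features(cloud$features), 2:7, B = 60, seed = 11)
  expect_equal(attr(gp, "B"), 60)
  expect_equal(gp$G, gp$ElogW - gp$logW)
  expect_equal(which.max(gp$G) + 1L, 4L)
  expect_equal(select_k(gp)$k, 4)
  lab4 <- attr(gp, "labels_by_k")$k4
  expect_equal(adj_rand(lab4, cloud$labels), 1)
})

test_that("gap profiles are computable at B = 1 and stable across seeds", {
  cloud <- generate_feature_cloud(3, 25, 6, seed = 12)
  Z <- zscore_features(cloud$features)
  gp1 <- gap_profile(Z, 2:4, B = 1, seed = 1)
  expect_true(all(is.finite(gp1$S)))
  gpa <- gap_profile(Z, 2:4, B = 200, seed = 21)
  gpb <- gap_profile(Z, 2:4, B = 200, seed = 22)
  expect_true(all(abs(gpa$G - gpb$G) < pmax(gpa$S, gpb$S)))
})

test_that("a single isotropic blob yields a flat gap curve", {
  rises <- vapply(1:7, function(s) {
    cloud <- generate_feature_cloud(1, 100, 6, seed = 30 + s)
    gp <- gap_profile(zscore_features(cloud$features), 2:7, B = 40,
                      seed = 40 + s)
    max(diff(gp$G))
  }, numeric(1))
  expect_gte(mean(rises < 0.4), 0.7)
})
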