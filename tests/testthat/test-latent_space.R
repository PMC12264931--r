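# PCA latent map, KDE surface, and two-stage clustering.

test_that("PC1 captures all variance for collinear toy data", {
  t_ <- seq(0, 1, length.out = 20)
  X <- cbind(a = 2 * t_, b = -t_)
  B <- cbind(c = t_, d = 3 * t_)
  rownames(X) <- rownames(B) <- sprintf("m%02d", seq_along(t_))
  map <- fit_latent_map(X, B)
  expect_equal(unname(map$explained_variance), c(1, 1))
  expect_equal(mean(map$scores$structural_pc1), 0, tolerance = 1e-8)
  expect_equal(mean(map$scores$bonding_pc1), 0, tolerance = 1e-8)
})

test_that("PC1 variance fraction equals the eigen-decomposition oracle", {
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3) %*% diag(c(3, 1, 0.3))
  colnames(X) <- c("f1", "f2", "f3")
  rownames(X) <- sprintf("m%02d", 1:20)
  map <- fit_latent_map(X, X)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(unname(map$explained_variance["structural"]),
               ev[1] / sum(ev), tolerance = 1e-10)
})

test_that("degenerate all-constant descriptors raise an error", {
  X <- matrix(1, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(fit_latent_map(X, X), "degenerate")
  expect_error(fit_latent_map(X[1:2, ], X[1:2, ]), "at least 3")
})

test_that("projection is a left inverse on the fit population", {
  set.seed(6)
  X <- matrix(rnorm(80), 20, 4,
              dimnames = list(sprintf("m%02d", 1:20), paste0("s", 1:4)))
  B <- matrix(rnorm(60), 20, 3,
              dimnames = list(sprintf("m%02d", 1:20), paste0("b", 1:3)))
  map <- fit_latent_map(X, B)
  pr <- project_latent(map, X, B)
  expect_equal(pr$structural_pc1, map$scores$structural_pc1)
  expect_equal(pr$bonding_pc1, map$scores$bonding_pc1)

  # out-of-population projection equals the manual (x - mean) . loading
  Xn <- matrix(rnorm(8), 2, 4, dimnames = list(c("n1", "n2"),
                                               paste0("s", 1:4)))
  Bn <- matrix(rnorm(6), 2, 3, dimnames = list(c("n1", "n2"),
                                               paste0("b", 1:3)))
  pn <- project_latent(map, Xn, Bn)
  manual <- sweep(Xn, 2, map$structural_fit$center) %*%
    map$structural_fit$rotation[, 1]
  expect_equal(pn$structural_pc1, as.numeric(manual))

  # duplicated molecule projects to identical coordinates
  pd <- project_latent(map, Xn[c(1, 1), ], Bn[c(1, 1), ])
  expect_equal(pd$structural_pc1[1], pd$structural_pc1[2])

  # registry mismatch is an error
  Xbad <- Xn; colnames(Xbad) <- paste0("z", 1:4)
  expect_error(project_latent(map, Xbad, Bn), "registry")
})

test_that("KDE surface matches the direct kernel sum and conserves mass", {
  set.seed(9)
  pts <- cbind(rnorm(150), rnorm(150, 2, 0.5))
  k <- latent_kde2d(pts, grid_size = 80)
  # mass over the padded grid
  mass <- sum(k$z) * diff(k$x[1:2]) * diff(k$y[1:2])
  expect_equal(mass, 1, tolerance = 0.02)
  # direct kernel-sum evaluation at 20 random grid nodes
  set.seed(10)
  ii <- sample(length(k$x), 20, replace = TRUE)
  jj <- sample(length(k$y), 20, replace = TRUE)
  at <- cbind(k$x[ii], k$y[jj])
  direct <- kde2d_at(pts, at, k$bandwidth)
  expect_equal(k$z[cbind(ii, jj)], direct, tolerance = 1e-8)

  # single tight cluster peaks at the cluster centre
  tight <- cbind(rnorm(50, 5, 0.01), rnorm(50, -2, 0.01))
  kt <- latent_kde2d(tight, bandwidth = c(0.05, 0.05), grid_size = 60)
  pk <- which(kt$z == max(kt$z), arr.ind = TRUE)
  expect_lt(abs(kt$x[pk[1]] - 5), 0.1)
  expect_lt(abs(kt$y[pk[2]] + 2), 0.1)
  # far-field decay
  expect_lt(kt$z[1, 1] / max(kt$z), 1e-6)
  expect_error(latent_kde2d(cbind(rep(1, 5), rep(2, 5))),
               "zero-variance")
})

test_that("two-stage clustering recovers well-separated blobs", {
  set.seed(12)
  b1 <- cbind(rnorm(120, 0, 0.3), rnorm(120, 0, 0.3))
  b2 <- cbind(rnorm(80, 6, 0.3), rnorm(80, 6, 0.3))
  pts <- rbind(b1, b2)
  truth <- rep(1:2, c(120, 80))
  ca <- cluster_latent(pts, n_clusters = 2)
  agree <- max(mean((ca$cluster == 1) == (truth == 1)),
               mean((ca$cluster == 2) == (truth == 1)))
  expect_gte(agree, 0.98)
  expect_gte(ca$subclusters, 8)          # subcluster stage is fine-grained

  # duplicated points land in the same cluster
  dup <- rbind(pts, pts[1:10, ])
  cd <- cluster_latent(dup, n_clusters = 2)
  expect_equal(cd$cluster[nrow(pts) + 1:10], cd$cluster[1:10])

  # k = 1 puts everything together; fewer points than clusters errors
  expect_true(all(cluster_latent(pts, 1)$cluster == 1))
  expect_error(cluster_latent(pts[1:3, ], 5), "fewer points")
})
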