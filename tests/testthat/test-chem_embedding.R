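test_that("PCA recovers an exact 2D plane embedded in 6D", {
  set.seed(21)
  basis <- qr.Q(qr(matrix(rnorm(12), 6, 2)))    # orthonormal 6D plane
  z <- matrix(rnorm(40 * 2), 40, 2) %*% diag(c(3, 1))
  X <- z %*% t(basis)
  emb <- fit_pca(X)
  expect_equal(sum(emb$diagnostics$explained_variance), 1, tolerance = 1e-9)
  # pairwise geometry of the plane is reproduced exactly
  expect_equal(as.matrix(dist(emb$coords)), as.matrix(dist(z)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA axes are scale-direction invariant and sign-deterministic", {
  set.seed(22)
  X <- matrix(rnorm(30 * 4), 30, 4)
  e1 <- fit_pca(X)
  e2 <- fit_pca(rbind(X, X))                    # duplicated dataset
  expect_equal(e2$coords[1:30, ], e1$coords, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_identical(fit_pca(X)$coords, e1$coords)
})

test_that("PCA matches an eigen-decomposition oracle on a small matrix", {
  set.seed(23)
  X <- matrix(rnorm(20), 5, 4)
  emb <- fit_pca(X)
  # independent oracle: eigen-decomposition of the covariance matrix
  ev <- eigen(cov(X), symmetric = TRUE)
  Xc <- sweep(X, 2, colMeans(X))
  oracle <- Xc %*% ev$vectors[, 1:2]
  for (k in 1:2) {                       # compare up to per-axis sign
    expect_equal(abs(emb$coords[, k]), abs(oracle[, k]), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  expect_equal(emb$diagnostics$explained_variance,
               (ev$values / sum(ev$values))[1:2], tolerance = 1e-9)
  # non-decreasing explained variance ordering
  expect_gte(emb$diagnostics$explained_variance[1],
             emb$diagnostics$explained_variance[2])
})

test_that("PCA rejects rank-deficient input", {
  X <- matrix(1:8, 8, 3)[, c(1, 1, 1)]   # all columns identical
  expect_error(fit_pca(X), "rank")
  expect_error(fit_pca(matrix(rnorm(4), 2, 2)), "at least 3")
})

test_that("GTM posterior is normalized and the objective never decreases", {
  set.seed(31)
  X <- rbind(matrix(rnorm(60 * 4, 0), 60), matrix(rnorm(60 * 4, 5), 60))
  emb <- suppressWarnings(fit_gtm(X, grid_size = 10, rbf_grid = 3,
                                  max_iter = 100))
  # a run stopped at max_iter flags non-convergence in its diagnostics
  expect_type(emb$diagnostics$converged, "logical")
  R <- emb$diagnostics$responsibilities
  expect_equal(rowSums(R), rep(1, nrow(X)), tolerance = 1e-9,
               ignore_attr = TRUE)
  ll <- emb$diagnostics$log_likelihood
  expect_true(all(diff(ll) >= -1e-8 * pmax(abs(ll[-length(ll)]), 1)))
  # coordinates live inside the latent square
  expect_true(all(emb$coords >= -1 - 1e-9 & emb$coords <= 1 + 1e-9))
})

test_that("GTM separates well-separated clusters in the 2D embedding", {
  set.seed(32)
  n <- 50
  X <- rbind(matrix(rnorm(n * 6, 0), n), matrix(rnorm(n * 6, 6), n))
  lab <- rep(c(1, 2), each = n)
  emb <- fit_gtm(X, labels = lab, grid_size = 12, rbf_grid = 4,
                 max_iter = 150)
  co <- emb$coords
  # silhouette-style criterion: mean within-cluster distance smaller than
  # mean between-cluster distance for every point
  D <- as.matrix(dist(co))
  sil <- vapply(seq_len(2 * n), function(i) {
    a <- mean(D[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- mean(D[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})

test_that("GTM is deterministic and maps identical molecules identically", {
  set.seed(33)
  X <- matrix(rnorm(30 * 5), 30, 5)
  X[7, ] <- X[3, ]                        # duplicated molecule
  e1 <- fit_gtm(X, grid_size = 8, rbf_grid = 3, max_iter = 50)
  e2 <- fit_gtm(X, grid_size = 8, rbf_grid = 3, max_iter = 50)
  expect_identical(e1$coords, e2$coords)
  expect_equal(e1$coords[7, ], e1$coords[3, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(fit_gtm(X[1:5, ]), "at least 10")
})

test_that("embedding coordinates serialize with library labels", {
  set.seed(34)
  X <- matrix(rnorm(36), 12, 3)
  rownames(X) <- paste0("m", 1:12)
  emb <- fit_pca(X, labels = rep(c("a", "b"), 6))
  path <- tempfile(fileext = ".csv")
  write_embedding(emb, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("id", "library", "dim1", "dim2"))
  expect_equal(back$id, rownames(X))
})
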