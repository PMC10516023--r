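test_that("variance_normalize matches the hand-computed toy", {
  X <- matrix(c(1, 2, 3,
                4, 6, 8,
                0, 1, 2,
                5, 5, 8), nrow = 3, ncol = 4)
  ## oracle: z-score each column, then demean each row
  Z <- apply(X, 2, function(col) (col - mean(col)) / sd(col))
  Z <- Z - rowMeans(Z)
  expect_equal(variance_normalize(X), Z, ignore_attr = TRUE)
})

test_that("variance_normalize output has the stated moments", {
  set.seed(1)
  X <- matrix(rnorm(50 * 20, mean = 3, sd = 2), 50, 20)
  Z <- variance_normalize(X)
  expect_equal(rowMeans(Z), rep(0, 50), tolerance = 1e-12)
  ## columns were unit-sd before row-demeaning, which perturbs column scale
  ## by O(1/sqrt(V)); re-applying is idempotent only up to that perturbation
  Z2 <- variance_normalize(Z)
  expect_equal(Z, Z2, tolerance = 0.1, ignore_attr = TRUE)
  expect_gt(min(diag(cor(Z, Z2))), 0.999)
  Xbad <- X
  Xbad[, 3] <- 7
  expect_error(variance_normalize(Xbad), "3")
})

test_that("regress_site removes injected site offsets exactly", {
  set.seed(2)
  V <- 40; N <- 60
  X <- matrix(rnorm(V * N), V, N)
  X <- X - rowMeans(X)
  sites <- rep(c("a", "b"), each = N / 2)
  offs <- cbind(rnorm(V, sd = 5), rnorm(V, sd = 5))
  Xoff <- X
  Xoff[, sites == "a"] <- Xoff[, sites == "a"] + offs[, 1]
  Xoff[, sites == "b"] <- Xoff[, sites == "b"] + offs[, 2]
  cleaned <- regress_site(Xoff, sites)
  reference <- regress_site(X, sites)
  expect_equal(cleaned, reference, tolerance = 1e-10)
  ## rows orthogonal to the site indicator
  ind <- as.numeric(sites == "a")
  expect_lt(max(abs(cleaned %*% (ind - mean(ind)))), 1e-8)
})

test_that("regress_site with a single site is row-demeaning", {
  set.seed(3)
  X <- matrix(rnorm(20 * 30), 20, 30)
  out <- regress_site(X, rep(1, 30))
  expect_equal(out, X - rowMeans(X), tolerance = 1e-10)
  f <- factor(rep("a", 30), levels = c("a", "ghost"))
  expect_error(regress_site(X, f), "ghost")
})

test_that("pca_whiten yields identity sample covariance and true spectrum", {
  set.seed(4)
  X <- matrix(rnorm(30 * 200), 30, 200)
  X <- X - rowMeans(X)
  w <- pca_whiten(X, 6)
  expect_equal(tcrossprod(w$reduced) / (200 - 1), diag(6), tolerance = 1e-8)
  expect_equal(w$reduced, w$transform %*% X, tolerance = 1e-10)
  ## eigenvalue oracle: independent eigendecomposition of the V x V
  ## second-moment matrix
  ev <- eigen(tcrossprod(X) / (200 - 1), symmetric = TRUE,
              only.values = TRUE)$values
  expect_equal(w$eigenvalues, ev[1:6], tolerance = 1e-8)
  expect_true(all(diff(w$eigenvalues) <= 1e-12))
  expect_error(pca_whiten(X, 31), "C must be")
})

test_that("pca_whiten at full rank preserves the data's own projection", {
  set.seed(5)
  L <- matrix(rnorm(40 * 4), 40, 4)
  X <- L %*% matrix(rnorm(4 * 100), 4, 100)   # rank 4
  w <- pca_whiten(X, 4)
  back <- MASS::ginv(w$transform) %*% w$reduced
  expect_equal(back, X, tolerance = 1e-8)
})

test_that("mgpca_whiten matches a literal transcription on a tiny case", {
  set.seed(6)
  V <- 4; N <- 6; C <- 3
  Xs <- lapply(1:2, function(m) {
    X <- matrix(rnorm(V * N), V, N)
    X - rowMeans(X)
  })
  out <- mgpca_whiten(Xs, C)
  ## oracle: average of scaled Gram matrices, top-C eigenpairs, then whiten
  ## each modality against its variance along the common directions
  Sigma_avg <- (N * crossprod(Xs[[1]]) / sum(Xs[[1]]^2) +
                  N * crossprod(Xs[[2]]) / sum(Xs[[2]]^2)) / 2
  eg <- eigen(Sigma_avg, symmetric = TRUE)
  Q <- eg$vectors[, 1:C]
  expect_equal(out[[1]]$eigenvalues, eg$values[1:C], tolerance = 1e-10)
  for (m in 1:2) {
    mu <- diag(t(Q) %*% crossprod(Xs[[m]]) %*% Q)
    Wm <- sqrt(N - 1) * diag(1 / mu) %*% t(Xs[[m]] %*% Q)
    ## package convention: rows scaled to give exactly unit-variance output
    red <- Wm %*% Xs[[m]]
    Wm <- Wm / sqrt(rowSums((red - rowMeans(red))^2) / (N - 1))
    expect_equal(abs(out[[m]]$transform), abs(Wm), tolerance = 1e-8)
    expect_equal(out[[m]]$reduced, out[[m]]$transform %*% Xs[[m]],
                 tolerance = 1e-12)
    expect_equal(apply(out[[m]]$reduced, 1, var), rep(1, C),
                 tolerance = 1e-10)
  }
})

test_that("mgpca_whiten with one modality reduces to PCA whitening", {
  set.seed(7)
  X <- matrix(rnorm(50 * 80), 50, 80)
  X <- X - rowMeans(X)
  a <- pca_whiten(X, 5)
  b <- mgpca_whiten(list(X), 5)[[1]]
  expect_equal(abs(a$reduced), abs(b$reduced), tolerance = 1e-8)
  expect_equal(tcrossprod(b$reduced) / (80 - 1), diag(5), tolerance = 1e-8)
})

test_that("mgpca_whiten on identical modalities matches single-modality PCA", {
  set.seed(8)
  X <- matrix(rnorm(60 * 90), 60, 90)
  X <- X - rowMeans(X)
  both <- mgpca_whiten(list(X, X), 4)
  solo <- pca_whiten(X, 4)
  for (m in 1:2) {
    expect_equal(abs(both[[m]]$reduced), abs(solo$reduced), tolerance = 1e-6)
  }
})

test_that("mgpca rows are near unit variance for distinct modalities", {
  d <- generate_multimodal(make_candidate("S2"), V = 300, N = 3000, seed = 10)
  wh <- mgpca_whiten(d$X, 12)
  for (m in 1:2) {
    v <- apply(wh[[m]]$reduced, 1, var)
    expect_true(all(abs(v - 1) < 0.1))
  }
  expect_error(mgpca_whiten(list(d$X[[1]], d$X[[2]][, 1:100]), 5),
               "share N")
})
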