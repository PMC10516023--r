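test_that("1D subspace CCA is the absolute Pearson correlation", {
  set.seed(50)
  a <- matrix(rnorm(500), 1, 500)
  b <- matrix(-0.8 * a + 0.6 * rnorm(500), 1, 500)
  cc <- subspace_cca(a, b)
  expect_equal(cc$canonical_correlation, abs(cor(a[1, ], b[1, ])),
               tolerance = 1e-12)
  expect_equal(abs(cc$p), 1)
  expect_equal(abs(cc$q), 1)
})

test_that("2D CCA matches the closed-form generalized eigen solution", {
  set.seed(51)
  N <- 4000
  S1 <- matrix(rnorm(2 * N), 2, N)
  mixL <- rbind(c(0.9, 0.2), c(-0.3, 1.1))
  S2 <- mixL %*% S1 * 0.7 + 0.7 * matrix(rnorm(2 * N), 2, N)
  cc <- subspace_cca(S1, S2)
  ## independent oracle: eigenvalues of Sxx^-1 Sxy Syy^-1 Syx
  X <- t(S1); Y <- t(S2)
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  Sxx <- crossprod(X) / (N - 1); Syy <- crossprod(Y) / (N - 1)
  Sxy <- crossprod(X, Y) / (N - 1)
  ev <- eigen(solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy))$values
  expect_equal(cc$canonical_correlation, sqrt(max(Re(ev))),
               tolerance = 1e-8)
  ## CCA dominates any single source pair
  expect_gte(cc$canonical_correlation,
             max(abs(cor(t(S1), t(S2)))) - 1e-10)
  ## achieved correlation equals the reported one
  expect_equal(abs(cor(cc$post_cca_sources[1, ], cc$post_cca_sources[2, ])),
               cc$canonical_correlation, tolerance = 1e-8)
})

test_that("posthoc_cca runs per linked subspace of a fitted model", {
  d <- generate_multimodal(make_candidate("S2"), V = 300, N = 800, seed = 52)
  fit <- msiva_fit(d, make_candidate("S2"), workflow = "msiva",
                   n_outer = 3, seed = 52)
  ccas <- posthoc_cca(fit)
  expect_length(ccas, 5L)
  for (cc in ccas) {
    expect_true(cc$canonical_correlation >= 0 &&
                  cc$canonical_correlation <= 1)
    expect_equal(sum(cc$p^2), 1, tolerance = 1e-9)
  }
  ## recovered linked subspaces carry strong cross-modal correlation
  expect_gt(median(vapply(ccas, `[[`, 1.0, "canonical_correlation")), 0.5)
})

test_that("reconstruction is additive and preserves the retained projection", {
  s <- make_candidate("S2")
  d <- generate_multimodal(s, V = 120, N = 400, seed = 53)
  wh <- mgpca_whiten(d$X, 12)
  W <- lapply(1:2, function(m) solve(wh[[m]]$transform %*% d$A[[m]]))
  model <- structure(
    list(W = W, whitening = lapply(wh, `[[`, "transform"),
         composite = Map(function(w, h) w %*% h$transform, W, wh),
         structure = s,
         S = Map(function(w, h) w %*% h$reduced, W, wh)),
    class = "msiva_model"
  )
  rec <- reconstruct(model)
  for (m in 1:2) {
    total <- Reduce(`+`, lapply(rec$X_hat, `[[`, m))
    expect_equal(total, rec$full[[m]], tolerance = 1e-10)
    ## perfect unmixing on noiseless data: the full reconstruction is the
    ## projection of X onto the retained C-dimensional subspace; here the
    ## data are exactly rank C, so the reconstruction reproduces X
    expect_equal(rec$full[[m]], d$X[[m]], tolerance = 1e-6)
    ## per-subspace variance shares lie in [0, 1] and sum to the total
    r2 <- vapply(rec$X_hat, function(xk)
      sum(xk[[m]]^2) / sum(d$X[[m]]^2), 1.0)
    expect_true(all(r2 >= 0 & r2 <= 1))
  }
})

test_that("svd_shared recovers shared structure with the right scaling", {
  set.seed(54)
  A <- matrix(rnorm(20 * 50), 20, 50)
  sh <- svd_shared(A, A)
  expect_equal(sh, sqrt(2) * A, tolerance = 1e-10, ignore_attr = TRUE)
  ## anti-correlated copy: same subspace, sign fixed to modality 1
  sh2 <- svd_shared(A, -A)
  expect_equal(sh2, sqrt(2) * A, tolerance = 1e-10, ignore_attr = TRUE)
  ## random rows: per-voxel agreement with a generic SVD oracle
  B <- matrix(rnorm(20 * 50), 20, 50)
  sh3 <- svd_shared(A, B)
  for (v in c(1, 7, 20)) {
    sv <- svd(rbind(A[v, ], B[v, ]))
    oracle <- sv$d[1] * sv$v[, 1]
    if (sum(oracle * A[v, ]) < 0) oracle <- -oracle
    expect_equal(sh3[v, ], oracle, tolerance = 1e-10)
  }
  ## zero rows flagged
  A0 <- A; A0[3, ] <- 0
  B0 <- B; B0[3, ] <- 0
  sh4 <- svd_shared(A0, B0)
  expect_equal(sh4[3, ], rep(0, 50))
  expect_equal(attr(sh4, "zero_rows"), 3L)
})

test_that("phenotype prediction recovers a noiseless linear target", {
  set.seed(55)
  X <- matrix(rnorm(600 * 5), 600, 5)
  y <- drop(X %*% c(2, -1, 0.5, 1, 3))
  res <- predict_phenotype(X, y, task = "regression", seed = 1)
  expect_lt(res$metric, 0.05 * sd(y))
  expect_true(res$lambda >= 0.1 - 1e-9 && res$lambda <= 1 + 1e-9)
  expect_equal(res$lambda, 0.1, tolerance = 1e-9)  # least shrinkage wins
})

test_that("classification of label-independent features is at chance", {
  accs <- vapply(1:5, function(s) {
    set.seed(200 + s)
    X <- matrix(rnorm(300 * 4), 300, 4)
    cls <- factor(rep(c("a", "b"), length.out = 300))
    predict_phenotype(X, cls, task = "classification", seed = s)$metric
  }, 1.0)
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("prediction contract errors fire", {
  X <- matrix(rnorm(60 * 2), 60, 2)
  expect_error(predict_phenotype(X, rnorm(10), seed = 1), "length N")
  expect_error(predict_phenotype(X, factor(rep("a", 60)),
                                 task = "classification", seed = 1),
               "2 classes")
})
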