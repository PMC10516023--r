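test_that("the Gaussian is the Kotz member beta=1, eta=1, lam=1/2", {
  kp <- kotz_params(beta = 1, eta = 1, lam = 0.5)
  expect_equal(kotz_neg_log_density(0, kp), 0.5 * log(2 * pi),
               tolerance = 1e-12)
  for (v in c(-1.3, 0.4, 2.2)) {
    expect_equal(kotz_neg_log_density(v, kp), -dnorm(v, log = TRUE),
                 tolerance = 1e-12)
  }
  ## 3D standard normal
  v <- c(0.3, -1.1, 0.7)
  expect_equal(kotz_neg_log_density(v, kp),
               -sum(dnorm(v, log = TRUE)), tolerance = 1e-12)
})

test_that("the Laplace-like member integrates to one (2D quadrature)", {
  kp <- kotz_params(beta = 0.5, eta = 1)
  gr <- seq(-14, 14, length.out = 401)
  h <- gr[2] - gr[1]
  dens <- outer(gr, gr, function(x, y) {
    mapply(function(a, b) exp(-kotz_neg_log_density(c(a, b), kp)), x, y)
  })
  expect_equal(sum(dens) * h^2, 1, tolerance = 1e-3)
})

test_that("unit-variance scale parameters match closed forms", {
  ## 1D Laplace: lambda = sqrt(2); Gaussian: 1/2; D-dim exponential with
  ## eta = 1: sqrt(D + 1)
  expect_equal(msiva:::kotz_lambda_unit(1, 0.5, 1), sqrt(2),
               tolerance = 1e-12)
  expect_equal(msiva:::kotz_lambda_unit(4, 1, 1), 0.5, tolerance = 1e-12)
  expect_equal(msiva:::kotz_lambda_unit(3, 0.5, 1), 2, tolerance = 1e-12)
})

test_that("the density is rotation invariant and flags the eta<1 pole", {
  kp <- kotz_params(beta = 0.5, eta = 1)
  v <- c(1.2, -0.5, 0.3)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(kotz_neg_log_density(v, kp),
               kotz_neg_log_density(drop(R %*% v), kp), tolerance = 1e-12)
  expect_identical(kotz_neg_log_density(rep(0, 4),
                                        kotz_params(beta = 0.5, eta = 0.5)),
                   Inf)
})

test_that("the default eta adapts to the subspace dimension", {
  kp <- kotz_params()
  expect_equal(msiva:::resolve_eta(kp, 1), 1)
  expect_equal(msiva:::resolve_eta(kp, 2), 1)
  expect_equal(msiva:::resolve_eta(kp, 3), 0.5)
  expect_equal(msiva:::resolve_eta(kp, 4), 0)
  expect_equal(msiva:::resolve_eta(kotz_params(eta = 1), 4), 1)
})

test_that("misa_loss matches a literal transcription on a tiny case", {
  ## 2 modalities, 2 sources each, one 2D linked block, identity unmixing
  s <- subspace_structure(c(2), unimodal = 0, M = 2, name = "tiny")
  kp <- kotz_params()
  Xr <- list(matrix(c(0.5, -1.0, 0.3, 0.8), 2, 2),
             matrix(c(1.1, 0.2, -0.4, 0.6), 2, 2))
  W <- list(diag(2), diag(2))
  ## oracle: -sum log|det| + mean_n of the stacked subspace density
  stacked <- rbind(Xr[[1]], Xr[[2]])
  oracle <- mean(apply(stacked, 2, kotz_neg_log_density, p = kp))
  expect_equal(misa_loss(W, Xr, s, kp), oracle, tolerance = 1e-12)

  ## non-identity W adds the log-determinant term
  W2 <- list(matrix(c(2, 0, 0, 1), 2, 2), diag(2))
  stacked2 <- rbind(W2[[1]] %*% Xr[[1]], Xr[[2]])
  oracle2 <- -log(2) + mean(apply(stacked2, 2, kotz_neg_log_density, p = kp))
  expect_equal(misa_loss(W2, Xr, s, kp), oracle2, tolerance = 1e-12)
})

test_that("the loss is invariant to source sign flips and sample order", {
  set.seed(11)
  s <- make_candidate("S2")
  Xr <- lapply(1:2, function(m) matrix(rnorm(12 * 40), 12, 40))
  W <- lapply(1:2, function(m) diag(12) + 0.05 * matrix(rnorm(144), 12, 12))
  base <- misa_loss(W, Xr, s)
  Wf <- W
  Wf[[1]][3, ] <- -Wf[[1]][3, ]
  expect_equal(misa_loss(Wf, Xr, s), base, tolerance = 1e-12)
  perm <- sample(40)
  Xp <- lapply(Xr, function(x) x[, perm])
  expect_equal(misa_loss(W, Xp, s), base, tolerance = 1e-12)
  expect_error(misa_loss(list(matrix(0, 12, 12), W[[2]]), Xr, s), "singular")
})

test_that("ground-truth unmixing beats random orthogonal unmixings", {
  s <- make_candidate("S2")
  d <- generate_multimodal(s, V = 40, N = 800, seed = 12)
  Xr <- d$S                      # identity mixing in source space
  Wt <- list(diag(12), diag(12))
  base <- misa_loss(Wt, Xr, s)
  set.seed(13)
  worse <- 0
  for (i in 1:100) {
    W <- lapply(1:2, function(m) qr.Q(qr(matrix(rnorm(144), 12, 12))))
    if (misa_loss(W, Xr, s) > base) worse <- worse + 1
  }
  expect_equal(worse, 100)
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(14)
  s <- subspace_structure(c(2), unimodal = 1, M = 2, name = "toy3")
  Xr <- lapply(1:2, function(m) matrix(rnorm(3 * 60), 3, 60))
  W <- lapply(1:2, function(m) diag(3) + 0.1 * matrix(rnorm(9), 3, 3))
  kp <- kotz_params()
  ctx <- msiva:::loss_context(s, kp)
  an <- msiva:::misa_loss_grad(W, Xr, ctx)$grad
  h <- 1e-6
  for (m in 1:2) {
    num <- matrix(0, 3, 3)
    for (i in 1:3) {
      for (j in 1:3) {
        Wp <- W; Wm <- W
        Wp[[m]][i, j] <- Wp[[m]][i, j] + h
        Wm[[m]][i, j] <- Wm[[m]][i, j] - h
        num[i, j] <- (misa_loss(Wp, Xr, s, kp) -
                        misa_loss(Wm, Xr, s, kp)) / (2 * h)
      }
    }
    expect_equal(an[[m]], num, tolerance = 1e-5)
  }
})

test_that("numerical_optimize descends and is stationary at an optimum", {
  set.seed(15)
  s <- subspace_structure(c(2), unimodal = 1, M = 2, name = "toy3")
  d <- generate_multimodal(s, V = 30, N = 1500, seed = 15)
  wh <- mgpca_whiten(d$X, 3)
  Xr <- lapply(wh, `[[`, "reduced")
  W0 <- lapply(1:2, function(m) diag(3) + 0.3 * matrix(rnorm(9), 3, 3))
  res <- numerical_optimize(W0, Xr, s, max_iter = 300)
  expect_lte(res$loss, res$initial_loss)
  ## restarting at the optimum moves (almost) nowhere
  res2 <- numerical_optimize(res$W, Xr, s, max_iter = 300)
  expect_lt(res$loss - res2$loss, 1e-4)
  ## a random perturbation of the optimum is strictly improved upon
  Wp <- lapply(res$W, function(w) w + 0.05 * matrix(rnorm(9), 3, 3))
  res3 <- numerical_optimize(Wp, Xr, s, max_iter = 300)
  expect_lt(res3$loss, misa_loss(Wp, Xr, s) - 1e-8)
})
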