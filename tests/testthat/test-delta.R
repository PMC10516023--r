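test_that("the confound design has exactly the stated ten demeaned columns", {
  set.seed(60)
  N <- 200
  age <- runif(N, 46, 79)
  Y <- build_confounds(age, sex = rbinom(N, 1, 0.5), motion = runif(N),
                       norm_vars = cbind(rnorm(N), rnorm(N)))
  expect_equal(ncol(Y), 10L)
  expect_equal(colMeans(Y), rep(0, 10), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(build_confounds(age, motion = runif(N),
                               norm_vars = cbind(rnorm(N), rnorm(N))),
               "sex")
})

test_that("sex-age interactions match a hand calculation on a 6-row toy", {
  age <- c(50, 55, 60, 65, 70, 75)
  sex <- c(1, -1, 1, -1, 1, -1)
  Y <- build_confounds(age, sex, motion = rep(0.1, 6),
                       norm_vars = cbind(1:6, 6:1))
  a <- age - mean(age)
  sx <- sex - mean(sex)
  for (j in 1:3) {
    hand <- sx * a^j
    hand <- hand - mean(hand)
    expect_equal(Y[, 4 + j], hand, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("stage 1 delta behaves at the two analytic extremes", {
  set.seed(61)
  N <- 400
  y <- rnorm(N); y <- y - mean(y)
  ## a predictor equal to age: beta = 1, delta = 0
  s1 <- delta_stage1(cbind(y), y)
  expect_equal(s1$beta1, 1, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(s1$delta1, rep(0, N), tolerance = 1e-10)
  ## predictors independent of age: delta ~ -y
  X <- scale(matrix(rnorm(N * 3), N, 3), scale = FALSE)
  s2 <- delta_stage1(X, y)
  expect_gt(cor(s2$delta1, -y), 0.99)
  expect_equal(mean(s2$delta1), 0, tolerance = 1e-10)
})

test_that("stage 2 removes confound structure and is shift-invariant", {
  set.seed(62)
  N <- 300
  age <- runif(N, 40, 80)
  Y <- build_confounds(age, sex = rbinom(N, 1, 0.5), motion = runif(N),
                       norm_vars = cbind(rnorm(N), rnorm(N)))
  ## delta1 built from Y's own columns vanishes
  d1 <- drop(Y %*% c(1, 0.1, 0, 2, 0, 0, 0, 1, 0.5, -1))
  s2 <- delta_stage2(d1, Y)
  expect_lt(max(abs(s2$delta2)), 1e-8)
  ## generic delta1: residual orthogonal to every confound column
  d1b <- rnorm(N)
  s2b <- delta_stage2(d1b, Y)
  expect_lt(max(abs(cor(s2b$delta2, Y))), 1e-10)
  ## adding any confound combination to delta1 leaves delta2 unchanged
  shift <- drop(Y %*% rnorm(10))
  s2c <- delta_stage2(d1b + shift, Y)
  expect_equal(s2b$delta2, s2c$delta2, tolerance = 1e-8)
})

test_that("partialized contributions are mutually orthogonalized", {
  set.seed(63)
  N <- 250
  age <- runif(N, 40, 80)
  Y <- build_confounds(age, sex = rbinom(N, 1, 0.5), motion = runif(N),
                       norm_vars = cbind(rnorm(N), rnorm(N)))
  X <- scale(matrix(rnorm(N * 3), N, 3) +
               0.5 * (age - mean(age)), scale = FALSE)
  s1 <- delta_stage1(X, age - mean(age))
  s2 <- delta_stage2(s1$delta1, Y, s1$contributions)
  corrected <- apply(s1$contributions, 2, function(v) {
    v - Y %*% MASS::ginv(crossprod(Y)) %*% crossprod(Y, v)
  })
  for (j in 1:3) {
    others <- corrected[, -j, drop = FALSE]
    expect_lt(max(abs(cor(s2$delta2p[, j], others))), 1e-8)
  }
})

test_that("a pure linear age signal leaves no partialized delta", {
  set.seed(64)
  N <- 300; V <- 40
  age <- runif(N, 46, 79)
  Y <- build_confounds(age, sex = rbinom(N, 1, 0.5), motion = runif(N),
                       norm_vars = cbind(rnorm(N), rnorm(N)))
  y <- age - mean(age)
  preds <- list(signal = matrix(rep(y, each = V), V, N))
  out <- delta_pipeline(preds, age, Y)
  expect_lt(max(abs(out$delta2p[[1]])), 1e-8)
  expect_equal(dim(out$beta1), c(V, 1L))
})

test_that("phenotype correlation maps count the full test family", {
  set.seed(65)
  N <- 120; V <- 100
  delta2p <- list(a = matrix(rnorm(V * N), V, N),
                  b = matrix(rnorm(V * N), V, N))
  ph <- data.frame(p1 = rnorm(N), p2 = rnorm(N), p3 = rnorm(N))
  res <- correlate_phenotypes(delta2p, ph)
  expect_equal(res$n_tests, 100 * 3 * 2)
  expect_equal(dim(res$r), c(100L, 3L, 2L))
  ## a phenotype equal to one delta row is recovered with certainty
  ph2 <- data.frame(hit = delta2p$a[7, ])
  res2 <- correlate_phenotypes(delta2p["a"], ph2)
  expect_equal(res2$r[7, 1, 1], 1, tolerance = 1e-12)
  expect_true(res2$significant[7, 1, 1])
  ## constant phenotypes are excluded with a warning
  expect_warning(correlate_phenotypes(delta2p, cbind(ph, k = 1)),
                 "constant")
})

test_that("permuted phenotypes stay near the nominal false-discovery rate", {
  set.seed(66)
  N <- 150; V <- 80
  delta2p <- list(matrix(rnorm(V * N), V, N))
  ph <- data.frame(x = rnorm(N), y = rnorm(N))
  res <- correlate_phenotypes(delta2p, ph, q = 0.05)
  expect_lte(sum(res$significant) / res$n_tests, 0.05)
})
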