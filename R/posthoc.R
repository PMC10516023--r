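## Classical CCA via the generalized-eigenvalue route with a small ridge for
## rank safety. X: N x p, Y: N x q (columns are variables).
cca_top <- function(X, Y, ridge = 1e-8) {
  X <- scale(X, center = TRUE, scale = FALSE)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  N <- nrow(X)
  Sxx <- crossprod(X) / (N - 1) + ridge * diag(ncol(X))
  Syy <- crossprod(Y) / (N - 1) + ridge * diag(ncol(Y))
  Sxy <- crossprod(X, Y) / (N - 1)
  ## symmetric inverse square root with rank truncation: stable for the
  ## near-collinear feature sets the RDC produces
  isqrt <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    keep <- e$values > max(e$values) * 1e-12
    U <- e$vectors[, keep, drop = FALSE]
    U %*% (t(U) / sqrt(e$values[keep]))
  }
  Wx <- isqrt(Sxx)
  Wy <- isqrt(Syy)
  sv <- svd(Wx %*% Sxy %*% Wy)
  p <- drop(Wx %*% sv$u[, 1])
  q <- drop(Wy %*% sv$v[, 1])
  p <- p / sqrt(sum(p^2))
  q <- q / sqrt(sum(q^2))
  ## orient so the canonical pair correlates positively
  if (stats::cor(X %*% p, Y %*% q) < 0) q <- -q
  list(cor = min(sv$d[1], 1), p = p, q = q,
       all_cors = pmin(sv$d[seq_len(min(ncol(X), ncol(Y)))], 1))
}

#' Per-subspace canonical correlation analysis
#'
#' Classical CCA between the two modalities' sources of one cross-modal
#' subspace, restricted to the top canonical pair: the unit-norm projections
#' `p_k, q_k` maximizing `corr(p_k' S_k[1], q_k' S_k[2])`. For a 1D subspace
#' this reduces to the absolute Pearson correlation with trivial
#' projections.
#'
#' @param Sk1,Sk2 d_k x N source blocks of the subspace in each modality.
#' @param ridge ridge added to the within-set covariances for rank safety; a
#'   warning is raised when it is actually needed.
#' @return `msiva_cca`: list with `p`, `q` (unit-norm projections),
#'   `canonical_correlation`, `all_correlations`, `post_cca_sources`
#'   (2 x N matrix: projected modality-1 and modality-2 sources).
#' @export
subspace_cca <- function(Sk1, Sk2, ridge = 1e-8) {
  stop_if_not_matrix(Sk1); stop_if_not_matrix(Sk2)
  d <- nrow(Sk1)
  N <- ncol(Sk1)
  if (nrow(Sk2) != d) stop("subspace blocks must have equal dimension")
  if (ncol(Sk2) != N) stop("subspace blocks must share N")
  if (N <= d) stop("need N > d_k")
  if (d == 1L) {
    r <- stats::cor(Sk1[1, ], Sk2[1, ])
    p <- 1; q <- if (r < 0) -1 else 1
    res <- list(cor = abs(r), p = p, q = q, all_cors = abs(r))
  } else {
    ev1 <- eigen(stats::cov(t(Sk1)), symmetric = TRUE, only.values = TRUE)$values
    ev2 <- eigen(stats::cov(t(Sk2)), symmetric = TRUE, only.values = TRUE)$values
    use_ridge <- 0
    if (min(ev1) < 1e-10 * max(ev1) || min(ev2) < 1e-10 * max(ev2)) {
      warning("rank-deficient subspace block; ridge-regularized CCA")
      use_ridge <- ridge
    }
    res <- cca_top(t(Sk1), t(Sk2), ridge = use_ridge)
  }
  structure(
    list(p = res$p, q = res$q,
         canonical_correlation = res$cor,
         all_correlations = res$all_cors,
         post_cca_sources = rbind(drop(crossprod(res$p, Sk1)),
                                  drop(crossprod(res$q, Sk2)))),
    class = "msiva_cca"
  )
}

#' @export
print.msiva_cca <- function(x, ...) {
  cat("<msiva_cca> canonical correlation:",
      format(x$canonical_correlation, digits = 4), "\n")
  invisible(x)
}

#' Post-hoc CCA of every linked subspace of a fitted model
#'
#' @param model `msiva_model` (M = 2).
#' @return list of `msiva_cca`, one per linked subspace.
#' @export
posthoc_cca <- function(model) {
  stopifnot(inherits(model, "msiva_model"))
  if (length(model$S) != 2L) stop("post-hoc CCA requires M = 2")
  blocks <- structure_index_map(model$structure)
  out <- list()
  for (b in blocks) {
    if (b$type == "linked") {
      out[[length(out) + 1L]] <- subspace_cca(
        model$S[[1]][b$idx, , drop = FALSE],
        model$S[[2]][b$idx, , drop = FALSE]
      )
    }
  }
  out
}

#' Subspace-wise data reconstruction
#'
#' Estimates the mixing matrices as the Moore-Penrose pseudo-inverse of the
#' composite C x V transforms, and reconstructs the data carried by each
#' subspace: `X_hat_k[m] = A_hat[m][, idx_k] %*% S_hat[m][idx_k, ]`. The
#' per-subspace reconstructions sum exactly to the full reconstruction
#' `A_hat[m] %*% S_hat[m]`.
#'
#' @param model `msiva_model`.
#' @return `msiva_reconstruction`: `A_hat` (per-modality V x C), `X_hat`
#'   (list over blocks; each a list of per-modality V x N matrices, `NULL`
#'   for modalities a unimodal block does not belong to), `blocks` (the
#'   block map), `full` (per-modality full reconstructions).
#' @export
reconstruct <- function(model) {
  stopifnot(inherits(model, "msiva_model"))
  M <- length(model$composite)
  A_hat <- lapply(model$composite, MASS::ginv)
  blocks <- structure_index_map(model$structure)
  X_hat <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    X_hat[[k]] <- lapply(seq_len(M), function(m) {
      A_hat[[m]][, b$idx, drop = FALSE] %*%
        model$S[[m]][b$idx, , drop = FALSE]
    })
  }
  full <- lapply(seq_len(M), function(m) A_hat[[m]] %*% model$S[[m]])
  structure(
    list(A_hat = A_hat, X_hat = X_hat, blocks = blocks, full = full),
    class = "msiva_reconstruction"
  )
}

#' Voxelwise SVD-shared cross-modal pattern
#'
#' For each voxel, stacks the two modalities' reconstructed N-vectors into a
#' 2 x N matrix and returns the top right-singular vector scaled by its
#' singular value: the shared cross-modal subject pattern. The sign is fixed
#' so the pattern correlates positively with the modality-1 row. A voxel
#' whose 2 x N block is all zero yields a zero row (flagged in the
#' `"zero_rows"` attribute).
#'
#' @param Xk1_hat,Xk2_hat V x N reconstructed matrices of one subspace in
#'   the two modalities.
#' @return V x N matrix of shared patterns.
#' @export
svd_shared <- function(Xk1_hat, Xk2_hat) {
  stop_if_not_matrix(Xk1_hat); stop_if_not_matrix(Xk2_hat)
  if (!all(dim(Xk1_hat) == dim(Xk2_hat))) stop("shapes must match")
  ## closed-form top eigenpair of the 2x2 matrix [[a, b], [b, c]] per voxel
  a <- rowSums(Xk1_hat^2)
  b <- rowSums(Xk1_hat * Xk2_hat)
  c_ <- rowSums(Xk2_hat^2)
  lam <- ((a + c_) + sqrt((a - c_)^2 + 4 * b^2)) / 2
  u1 <- b
  u2 <- lam - a
  ## degenerate off-diagonal: eigvec along the dominant axis
  axis_fix <- abs(b) < 1e-300
  u1[axis_fix] <- as.numeric(a[axis_fix] >= c_[axis_fix])
  u2[axis_fix] <- as.numeric(a[axis_fix] < c_[axis_fix])
  nrm <- sqrt(u1^2 + u2^2)
  zero <- nrm == 0 | lam == 0
  nrm[zero] <- 1
  u1 <- u1 / nrm; u2 <- u2 / nrm
  shared <- u1 * Xk1_hat + u2 * Xk2_hat     # = sigma * v1' per voxel
  flip <- rowSums(shared * Xk1_hat) < 0
  shared[flip, ] <- -shared[flip, , drop = FALSE]
  shared[zero, ] <- 0
  attr(shared, "zero_rows") <- which(zero)
  shared
}

#' Phenotype prediction from source features
#'
#' Ridge-penalized prediction of a phenotype from (post-CCA) sources:
#' 10-fold cross-validation on a stratified training split over the
#' regularization grid {0.1, 0.2, ..., 1}, refit on the full training set at
#' the selected penalty, evaluated on the holdout. Regression reports the
#' mean absolute error; classification (a ridge-penalized linear logistic
#' model) reports the balanced accuracy `0.5 * (TPR + TNR)`.
#'
#' @param features N x p numeric matrix.
#' @param target length-N numeric (regression) or two-level factor/vector
#'   (classification).
#' @param task `"regression"` or `"classification"`.
#' @param seed integer seed driving the stratified split and CV folds.
#' @param train_frac training fraction for the derived split (default 0.7).
#' @param holdout_idx optional explicit holdout indices (overrides the
#'   derived split, e.g. to mirror a fixed 2000/907 split).
#' @param lambda_grid regularization grid.
#' @return list with `metric` (`mae` or `balanced_accuracy`), `task`,
#'   `lambda`, `predictions`, `holdout_idx`.
#' @export
predict_phenotype <- function(features, target,
                              task = c("regression", "classification"),
                              seed = 1L, train_frac = 0.7,
                              holdout_idx = NULL,
                              lambda_grid = seq(0.1, 1, by = 0.1)) {
  task <- match.arg(task)
  features <- as.matrix(features)
  N <- nrow(features)
  if (length(target) != N) stop("target must have length N")

  if (task == "classification") {
    target <- factor(target)
    if (nlevels(target) != 2L) stop("classification needs exactly 2 classes")
  }
  strata <- if (task == "regression") {
    ## age-binned deciles for stratification
    cut(rank(target, ties.method = "first"),
        breaks = 10, labels = FALSE)
  } else {
    as.integer(target)
  }
  if (is.null(holdout_idx)) {
    holdout_idx <- with_seed(split_seed(seed, "split"), {
      unlist(lapply(split(seq_len(N), strata), function(ix) {
        n_hold <- max(1L, round(length(ix) * (1 - train_frac)))
        sample(ix, n_hold)
      }), use.names = FALSE)
    })
  }
  train_idx <- setdiff(seq_len(N), holdout_idx)
  if (task == "classification" &&
      length(unique(target[train_idx])) < 2L) {
    stop("training split contains a single class")
  }
  foldid <- integer(length(train_idx))
  with_seed(split_seed(seed, "cv"), {
    for (g in split(seq_along(train_idx), strata[train_idx])) {
      foldid[g] <- sample(rep_len(1:10, length(g)))
    }
  })
  family <- if (task == "regression") "gaussian" else "binomial"
  y_train <- if (task == "regression") target[train_idx] else
    as.numeric(target[train_idx]) - 1
  lam <- sort(lambda_grid, decreasing = TRUE)
  cvfit <- glmnet::cv.glmnet(features[train_idx, , drop = FALSE], y_train,
                             family = family, alpha = 0, lambda = lam,
                             foldid = foldid, standardize = TRUE,
                             type.measure = if (task == "regression")
                               "mae" else "class")
  fit <- glmnet::glmnet(features[train_idx, , drop = FALSE], y_train,
                        family = family, alpha = 0, lambda = lam,
                        standardize = TRUE)
  pred <- drop(stats::predict(fit, features[holdout_idx, , drop = FALSE],
                              s = cvfit$lambda.min,
                              type = if (task == "regression")
                                "response" else "class"))
  if (task == "regression") {
    metric <- mean(abs(pred - target[holdout_idx]))
    names(metric) <- "mae"
  } else {
    truth <- as.numeric(target[holdout_idx]) - 1
    pred <- as.numeric(pred)
    tpr <- mean(pred[truth == 1] == 1)
    tnr <- mean(pred[truth == 0] == 0)
    metric <- 0.5 * (tpr + tnr)
    names(metric) <- "balanced_accuracy"
  }
  list(metric = metric, task = task, lambda = cvfit$lambda.min,
       predictions = pred, holdout_idx = holdout_idx)
}
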