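#' Variance-normalize a feature matrix
#'
#' Standardizes each column (sample) to zero mean and unit standard
#' deviation, then removes the mean across samples from each row (feature).
#' This is the standard front-end applied to each modality before whitening.
#'
#' @param X V x N numeric matrix (features x samples).
#' @return matrix of the same shape.
#' @export
variance_normalize <- function(X) {
  stop_if_not_matrix(X)
  sds <- apply(X, 2, stats::sd)
  bad <- which(sds == 0)
  if (length(bad) > 0) {
    stop("zero-variance sample column(s): ", paste(bad, collapse = ", "))
  }
  X <- scale(X, center = TRUE, scale = sds)
  X <- X - rowMeans(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  X
}

#' Regress out site effects
#'
#' Projects each feature row onto the orthogonal complement of the design
#' `L = [1, one-hot site columns]`: `X <- X - X L (L'L)^- L'` (pseudo-inverse
#' for the rank-deficient intercept + full one-hot design).
#'
#' @param X V x N matrix.
#' @param site_labels length-N vector (factor, character or integer).
#' @return matrix with site means (and the grand mean) removed from each row.
#' @export
regress_site <- function(X, site_labels) {
  stop_if_not_matrix(X)
  if (length(site_labels) != ncol(X)) stop("site_labels must have length N")
  f <- if (is.factor(site_labels)) site_labels else factor(site_labels)
  counts <- table(f)
  if (any(counts == 0)) {
    stop("site(s) with zero samples: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  }
  L <- cbind(1, outer(as.integer(f), seq_along(levels(f)), `==`) * 1)
  P <- L %*% MASS::ginv(crossprod(L)) %*% t(L)
  X - X %*% P
}

new_whitening <- function(reduced, transform, eigenvalues, method) {
  structure(
    list(reduced = reduced, transform = transform,
         eigenvalues = eigenvalues, method = method),
    class = "msiva_whitening"
  )
}

#' @export
print.msiva_whitening <- function(x, ...) {
  cat("<msiva_whitening> method:", x$method,
      " C:", nrow(x$reduced), " N:", ncol(x$reduced), "\n")
  invisible(x)
}

## Fix the sign of each transform row so its largest-magnitude entry is
## positive; keeps results stable across BLAS implementations.
sign_fix <- function(W) {
  s <- apply(W, 1, function(r) sign(r[which.max(abs(r))]))
  s[s == 0] <- 1
  W * s
}

#' PCA whitening of one modality
#'
#' Projects `X` onto its top `C` principal directions and scales them so the
#' reduced data `Xr = transform %*% X` has identity sample covariance
#' (`Xr %*% t(Xr) / (N - 1) = I`). Input rows are expected to be demeaned
#' (see [variance_normalize()]); no centering is applied internally so that
#' the reported linear transform reproduces `reduced` exactly.
#'
#' @param X V x N matrix.
#' @param C number of components to retain; `C <= min(V, N - 1)`.
#' @return `msiva_whitening` with fields `reduced` (C x N), `transform`
#'   (C x V), `eigenvalues` (top-C covariance spectrum), `method = "pca"`.
#' @export
pca_whiten <- function(X, C) {
  stop_if_not_matrix(X)
  V <- nrow(X); N <- ncol(X)
  if (C > min(V, N - 1L)) stop("C must be <= min(V, N - 1)")
  G <- crossprod(X)                      # N x N Gram
  eg <- eigen(G, symmetric = TRUE)
  mu <- eg$values[seq_len(C)]
  if (any(mu < 1e-10 * eg$values[1])) {
    stop("requested components fall below the eigenvalue floor ",
         "(rank-deficient data); reduce C")
  }
  Q <- eg$vectors[, seq_len(C), drop = FALSE]
  W <- sign_fix(sqrt(N - 1) * (1 / mu) * t(X %*% Q))   # C x V
  new_whitening(
    reduced = W %*% X,
    transform = W,
    eigenvalues = mu / (N - 1),
    method = "pca"
  )
}

#' Multimodal group PCA (MGPCA) whitening
#'
#' Finds directions of maximal *common* variation across modalities: the
#' average of the per-modality Gram matrices, each scaled by its total
#' variance, `Sigma_avg = (1/M) sum_m N X[m]'X[m] / ||X[m]||_F^2`, is
#' eigendecomposed once; its top-C eigenvectors Q define shared sample-space
#' components. Each modality is then whitened against its own variance along
#' those shared directions, so the per-modality reduced data has
#' approximately unit-variance rows (exactly unit, and identical to
#' [pca_whiten()] up to sign, when M = 1).
#'
#' @param Xs list of V x N matrices (equal N; V may differ).
#' @param C components to retain, `C <= N - 1`.
#' @return list of `msiva_whitening` (method `"mgpca"`), one per modality;
#'   all share the `eigenvalues` of `Sigma_avg`.
#' @export
mgpca_whiten <- function(Xs, C) {
  stopifnot(is.list(Xs), length(Xs) >= 1L)
  lapply(Xs, stop_if_not_matrix, name = "Xs[[m]]")
  Ns <- vapply(Xs, ncol, 1L)
  if (length(unique(Ns)) != 1L) stop("all modalities must share N")
  N <- Ns[1]
  if (C > N - 1L) stop("C must be <= N - 1")
  M <- length(Xs)

  Gs <- lapply(Xs, crossprod)            # N x N per modality
  fr2 <- vapply(Gs, function(G) sum(diag(G)), 1.0)
  Sigma_avg <- Reduce(`+`, Map(function(G, f) N * G / f, Gs, fr2)) / M
  eg <- eigen(Sigma_avg, symmetric = TRUE)
  lam <- eg$values[seq_len(C)]
  if (any(lam < 1e-10 * eg$values[1])) {
    stop("requested components fall below the eigenvalue floor ",
         "(rank-deficient common subspace); reduce C")
  }
  Q <- eg$vectors[, seq_len(C), drop = FALSE]

  lapply(seq_len(M), function(m) {
    B <- Gs[[m]] %*% Q                   # N x C
    mu <- colSums(Q * B)                 # modality variance along each q_i
    if (any(mu < 1e-10 * max(mu))) {
      stop("modality ", m, " has (near-)zero variance along a common ",
           "direction; reduce C")
    }
    W <- sign_fix(sqrt(N - 1) * (1 / mu) * t(Xs[[m]] %*% Q))  # C x V
    red <- W %*% Xs[[m]]
    ## exact unit-variance rows (the 1/mu scaling is exact only at M = 1,
    ## where the common directions are this modality's own eigenvectors)
    sdv <- sqrt(rowSums((red - rowMeans(red))^2) / (N - 1))
    W <- W / sdv
    new_whitening(
      reduced = red / sdv,
      transform = W,
      eigenvalues = lam,
      method = "mgpca"
    )
  })
}
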