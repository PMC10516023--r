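#' Build the confound design for brain-age delta correction
#'
#' Ten demeaned columns: linear, quadratic and cubic age, sex, the
#' interaction of sex with each age term, the framewise-displacement motion
#' summary, and the two spatial-normalization covariates (one per imaging
#' modality).
#'
#' @param age length-N chronological age in years.
#' @param sex length-N numeric or two-level coding.
#' @param motion length-N framewise displacement.
#' @param norm_vars N x 2 matrix of spatial normalization covariates.
#' @return N x 10 matrix `Y`, every column demeaned.
#' @export
build_confounds <- function(age, sex, motion, norm_vars) {
  need <- c(age = missing(age), sex = missing(sex), motion = missing(motion),
            norm_vars = missing(norm_vars))
  if (any(need)) stop("missing confound input(s): ",
                      paste(names(need)[need], collapse = ", "))
  N <- length(age)
  sex <- as.numeric(sex)
  motion <- as.numeric(motion)
  norm_vars <- as.matrix(norm_vars)
  if (length(sex) != N || length(motion) != N || nrow(norm_vars) != N) {
    stop("all confound inputs must have length N")
  }
  if (ncol(norm_vars) != 2L) stop("norm_vars must have 2 columns")
  a <- age - mean(age)
  sx <- sex - mean(sex)
  age_terms <- cbind(a, a^2, a^3)
  Y <- cbind(age_terms, sx, sx * age_terms, motion, norm_vars)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  attr(Y, "scaled:center") <- NULL
  colnames(Y) <- c("age", "age2", "age3", "sex",
                   "sex_age", "sex_age2", "sex_age3",
                   "motion", "norm_smri", "norm_fmri")
  Y
}

## least-squares coefficients with a ridge fallback for collinearity
ls_beta <- function(X, y, warn_label = "predictors") {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("collinear ", warn_label, "; ridge (1e-8) fallback")
    return(drop(solve(crossprod(X) + 1e-8 * diag(ncol(X)), crossprod(X, y))))
  }
  drop(qr.coef(qx, y))
}

#' Stage 1: initial voxelwise brain-age delta
#'
#' Regresses demeaned chronological age on the voxel's predictor matrix and
#' forms the initial delta `delta1 = Xhat %*% beta1 - y` (model-predicted
#' minus true age).
#'
#' @param Xhat_i N x p predictor matrix for one voxel (column-demeaned).
#' @param y length-N demeaned age.
#' @return list with `beta1` (length p), `delta1` (length N), and
#'   `contributions` (N x p columnwise predictor contributions
#'   `Xhat_i[, j] * beta1[j]`, used by the stage-2 breakdown).
#' @export
delta_stage1 <- function(Xhat_i, y) {
  Xhat_i <- as.matrix(Xhat_i)
  if (nrow(Xhat_i) != length(y)) stop("Xhat_i and y disagree on N")
  beta1 <- ls_beta(Xhat_i, y, "age predictors")
  contributions <- Xhat_i * rep(beta1, each = nrow(Xhat_i))
  list(beta1 = beta1,
       delta1 = drop(Xhat_i %*% beta1) - y,
       contributions = contributions)
}

#' Stage 2: confound-corrected and partialized delta
#'
#' Removes age dependence and confounds from the initial delta,
#' `delta2 = delta1 - Y %*% beta2`, and produces a per-predictor breakdown:
#' each predictor's stage-1 contribution is confound-residualized the same
#' way, then partialized by residualizing it on all the *other* predictors'
#' corrected contributions, yielding `delta2p` per predictor.
#'
#' @param delta1 length-N initial delta.
#' @param Y N x k confound design from [build_confounds()].
#' @param contributions optional N x p stage-1 contributions; when supplied,
#'   `delta2p` (N x p) is returned.
#' @return list with `beta2`, `delta2`, and (given contributions) `delta2p`.
#' @export
delta_stage2 <- function(delta1, Y, contributions = NULL) {
  Y <- as.matrix(Y)
  if (nrow(Y) != length(delta1)) stop("Y and delta1 disagree on N")
  ## QR for the (usual) full-rank case; Moore-Penrose pseudo-inverse of Z
  ## itself (not of Z'Z, which squares the condition number) otherwise
  resid_on <- function(v, Z) {
    b <- tryCatch(ls_beta(Z, v, "confounds"),
                  warning = function(w) drop(MASS::ginv(Z) %*% v))
    v - drop(Z %*% b)
  }
  beta2 <- tryCatch(ls_beta(Y, delta1, "confound design"),
                    warning = function(w) {
                      warning("rank-deficient confound design; ",
                              "pseudo-inverse fit")
                      drop(MASS::ginv(Y) %*% delta1)
                    })
  delta2 <- delta1 - drop(Y %*% beta2)
  out <- list(beta2 = beta2, delta2 = delta2)
  if (!is.null(contributions)) {
    contributions <- as.matrix(contributions)
    corrected <- apply(contributions, 2, resid_on, Z = Y)
    corrected <- matrix(corrected, nrow = nrow(Y))
    p <- ncol(corrected)
    delta2p <- corrected
    if (p > 1L) {
      for (j in seq_len(p)) {
        others <- corrected[, -j, drop = FALSE]
        if (stats::sd(delta2p[, j]) > 0 && any(apply(others, 2, stats::sd) > 0)) {
          delta2p[, j] <- resid_on(corrected[, j], others)
        }
      }
    }
    out$delta2p <- delta2p
  }
  out
}

#' Voxelwise two-stage delta pipeline
#'
#' Applies [delta_stage1()] and [delta_stage2()] at every voxel of a set of
#' predictor maps (e.g. SVD-shared patterns per cross-modal subspace,
#' reconstructed sMRI patterns, unimodal reconstructions).
#'
#' @param predictors list of p V x N matrices, one per predictor; voxel i's
#'   predictor matrix stacks row i of each.
#' @param age length-N chronological age (demeaned internally).
#' @param Y N x k confound design.
#' @return `msiva_delta`: `beta1` (V x p), `delta1`, `delta2` (V x N),
#'   `delta2p` (list of p V x N matrices), `predictor_names`.
#' @export
delta_pipeline <- function(predictors, age, Y) {
  stopifnot(is.list(predictors), length(predictors) >= 1L)
  Vn <- vapply(predictors, nrow, 1L)
  if (length(unique(Vn)) != 1L) stop("predictor maps must share V")
  V <- Vn[1]
  N <- ncol(predictors[[1]])
  if (length(age) != N) stop("age must have length N")
  y <- age - mean(age)
  p <- length(predictors)
  beta1 <- matrix(NA_real_, V, p)
  delta1 <- matrix(NA_real_, V, N)
  delta2 <- matrix(NA_real_, V, N)
  delta2p <- lapply(seq_len(p), function(j) matrix(NA_real_, V, N))
  names(delta2p) <- names(predictors) %||% paste0("predictor", seq_len(p))
  for (i in seq_len(V)) {
    Xi <- vapply(predictors, function(P) P[i, ], numeric(N))
    Xi <- scale(Xi, center = TRUE, scale = FALSE)
    s1 <- delta_stage1(Xi, y)
    s2 <- delta_stage2(s1$delta1, Y, s1$contributions)
    beta1[i, ] <- s1$beta1
    delta1[i, ] <- s1$delta1
    delta2[i, ] <- s2$delta2
    for (j in seq_len(p)) delta2p[[j]][i, ] <- s2$delta2p[, j]
  }
  structure(
    list(beta1 = beta1, delta1 = delta1, delta2 = delta2,
         delta2p = delta2p,
         predictor_names = names(predictors) %||%
           paste0("predictor", seq_len(p))),
    class = "msiva_delta"
  )
}

#' Correlate partialized deltas with phenotypes
#'
#' Pearson correlation between each predictor's partialized delta map and
#' each phenotype across subjects, with Benjamini-Hochberg FDR correction
#' over the full flattened voxels x phenotypes x predictors family.
#'
#' @param delta2p list of p V x N partialized delta maps (or one matrix).
#' @param phenotypes N x P data.frame or matrix; constant columns are
#'   excluded with a warning.
#' @param q FDR level (default 0.05).
#' @return list with arrays `r` and `qvalue` (V x P x p), logical
#'   `significant`, and `counts` (P x p significant-voxel counts).
#' @export
correlate_phenotypes <- function(delta2p, phenotypes, q = 0.05) {
  if (is.matrix(delta2p)) delta2p <- list(delta2p)
  phenotypes <- as.matrix(phenotypes)
  N <- ncol(delta2p[[1]])
  if (nrow(phenotypes) != N) stop("phenotypes must have N rows")
  keep <- apply(phenotypes, 2, stats::sd) > 0
  if (!all(keep)) {
    warning("excluding constant phenotype(s): ",
            paste(colnames(phenotypes)[!keep], collapse = ", "))
    phenotypes <- phenotypes[, keep, drop = FALSE]
  }
  P <- ncol(phenotypes)
  J <- length(delta2p)
  V <- nrow(delta2p[[1]])
  r <- array(NA_real_, dim = c(V, P, J),
             dimnames = list(NULL, colnames(phenotypes), names(delta2p)))
  for (j in seq_len(J)) {
    r[, , j] <- stats::cor(t(delta2p[[j]]), phenotypes)
  }
  tstat <- r * sqrt((N - 2) / pmax(1 - r^2, 1e-300))
  pval <- 2 * stats::pt(-abs(tstat), df = N - 2)
  qvalue <- array(stats::p.adjust(pval, method = "BH"), dim = dim(pval),
                  dimnames = dimnames(r))
  significant <- qvalue < q
  counts <- apply(significant, c(2, 3), sum)
  list(r = r, qvalue = qvalue, significant = significant, counts = counts,
       n_tests = length(pval))
}

#' Build the standard delta predictor set from a fitted model
#'
#' For each cross-modal subspace: the voxelwise SVD-shared pattern of the
#' two modalities' reconstructions and the reconstructed modality-1 (sMRI)
#' pattern; plus the reconstructed data of every unimodal subspace. Under
#' the five-2D-block structure this yields the 5 + 5 + 4 = 14 predictors
#' used in the voxelwise analysis; the layout is derived from the fitted
#' structure, not hard-coded.
#'
#' @param model `msiva_model` (M = 2).
#' @param recon optional precomputed [reconstruct()] result.
#' @return named list of V x N predictor matrices.
#' @export
delta_predictors <- function(model, recon = reconstruct(model)) {
  stopifnot(inherits(model, "msiva_model"))
  if (length(model$S) != 2L) stop("predictor layout requires M = 2")
  blocks <- recon$blocks
  preds <- list()
  for (k in seq_along(blocks)) {
    if (blocks[[k]]$type == "linked") {
      preds[[paste0("svd_shared_", length(preds) + 1L)]] <-
        svd_shared(recon$X_hat[[k]][[1]], recon$X_hat[[k]][[2]])
    }
  }
  i <- 0L
  for (k in seq_along(blocks)) {
    if (blocks[[k]]$type == "linked") {
      i <- i + 1L
      preds[[paste0("smri_linked_", i)]] <- recon$X_hat[[k]][[1]]
    }
  }
  i <- 0L
  for (m in 1:2) {
    for (k in seq_along(blocks)) {
      if (blocks[[k]]$type == "unimodal") {
        i <- i + 1L
        preds[[paste0("unimodal_", i)]] <- recon$X_hat[[k]][[m]]
      }
    }
  }
  preds
}
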