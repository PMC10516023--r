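## Moreau-Amari index of a nonnegative aggregation matrix H. For square H
## (K x K) this is the classical normalization 1/(2K(K-1)) [...]: 0 at a
## scaled block permutation, 1 for uniform interference. When the estimated
## and generating structures have different subspace counts (K1 x K2, the
## off-diagonal cells of a structure grid) each directional term is
## normalized by its own worst case so the index stays in [0, 1] and reduces
## to the classical form at K1 = K2.
isi_from_H <- function(H) {
  K1 <- nrow(H)
  K2 <- ncol(H)
  if (K1 < 2L || K2 < 2L) return(0)
  rmax <- apply(H, 1, max)
  cmax <- apply(H, 2, max)
  if (any(rmax == 0) || any(cmax == 0)) {
    stop("H has an all-zero row or column; not a valid solution")
  }
  0.5 * (sum(rowSums(H) / rmax - 1) / (K1 * (K2 - 1)) +
           sum(colSums(H) / cmax - 1) / (K2 * (K1 - 1)))
}

#' Interference report and multidataset ISI
#'
#' Computes the per-modality interference matrices `W_hat[m] %*% A[m]`
#' (composite unmixing times ground-truth mixing), aggregates their absolute
#' entries into subspace blocks via the estimated (rows) and ground-truth
#' (columns) assignment matrices over the stacked, block-diagonal
#' multidataset interference, and evaluates the normalized Moreau-Amari
#' intersymbol interference. 0 means perfect recovery up to permutation and
#' scale; 1 means uniform interference.
#'
#' @param model `msiva_model`.
#' @param truth_A list of per-modality ground-truth V x C mixing matrices.
#' @param truth_structure `msiva_structure` used to generate the data.
#' @return `msiva_interference`: list with `WA` (per-modality C x C
#'   interference), `H` (aggregated K x K), `isi`, `per_modality_isi`.
#' @export
interference <- function(model, truth_A, truth_structure) {
  stopifnot(inherits(model, "msiva_model"),
            inherits(truth_structure, "msiva_structure"))
  M <- length(model$composite)
  if (length(truth_A) != M) stop("truth_A must have one matrix per modality")
  C <- model$structure$C
  if (truth_structure$C != C) stop("estimated and true C differ")
  WA <- Map(function(Wc, A) {
    if (ncol(Wc) != nrow(A)) stop("shape mismatch between transform and mixing")
    Wc %*% A
  }, model$composite, truth_A)

  ## stacked block-diagonal multidataset interference
  G <- matrix(0, M * C, M * C)
  for (m in seq_len(M)) {
    rows <- (m - 1L) * C + seq_len(C)
    G[rows, rows] <- abs(WA[[m]])
  }
  idx_est <- subspace_indices(model$structure)
  idx_gt <- subspace_indices(truth_structure)
  H <- matrix(0, length(idx_est), length(idx_gt))
  for (i in seq_along(idx_est)) {
    for (j in seq_along(idx_gt)) {
      H[i, j] <- sum(G[idx_est[[i]], idx_gt[[j]], drop = FALSE])
    }
  }

  per_mod <- vapply(seq_len(M), function(m) {
    bi_est <- modality_block_indices(model$structure)
    bi_gt <- modality_block_indices(truth_structure)
    Hm <- matrix(0, length(bi_est), length(bi_gt))
    Am <- abs(WA[[m]])
    for (i in seq_along(bi_est)) {
      for (j in seq_along(bi_gt)) {
        Hm[i, j] <- sum(Am[bi_est[[i]], bi_gt[[j]], drop = FALSE])
      }
    }
    isi_from_H(Hm)
  }, 1.0)

  structure(
    list(WA = WA, H = H, isi = isi_from_H(H), per_modality_isi = per_mod),
    class = "msiva_interference"
  )
}

## within-modality block index list (linked blocks + that modality's
## unimodal blocks), on 1..C indices
modality_block_indices <- function(s) {
  lapply(structure_index_map(s), `[[`, "idx")
}

#' @export
print.msiva_interference <- function(x, ...) {
  cat("<msiva_interference> ISI:", format(x$isi, digits = 4),
      " per-modality:", paste(format(x$per_modality_isi, digits = 4),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Mean correlation coefficient over cross-modal subspaces
#'
#' Two-stage summary balancing subspaces of different dimensions: within
#' each cross-modal subspace k the aggregate is
#' `(1/(2 d_k)) * sum_i (max_j |R_k[i, j]| + max_j |R_k[j, i]|)`, and the MCC
#' is the mean of the aggregates over the K cross-modal subspaces.
#'
#' @param R_blocks list of per-subspace d_k x d_k cross-modal correlation
#'   matrices.
#' @param dims optional integer vector of subspace dimensions d_k; defaults
#'   to the block sizes (they must agree when supplied).
#' @return scalar in \[0, 1\] for correlation inputs.
#' @export
mcc <- function(R_blocks, dims = NULL) {
  if (length(R_blocks) == 0L) stop("empty block list")
  sizes <- vapply(R_blocks, nrow, 1L)
  if (is.null(dims)) dims <- sizes
  if (!all(dims == sizes)) {
    stop("subspace dims and correlation block sizes disagree")
  }
  agg <- mapply(function(R, d) {
    R <- abs(R)
    (sum(apply(R, 1, max)) + sum(apply(R, 2, max))) / (2 * d)
  }, R_blocks, dims)
  mean(agg)
}

#' Cross-modal Pearson correlation matrix
#'
#' Entry (i, j) is the Pearson correlation between source i of modality 1
#' and source j of modality 2.
#'
#' @param S1,S2 C x N source matrices with equal N.
#' @return C x C correlation matrix.
#' @export
cross_modal_pearson <- function(S1, S2) {
  stop_if_not_matrix(S1); stop_if_not_matrix(S2)
  if (ncol(S1) != ncol(S2)) stop("sources must share N")
  if (any(apply(S1, 1, stats::sd) == 0) || any(apply(S2, 1, stats::sd) == 0)) {
    stop("zero-variance source row")
  }
  stats::cor(t(S1), t(S2))
}

#' Per-subspace cross-modal correlation blocks of a fitted model
#'
#' @param model `msiva_model` with M = 2.
#' @return list of d_k x d_k Pearson blocks, one per linked subspace.
#' @export
cross_modal_blocks <- function(model) {
  stopifnot(inherits(model, "msiva_model"))
  if (length(model$S) != 2L) stop("cross-modal blocks require M = 2")
  R <- cross_modal_pearson(model$S[[1]], model$S[[2]])
  blocks <- structure_index_map(model$structure)
  out <- list()
  for (b in blocks) {
    if (b$type == "linked") {
      out[[length(out) + 1L]] <- R[b$idx, b$idx, drop = FALSE]
    }
  }
  out
}

#' Randomized dependence coefficient
#'
#' Nonlinear dependence between two samples: both variables are
#' copula-transformed (empirical ranks / N), lifted with random sinusoidal
#' features (`sin` of Gaussian random projections of the rank and an
#' intercept), and the top canonical correlation between the two feature
#' sets is returned. Deterministic given `seed`.
#'
#' @param x,y numeric vectors of equal length N >= 20.
#' @param n_features random features per variable (default 5).
#' @param scale standard deviation of the random projection weights
#'   (default 1/6).
#' @param seed integer seed for the random features.
#' @return scalar in \[0, 1\].
#' @export
rdc <- function(x, y, n_features = 5L, scale = 1 / 6, seed = 1L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  N <- length(x)
  if (N < 20L) stop("need N >= 20")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  fx <- rdc_features(x, n_features, scale, split_seed(seed, "rdc"))
  fy <- rdc_features(y, n_features, scale, split_seed(seed, "rdc") + 1L)
  cc <- cca_top(fx, fy, ridge = 1e-8)
  min(1, max(0, cc$cor))
}

rdc_features <- function(x, k, scale, seed) {
  N <- length(x)
  P <- cbind(rank(x, ties.method = "average") / N, 1)
  Wr <- with_seed(seed, matrix(stats::rnorm(2 * k, sd = scale), 2, k))
  sin(P %*% Wr)
}

#' Permutation null quantile for the RDC
#'
#' @param x,y as in [rdc()].
#' @param n_perm number of permutations (default 100).
#' @param probs quantile(s) of the null distribution to return.
#' @inheritParams rdc
#' @return numeric quantile(s) of RDC under independent pairing.
#' @export
rdc_null_quantile <- function(x, y, n_perm = 100L, probs = 0.95,
                              n_features = 5L, scale = 1 / 6, seed = 1L) {
  perms <- with_seed(split_seed(seed, "perm"), {
    replicate(n_perm, sample.int(length(y)))
  })
  vals <- vapply(seq_len(n_perm), function(b) {
    rdc(x, y[perms[, b]], n_features = n_features, scale = scale,
        seed = seed + b)
  }, 1.0)
  stats::quantile(vals, probs = probs, names = FALSE)
}
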