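#' Generate a synthetic multimodal dataset
#'
#' Draws latent sources realizing a given subspace structure and mixes them
#' into observed data `X[m] = A[m] %*% S[m]` (noiseless). Each subspace is an
#' independent draw from a multivariate Laplace distribution constructed as a
#' Gaussian scale mixture: a correlated multivariate normal, all of whose
#' coordinates (across modalities, for a linked block) share one
#' exponential-scale mixing variable, so sources within a subspace are
#' dependent even when uncorrelated. Within linked block k, the i-th source
#' of each modality pair has target Pearson correlation drawn uniformly from
#' `[corr_low, corr_high]`; the scale mixture preserves the Gaussian
#' correlation in population, so no further calibration is applied.
#' Unimodal sources are independent univariate Laplace. All sources are
#' standardized to zero mean, unit variance; mixing matrices have i.i.d.
#' standard-normal entries (redrawn if condition number exceeds 1e6).
#'
#' @param s `msiva_structure` (see [make_candidate()]).
#' @param V features per modality (voxels); default 20000.
#' @param N samples (subjects); default 3000.
#' @param corr_low,corr_high cross-modal correlation range for linked pairs;
#'   defaults 0.65 and 0.85.
#' @param seed integer seed; the dataset is bit-reproducible from it.
#' @param full_block_corr if `TRUE`, correlate every cross-modal source pair
#'   within a linked block at the drawn target (not just same-index pairs).
#' @return `msiva_dataset`: list with `X` (per-modality V x N), `A`
#'   (V x C mixing), `S` (C x N ground-truth sources), `structure`,
#'   `target_corr` (per linked block, the drawn pair correlations), `seed`.
#' @examples
#' d <- generate_multimodal(make_candidate("S2"), V = 50, N = 200, seed = 1)
#' dim(d$X[[1]])
#' @export
generate_multimodal <- function(s, V = 20000L, N = 3000L,
                                corr_low = 0.65, corr_high = 0.85,
                                seed = 1L, full_block_corr = FALSE) {
  stopifnot(inherits(s, "msiva_structure"))
  if (V < s$C) stop("V must be >= C (", s$C, " sources)")
  if (N < 2L) stop("N must be >= 2")
  if (!(corr_low >= 0 && corr_low <= corr_high)) {
    stop("need 0 <= corr_low <= corr_high")
  }
  if (corr_high >= 1) stop("corr_high must be < 1")
  M <- s$M
  C <- s$C
  blocks <- structure_index_map(s)

  with_seed(split_seed(seed, "generate"), {
    S <- lapply(seq_len(M), function(m) matrix(0, C, N))
    target_corr <- list()
    for (b in blocks) {
      if (b$type == "linked") {
        d <- b$d
        rho <- stats::runif(d, corr_low, corr_high)
        target_corr[[length(target_corr) + 1L]] <- rho
        ## covariance of the stacked (M*d)-vector: identity within modality,
        ## same-index (or full-block) cross-modal correlation rho
        D <- M * d
        Sigma <- diag(D)
        for (m1 in seq_len(M - 1L)) {
          for (m2 in seq.int(m1 + 1L, M)) {
            for (i in seq_len(d)) {
              jj <- if (full_block_corr) seq_len(d) else i
              for (j in jj) {
                r <- if (i == j) rho[i] else mean(rho)
                Sigma[(m1 - 1L) * d + i, (m2 - 1L) * d + j] <- r
                Sigma[(m2 - 1L) * d + j, (m1 - 1L) * d + i] <- r
              }
            }
          }
        }
        Z <- rmv_laplace(N, Sigma)           # D x N
        for (m in seq_len(M)) {
          S[[m]][b$idx, ] <- Z[(m - 1L) * d + seq_len(d), , drop = FALSE]
        }
      } else {
        ## one independent univariate Laplace source per modality
        for (m in seq_len(M)) {
          S[[m]][b$idx, ] <- rmv_laplace(N, diag(1))
        }
      }
    }
    S <- lapply(S, standardize_rows)
  })

  A <- with_seed(split_seed(seed, "mixing"), {
    lapply(seq_len(M), function(m) {
      for (try in 1:50) {
        Am <- matrix(stats::rnorm(V * C), V, C)
        if (kappa(Am, exact = FALSE) < 1e6) return(Am)
      }
      stop("could not draw a well-conditioned mixing matrix")
    })
  })

  X <- lapply(seq_len(M), function(m) A[[m]] %*% S[[m]])
  structure(
    list(X = X, A = A, S = S, structure = s, target_corr = target_corr,
         site_labels = NULL, phenotypes = NULL, seed = seed),
    class = "msiva_dataset"
  )
}

## Multivariate Laplace via Gaussian scale mixture: sqrt(E) * Z with
## E ~ Exp(1) shared across coordinates, Z ~ N(0, Sigma). Marginals are
## Laplace; Pearson correlations equal Sigma's in population.
rmv_laplace <- function(N, Sigma) {
  D <- nrow(Sigma)
  L <- chol(Sigma)
  Z <- t(L) %*% matrix(stats::rnorm(D * N), D, N)
  e <- stats::rexp(N)
  Z * rep(sqrt(e), each = D)
}

#' @export
print.msiva_dataset <- function(x, ...) {
  cat("<msiva_dataset> ", x$structure$name, "\n", sep = "")
  cat("  modalities:", length(x$X),
      " V:", paste(vapply(x$X, nrow, 1L), collapse = "/"),
      " N:", ncol(x$X[[1]]), "\n")
  cat("  ground truth:", if (is.null(x$A)) "absent" else "present", "\n")
  invisible(x)
}

#' Assemble a dataset from user matrices
#'
#' @param X list of per-modality V x N matrices (equal N).
#' @param structure optional `msiva_structure`.
#' @param A,S optional ground-truth mixing/source matrices.
#' @param site_labels optional length-N vector of site labels.
#' @param phenotypes optional data.frame with N rows.
#' @return `msiva_dataset`.
#' @export
as_msiva_dataset <- function(X, structure = NULL, A = NULL, S = NULL,
                             site_labels = NULL, phenotypes = NULL) {
  lapply(X, stop_if_not_matrix, name = "X[[m]]")
  Ns <- vapply(X, ncol, 1L)
  if (length(unique(Ns)) != 1L) stop("all modalities must share N")
  if (!is.null(site_labels) && length(site_labels) != Ns[1]) {
    stop("site_labels must have length N")
  }
  structure(
    list(X = X, A = A, S = S, structure = structure,
         target_corr = NULL, site_labels = site_labels,
         phenotypes = phenotypes, seed = NA_integer_),
    class = "msiva_dataset"
  )
}
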