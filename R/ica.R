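#' Infomax ICA
#'
#' Batch natural-gradient Infomax with the logistic nonlinearity, initialized
#' at the identity. The learning rate anneals (x 0.9, step reverted) whenever
#' the Infomax log-likelihood decreases. Components are returned in a
#' canonical deterministic order (descending excess-kurtosis magnitude),
#' sign-fixed so each source has positive skewness, and row-scaled so every
#' source has unit variance.
#'
#' @param Xr C x N whitened matrix.
#' @param seed kept for interface symmetry; the algorithm is deterministic
#'   (identity initialization, batch updates).
#' @param max_iter maximum full-data passes.
#' @param tol convergence tolerance on the relative weight change.
#' @param lrate initial learning rate (annealed x0.9 on any objective
#'   decrease, so a fairly aggressive default is safe in batch mode).
#' @return list with `W` (C x C unmixing), `S` (C x N unit-variance sources),
#'   `iterations`, `converged`, `final_change`.
#' @export
infomax_ica <- function(Xr, seed = 1L, max_iter = 512L, tol = 1e-7,
                        lrate = 0.2) {
  stop_if_not_matrix(Xr)
  C <- nrow(Xr)
  N <- ncol(Xr)
  W <- diag(C)
  obj_prev <- -Inf
  change <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Y <- W %*% Xr
    g <- stats::plogis(Y)
    obj <- determinant(W)$modulus[1] +
      sum(rowMeans(log(pmax(g * (1 - g), 1e-300))))
    if (obj < obj_prev) {
      ## overshoot: revert and anneal
      W <- W_prev
      lrate <- lrate * 0.9
      if (lrate < 1e-10) break
      next
    }
    W_prev <- W
    obj_prev <- obj
    delta <- lrate * (diag(C) + ((1 - 2 * g) %*% t(Y)) / N) %*% W
    W <- W + delta
    if (!all(is.finite(W)) || max(abs(W)) > 1e8) {
      stop("Infomax diverged (weight blow-up); try a smaller learning rate")
    }
    change <- sqrt(sum(delta^2)) / sqrt(sum(W^2))
    if (change < tol) break
  }
  ## canonical order, sign and scale
  Y <- W %*% Xr
  W <- order_components(W, Y)
  Y <- W %*% Xr
  sdv <- sqrt(rowSums((Y - rowMeans(Y))^2) / (N - 1))
  W <- W / sdv
  list(W = W, S = W %*% Xr, iterations = iter,
       converged = change < tol, final_change = change)
}

## Deterministic component ordering: descending |excess kurtosis|, sign set
## so skewness is positive (ICA is permutation/sign ambiguous).
order_components <- function(W, Y) {
  Yc <- Y - rowMeans(Y)
  m2 <- rowMeans(Yc^2)
  kurt <- rowMeans(Yc^4) / m2^2 - 3
  skew <- rowMeans(Yc^3) / m2^1.5
  W <- W[order(-abs(kurt)), , drop = FALSE]
  skew <- skew[order(-abs(kurt))]
  s <- ifelse(skew < 0, -1, 1)
  W * s
}

#' Refine an ICA solution with the subspace loss
#'
#' Runs the numerical optimizer on a single modality with the all-1D-blocks
#' structure (plain ICA as a one-modality subspace model), initialized at the
#' Infomax solution. The refined loss never exceeds the initial loss.
#'
#' @param Xr C x N reduced data.
#' @param W_infomax C x C initialization.
#' @param kp `msiva_kotz`.
#' @param max_iter L-BFGS cap.
#' @return list with `W`, `loss`, `initial_loss`.
#' @export
refine_with_misa_ica <- function(Xr, W_infomax, kp = kotz_params(),
                                 max_iter = 200L) {
  C <- nrow(W_infomax)
  s1 <- subspace_structure(rep(1L, C), unimodal = 0L, M = 1L,
                           name = "ica-1d")
  res <- numerical_optimize(list(W_infomax), list(Xr), s1, kp,
                            max_iter = max_iter)
  list(W = res$W[[1]], loss = res$loss, initial_loss = res$initial_loss)
}

#' Group ICA over MGPCA-reduced modalities
#'
#' Runs [infomax_ica()] on the element-wise sum of the per-modality reduced
#' data; the single resulting unmixing matrix is shared by every modality.
#'
#' @param Xr_list list of equal-shape C x N reduced matrices.
#' @inheritParams infomax_ica
#' @return as [infomax_ica()].
#' @export
group_ica <- function(Xr_list, seed = 1L, max_iter = 512L, tol = 1e-7,
                      lrate = 0.2) {
  stopifnot(is.list(Xr_list), length(Xr_list) >= 1L)
  dims <- vapply(Xr_list, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all reduced modalities must share the same shape")
  }
  infomax_ica(Reduce(`+`, Xr_list), seed = seed, max_iter = max_iter,
              tol = tol, lrate = lrate)
}

#' Build an initialization for the subspace model
#'
#' Assembles one of the three initialization workflows into per-modality
#' composite transforms `W0[m] = W_ica[m] %*% W_whiten[m]`:
#' \describe{
#'   \item{unimodal}{separate PCA whitening + separate Infomax per modality}
#'   \item{msiva}{MGPCA whitening + separate Infomax per modality, each
#'     refined by the one-modality subspace loss}
#'   \item{multimodal}{MGPCA whitening + group ICA shared across modalities}
#' }
#'
#' @param data `msiva_dataset`.
#' @param C number of sources per modality.
#' @param workflow `"unimodal"`, `"msiva"` or `"multimodal"`.
#' @param seed integer seed.
#' @param kp `msiva_kotz` (used by the msiva refinement stage).
#' @param ica_max_iter,ica_tol Infomax controls.
#' @return `msiva_init`: list with `W0` (per-modality C x V), `ica_unmixing`
#'   (per-modality C x C), `whitening` (per-modality `msiva_whitening`),
#'   `workflow`, `convergence_log`.
#' @export
build_init <- function(data, C, workflow = c("msiva", "unimodal", "multimodal"),
                       seed = 1L, kp = kotz_params(),
                       ica_max_iter = 512L, ica_tol = 1e-7) {
  stopifnot(inherits(data, "msiva_dataset"))
  workflow <- match.arg(workflow)
  X <- data$X
  M <- length(X)
  ica_seed <- split_seed(seed, "ica")
  log <- list()

  if (workflow == "unimodal") {
    wh <- lapply(X, pca_whiten, C = C)
    ica <- lapply(wh, function(w) {
      infomax_ica(w$reduced, seed = ica_seed,
                  max_iter = ica_max_iter, tol = ica_tol)
    })
    unmix <- lapply(ica, `[[`, "W")
    log$infomax <- lapply(ica, function(r)
      r[c("iterations", "converged", "final_change")])
  } else {
    wh <- mgpca_whiten(X, C = C)
    if (workflow == "msiva") {
      ica <- lapply(wh, function(w) {
        infomax_ica(w$reduced, seed = ica_seed,
                    max_iter = ica_max_iter, tol = ica_tol)
      })
      log$infomax <- lapply(ica, function(r)
        r[c("iterations", "converged", "final_change")])
      ref <- Map(function(w, r) refine_with_misa_ica(w$reduced, r$W, kp = kp),
                 wh, ica)
      unmix <- lapply(ref, `[[`, "W")
      log$misa_ica <- lapply(ref, function(r)
        r[c("loss", "initial_loss")])
    } else {
      g <- group_ica(lapply(wh, `[[`, "reduced"), seed = ica_seed,
                     max_iter = ica_max_iter, tol = ica_tol)
      unmix <- rep(list(g$W), M)
      log$infomax <- g[c("iterations", "converged", "final_change")]
    }
  }

  W0 <- Map(function(u, w) u %*% w$transform, unmix, wh)
  structure(
    list(W0 = W0, ica_unmixing = unmix, whitening = wh,
         workflow = workflow, convergence_log = log, seed = seed),
    class = "msiva_init"
  )
}

#' @export
print.msiva_init <- function(x, ...) {
  cat("<msiva_init> workflow:", x$workflow,
      " modalities:", length(x$W0),
      " C:", nrow(x$W0[[1]]), "\n")
  invisible(x)
}
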