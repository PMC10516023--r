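## Precompute per-subspace constants (stacked indices, lambda, log-normalizer)
## so the loss and gradient are cheap inside optimization loops.
loss_context <- function(s, kp) {
  idx <- subspace_indices(s)
  ctx <- list(
    idx = idx,
    dims = vapply(idx, length, 1L),
    beta = kp$beta
  )
  ctx$eta <- vapply(ctx$dims, function(d) resolve_eta(kp, d), 1.0)
  ctx$lam <- vapply(ctx$dims, function(d) resolve_lambda(kp, d), 1.0)
  ctx$logc <- mapply(function(d, e, l) kotz_log_const(d, kp$beta, e, l),
                     ctx$dims, ctx$eta, ctx$lam)
  ctx
}

## Subspace (marginal-entropy) term of the loss from the stacked source
## matrix Ystack (MC x N): sum_k mean_n -ln p_k(y_k,n).
subspace_term <- function(Ystack, ctx) {
  total <- 0
  for (k in seq_along(ctx$idx)) {
    r2 <- colSums(Ystack[ctx$idx[[k]], , drop = FALSE]^2)
    r2 <- pmax(r2, 1e-300)
    term <- ctx$lam[k] * r2^ctx$beta - ctx$logc[k]
    if (ctx$eta[k] != 1) term <- term - (ctx$eta[k] - 1) * log(r2)
    total <- total + mean(term)
  }
  total
}

stack_sources <- function(W_list, Xr_list) {
  do.call(rbind, Map(`%*%`, W_list, Xr_list))
}

#' MISA loss
#'
#' The mutual-information-among-subspaces objective: the KL divergence
#' between the joint source density and the product of the K subspace Kotz
#' densities, up to the W-independent data entropy (dropped). Concretely
#' `-sum_m ln|det W[m]| + (1/N) sum_n sum_k -ln p_k(P_k s_n)` where `s_n`
#' stacks all modalities' estimated sources for sample n.
#'
#' @param W_list per-modality square C x C unmixing matrices acting on
#'   reduced data.
#' @param Xr_list per-modality C x N reduced (whitened) data.
#' @param s `msiva_structure`.
#' @param kp `msiva_kotz`.
#' @return scalar loss.
#' @export
misa_loss <- function(W_list, Xr_list, s, kp = kotz_params()) {
  stopifnot(length(W_list) == s$M, length(Xr_list) == s$M)
  ld <- vapply(W_list, function(W) determinant(W)$modulus[1], 1.0)
  if (any(!is.finite(ld))) stop("singular unmixing matrix")
  ctx <- loss_context(s, kp)
  -sum(ld) + subspace_term(stack_sources(W_list, Xr_list), ctx)
}

## Loss and relative gradient in one pass. Gradient wrt W[m]:
##   dL/dW[m] = -(W[m]^-T) + (1/N) G[m] Xr[m]^T,
## where G[m][i, n] = y_in * phi_k(r_kn) for source i in subspace k,
##   phi_k(r) = 2 beta lam r^(2 beta - 2) - 2 (eta - 1) / r^2.
misa_loss_grad <- function(W_list, Xr_list, ctx) {
  M <- length(W_list)
  C <- nrow(W_list[[1]])
  N <- ncol(Xr_list[[1]])
  Y <- stack_sources(W_list, Xr_list)
  ld <- 0
  Winv_t <- vector("list", M)
  for (m in seq_len(M)) {
    dt <- determinant(W_list[[m]])
    if (!is.finite(dt$modulus[1])) return(list(loss = Inf, grad = NULL))
    ld <- ld + dt$modulus[1]
    inv <- tryCatch(solve(W_list[[m]]), error = function(e) NULL)
    if (is.null(inv)) return(list(loss = Inf, grad = NULL))
    Winv_t[[m]] <- t(inv)
  }
  G <- matrix(0, M * C, N)
  total <- 0
  for (k in seq_along(ctx$idx)) {
    ii <- ctx$idx[[k]]
    Yk <- Y[ii, , drop = FALSE]
    r2 <- pmax(colSums(Yk^2), 1e-300)
    term <- ctx$lam[k] * r2^ctx$beta - ctx$logc[k]
    phi <- 2 * ctx$beta * ctx$lam[k] * r2^(ctx$beta - 1)
    if (ctx$eta[k] != 1) {
      term <- term - (ctx$eta[k] - 1) * log(r2)
      phi <- phi - 2 * (ctx$eta[k] - 1) / r2
    }
    total <- total + mean(term)
    G[ii, ] <- Yk * rep(phi, each = length(ii))
  }
  grad <- vector("list", M)
  for (m in seq_len(M)) {
    rows <- (m - 1L) * C + seq_len(C)
    grad[[m]] <- -Winv_t[[m]] +
      (G[rows, , drop = FALSE] %*% t(Xr_list[[m]])) / N
  }
  list(loss = -ld + total, grad = grad)
}

#' Quasi-Newton refinement of the unmixing matrices
#'
#' Minimizes [misa_loss()] by L-BFGS in the relative (natural-gradient)
#' parameterization `W[m] = (I + E[m]) W0[m]`, optimizing the E's jointly
#' across modalities from `E = 0`. Determinants are kept away from zero by a
#' hard cap: parameter points with `|det W[m]| < 1e-12` score a large finite
#' penalty, which the line search backtracks away from.
#'
#' @param W0_list initial per-modality C x C unmixing matrices.
#' @param Xr_list per-modality reduced data.
#' @param s `msiva_structure`.
#' @param kp `msiva_kotz`.
#' @param max_iter L-BFGS iteration cap.
#' @param tol relative convergence tolerance on the loss.
#' @return list with `W` (refined matrices; final loss never above the
#'   initial), `loss`, `initial_loss`, `converged`, `message`.
#' @export
numerical_optimize <- function(W0_list, Xr_list, s, kp = kotz_params(),
                               max_iter = 200L, tol = 1e-9) {
  M <- length(W0_list)
  C <- nrow(W0_list[[1]])
  ctx <- loss_context(s, kp)
  unpack <- function(par) {
    lapply(seq_len(M), function(m) {
      E <- matrix(par[(m - 1L) * C * C + seq_len(C * C)], C, C)
      (diag(C) + E) %*% W0_list[[m]]
    })
  }
  big <- 1e10
  guarded <- function(par) {
    W <- unpack(par)
    dets <- vapply(W, function(w) abs(det(w)), 1.0)
    if (any(!is.finite(dets)) || any(dets < 1e-12)) {
      return(list(loss = Inf, grad = NULL))
    }
    misa_loss_grad(W, Xr_list, ctx)
  }
  fn <- function(par) {
    loss <- guarded(par)$loss
    if (!is.finite(loss)) big else loss
  }
  gr <- function(par) {
    lg <- guarded(par)
    if (is.null(lg$grad) || !is.finite(lg$loss)) return(rep(0, length(par)))
    ## chain rule through W = (I + E) W0: dL/dE = dL/dW %*% W0'
    unlist(lapply(seq_len(M), function(m) lg$grad[[m]] %*% t(W0_list[[m]])))
  }
  par0 <- rep(0, M * C * C)
  loss0 <- fn(par0)
  res <- tryCatch(
    stats::optim(par0, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = max_iter,
                                factr = tol / .Machine$double.eps)),
    error = function(e) NULL
  )
  if (is.null(res) || !is.finite(res$value) || res$value > loss0) {
    if (!is.null(res) && res$value > loss0 + 1e-12) {
      warning("L-BFGS line search failed to improve; keeping initial point")
    }
    return(list(W = W0_list, loss = loss0, initial_loss = loss0,
                converged = FALSE,
                message = if (is.null(res)) "optimizer error" else res$message))
  }
  list(W = unpack(res$par), loss = res$value, initial_loss = loss0,
       converged = res$convergence == 0, message = res$message)
}
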