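#' Kotz distribution parameters
#'
#' The subspace densities are members of the Kotz family
#' `p(v) = c_d ||v||^(2(eta-1)) exp(-lam ||v||^(2 beta))` on R^d. The
#' defaults `beta = 0.5, eta = 1` give the multivariate-Laplace-like member
#' matching the synthetic generator; `beta = 1, eta = 1, lam = 1/2` is the
#' standard Gaussian.
#'
#' @param beta shape exponent > 0.
#' @param eta power parameter, or `NULL` (default) for the
#'   dimension-adapted choice `eta_d = 1` for `d <= 2` and `2 - d/2` for
#'   `d >= 3`, which matches the small-radius behavior `r * exp(-sqrt(2) r)`
#'   of the multivariate Laplace radial density in every dimension
#'   (integrability needs only `eta > 1 - d/2`, which this satisfies).
#' @param lam scale > 0, or `NULL` to set it per subspace so that
#'   `E||v||^2 = d` (unit variance per coordinate).
#' @return `msiva_kotz` parameter object.
#' @export
kotz_params <- function(beta = 0.5, eta = NULL, lam = NULL) {
  stopifnot(beta > 0, is.null(lam) || lam > 0)
  structure(list(beta = beta, eta = eta, lam = lam), class = "msiva_kotz")
}

resolve_eta <- function(kp, d) {
  e <- kp$eta %||% (if (d <= 2) 1 else 2 - d / 2)
  if (e <= 1 - d / 2) stop("eta must exceed 1 - d/2 for integrability")
  e
}

## lambda giving E||v||^2 = d for dimension d:
## with a0 = (d/2 + eta - 1)/beta, E||v||^2 = lam^(-1/beta) *
## gamma(a0 + 1/beta)/gamma(a0), so lam = (gamma(a0+1/beta)/(d gamma(a0)))^beta.
## Gaussian check (beta=1, eta=1): lam = 1/2; Laplace-like (beta=.5, eta=1):
## lam = sqrt(d+1).
kotz_lambda_unit <- function(d, beta, eta) {
  a0 <- (d / 2 + eta - 1) / beta
  exp(beta * (lgamma(a0 + 1 / beta) - lgamma(a0) - log(d)))
}

## log normalization constant:
## c_d = beta * lam^((d/2+eta-1)/beta) * gamma(d/2) /
##       (pi^(d/2) * gamma((d/2+eta-1)/beta))
kotz_log_const <- function(d, beta, eta, lam) {
  a0 <- (d / 2 + eta - 1) / beta
  log(beta) + a0 * log(lam) + lgamma(d / 2) - (d / 2) * log(pi) - lgamma(a0)
}

resolve_lambda <- function(kp, d) {
  kp$lam %||% kotz_lambda_unit(d, kp$beta, resolve_eta(kp, d))
}

#' Kotz negative log-density
#'
#' `-ln p(v)` for the Kotz family, including the closed-form normalization
#' constant so loss values are comparable across subspace structures of
#' different dimensions.
#'
#' @param v numeric vector (one point in R^d).
#' @param p `msiva_kotz`; a `NULL` `lam` resolves to the unit-variance scale
#'   for `d = length(v)`.
#' @return scalar; `+Inf` at `v = 0` when `eta < 1` (density pole).
#' @export
kotz_neg_log_density <- function(v, p = kotz_params()) {
  stopifnot(inherits(p, "msiva_kotz"))
  d <- length(v)
  if (d < 1L) stop("v must have at least one element")
  eta <- resolve_eta(p, d)
  lam <- resolve_lambda(p, d)
  r2 <- sum(v^2)
  if (r2 == 0 && eta < 1) return(Inf)
  lc <- kotz_log_const(d, p$beta, eta, lam)
  term_r <- if (eta == 1) 0 else -(eta - 1) * log(r2)
  -lc + term_r + lam * r2^p$beta
}
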