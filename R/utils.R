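#' @keywords internal
"_PACKAGE"

## All randomness in the package flows from one master seed via this
## counter-based splitter so that independent stages never share a stream.
## Offsets stay below 2^31 - 1 (R integers are 32-bit).
split_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(
    generate = 101L, mixing = 211L, ica = 307L, gica = 401L,
    fit = 503L, cv = 601L, rdc = 701L, split = 811L, perm = 907L
  )
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]]) %% 2147483629)
}

## Evaluate `expr` under a local RNG state; restores .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_if_not_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`", name, "` must be a numeric matrix", call. = FALSE)
  }
  invisible(x)
}

## Row-wise standardization to zero mean, unit (sample) variance.
standardize_rows <- function(S) {
  mu <- rowMeans(S)
  S <- S - mu
  sdv <- sqrt(rowSums(S^2) / (ncol(S) - 1))
  if (any(sdv == 0)) stop("cannot standardize a constant row")
  S / sdv
}

`%||%` <- function(a, b) if (is.null(a)) b else a
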