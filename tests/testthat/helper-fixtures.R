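## Shared fixtures: everything is generated in code at test time.

## Small whitened Laplace mixture with known ground truth, one modality.
laplace_mixture <- function(C = 3, N = 2000, seed = 1) {
  set.seed(seed)
  S <- matrix(stats::rexp(C * N) * sign(stats::rnorm(C * N)), C, N)
  S <- S - rowMeans(S)
  S <- S / apply(S, 1, sd)
  A <- matrix(stats::rnorm(C * C), C, C)
  list(S = S, A = A, X = A %*% S)
}

## Literal transcription of the Amari-type index for a square nonnegative
## matrix, used as the brute-force oracle for the packaged implementation.
amari_oracle <- function(H) {
  K <- nrow(H)
  row_part <- 0
  for (i in seq_len(K)) {
    row_part <- row_part - 1
    for (j in seq_len(K)) {
      row_part <- row_part + H[i, j] / max(H[i, ])
    }
  }
  col_part <- 0
  for (j in seq_len(K)) {
    col_part <- col_part - 1
    for (i in seq_len(K)) {
      col_part <- col_part + H[i, j] / max(H[, j])
    }
  }
  (row_part + col_part) / (2 * K * (K - 1))
}

## Literal transcription of the two-stage MCC formula.
mcc_oracle <- function(R_blocks) {
  vals <- vapply(R_blocks, function(R) {
    d <- nrow(R)
    acc <- 0
    for (i in seq_len(d)) {
      acc <- acc + max(abs(R[i, ])) + max(abs(R[, i]))
    }
    acc / (2 * d)
  }, 1.0)
  mean(vals)
}

## All row permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

## Amari index of a plain (source-level) square matrix of absolute values.
source_isi <- function(G) {
  amari_oracle(abs(G))
}
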