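## Jonker-Volgenant shortest-augmenting-path solver for the linear
## assignment problem (square cost matrix, minimization). O(n^3); n = C here.
## Returns `match`: match[i] = column assigned to row i.
solve_assignment_min <- function(a) {
  n <- nrow(a)
  stopifnot(ncol(a) == n, all(is.finite(a)))
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1L)     # column potentials, index j+1 (col 0 virtual)
  p <- integer(n + 1L)     # p[j+1] = row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- a[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match <- integer(n)
  for (j in seq_len(n)) match[p[j + 1L]] <- j
  match
}

## Correlation matrix between rows of two matrices, safe for constant rows.
safe_row_cor <- function(A, B) {
  sa <- apply(A, 1, stats::sd)
  sb <- apply(B, 1, stats::sd)
  R <- matrix(0, nrow(A), nrow(B))
  ok_a <- sa > 0
  ok_b <- sb > 0
  if (any(ok_a) && any(ok_b)) {
    R[ok_a, ok_b] <- stats::cor(t(A[ok_a, , drop = FALSE]),
                                t(B[ok_b, , drop = FALSE]))
  }
  R
}

## Subspace-term bookkeeping for fast permutation scoring: per-subspace
## loss terms, recomputed only for blocks touched by a candidate move.
align_state <- function(Ystack, ctx) {
  C_total <- nrow(Ystack)
  sub_of <- integer(C_total)
  for (k in seq_along(ctx$idx)) sub_of[ctx$idx[[k]]] <- k
  terms <- vapply(seq_along(ctx$idx), function(k)
    subspace_term_one(Ystack, ctx, k), 1.0)
  list(Y = Ystack, terms = terms, sub_of = sub_of)
}

subspace_term_one <- function(Ystack, ctx, k) {
  r2 <- pmax(colSums(Ystack[ctx$idx[[k]], , drop = FALSE]^2), 1e-300)
  term <- ctx$lam[k] * r2^ctx$beta - ctx$logc[k]
  if (ctx$eta[k] != 1) term <- term - (ctx$eta[k] - 1) * log(r2)
  mean(term)
}

## Score a candidate row permutation of the stacked matrix: rows `from` are
## replaced by rows `to` (a swap when passed both ways). Returns the new
## total and the recomputed terms for affected subspaces.
score_move <- function(state, ctx, rows_a, rows_b) {
  Y <- state$Y
  tmp <- Y[rows_a, , drop = FALSE]
  Y[rows_a, ] <- Y[rows_b, , drop = FALSE]
  Y[rows_b, ] <- tmp
  ks <- unique(state$sub_of[c(rows_a, rows_b)])
  new_terms <- state$terms
  for (k in ks) new_terms[k] <- subspace_term_one(Y, ctx, k)
  list(Y = Y, terms = new_terms, total = sum(new_terms))
}

#' Greedy combinatorial cross-modal subspace alignment
#'
#' Searches row permutations of the per-modality unmixing matrices for a
#' lower [misa_loss()]. Modality 1 is the fixed reference for cross-modal
#' matching: first a global bipartite assignment pairs each non-reference
#' modality's sources to the reference by absolute cross-modal correlation
#' (optimal assignment, not greedy), then accept-only-improving swaps of
#' individual source rows (within one modality and jointly across all
#' modalities) and of whole equal-size subspace blocks are applied until no
#' swap improves the loss. Row permutations leave `|det W|` unchanged, so
#' only the subspace term is rescored. The identity permutation is always
#' admissible: the returned loss never exceeds the input loss.
#'
#' @param W_list per-modality C x C unmixing matrices.
#' @param Xr_list per-modality reduced data.
#' @param s `msiva_structure`.
#' @param kp `msiva_kotz`.
#' @param max_passes cap on greedy sweeps.
#' @return list with `W` (row-permuted copies), `loss`, `perms` (per-modality
#'   integer permutations applied to the rows).
#' @export
align_subspaces <- function(W_list, Xr_list, s, kp = kotz_params(),
                            max_passes = 8L) {
  M <- s$M
  C <- s$C
  ctx <- loss_context(s, kp)
  base_ld <- sum(vapply(W_list, function(W) determinant(W)$modulus[1], 1.0))
  Ystack <- stack_sources(W_list, Xr_list)
  state <- align_state(Ystack, ctx)
  perms <- lapply(seq_len(M), function(m) seq_len(C))
  total <- sum(state$terms)
  eps <- 1e-12

  srow <- function(m, i) (m - 1L) * C + i

  apply_perm <- function(m, a) {
    ## candidate: new row i of modality m = current row a[i]
    Y <- state$Y
    rows <- srow(m, seq_len(C))
    Y[rows, ] <- Y[rows, , drop = FALSE][a, , drop = FALSE]
    new_terms <- state$terms
    ks <- sort(unique(state$sub_of[rows]))
    for (k in ks) new_terms[k] <- subspace_term_one(Y, ctx, k)
    list(Y = Y, terms = new_terms, total = sum(new_terms))
  }

  ## stage 1: optimal bipartite matching to the reference modality
  if (M > 1L) {
    ref_rows <- srow(1L, seq_len(C))
    for (m in 2:M) {
      R <- abs(safe_row_cor(state$Y[ref_rows, , drop = FALSE],
                            state$Y[srow(m, seq_len(C)), , drop = FALSE]))
      a <- solve_assignment_min(-R)
      cand <- apply_perm(m, a)
      if (cand$total < total - eps) {
        state$Y <- cand$Y
        state$terms <- cand$terms
        total <- cand$total
        perms[[m]] <- perms[[m]][a]
      }
    }
  }

  ## stage 1.5: dependence-driven regrouping. Sources in one subspace share
  ## a scale variable, so their squared amplitudes ("envelopes") correlate;
  ## blocks are assembled greedily from the envelope-correlation matrix and
  ## the candidate joint permutation is accepted only if it lowers the loss.
  blocks <- structure_index_map(s)
  linked <- Filter(function(b) b$type == "linked", blocks)
  if (any(vapply(linked, `[[`, 1L, "d") > 1L)) {
    Env <- t(vapply(seq_len(C), function(i) {
      rows <- vapply(seq_len(M), srow, 1L, i = i)
      colSums(state$Y[rows, , drop = FALSE]^2)
    }, numeric(ncol(state$Y))))
    D <- abs(safe_row_cor(Env, Env))
    diag(D) <- 0
    remaining <- seq_len(C)
    slots <- vector("list", length(linked))
    for (bi in order(-vapply(linked, `[[`, 1L, "d"))) {
      d <- linked[[bi]]$d
      if (d == 1L) next
      Dr <- D[remaining, remaining, drop = FALSE]
      seedpair <- remaining[which(Dr == max(Dr), arr.ind = TRUE)[1, ]]
      blk <- seedpair
      while (length(blk) < d) {
        cand <- setdiff(remaining, blk)
        blk <- c(blk, cand[which.max(
          vapply(cand, function(x) mean(D[x, blk]), 1.0))])
      }
      slots[[bi]] <- blk
      remaining <- setdiff(remaining, blk)
    }
    for (bi in seq_along(linked)) {
      if (is.null(slots[[bi]])) {
        slots[[bi]] <- remaining[1L]
        remaining <- remaining[-1L]
      }
    }
    gperm <- integer(C)
    for (bi in seq_along(linked)) gperm[linked[[bi]]$idx] <- slots[[bi]]
    uni_idx <- unlist(lapply(Filter(function(b) b$type == "unimodal", blocks),
                             `[[`, "idx"))
    gperm[uni_idx] <- remaining
    Ycand <- state$Y
    for (m in seq_len(M)) {
      rows <- srow(m, seq_len(C))
      Ycand[rows, ] <- Ycand[rows, , drop = FALSE][gperm, , drop = FALSE]
    }
    cand_terms <- vapply(seq_along(ctx$idx), function(k)
      subspace_term_one(Ycand, ctx, k), 1.0)
    if (sum(cand_terms) < total - eps) {
      state$Y <- Ycand
      state$terms <- cand_terms
      total <- sum(cand_terms)
      for (m in seq_len(M)) perms[[m]] <- perms[[m]][gperm]
    }
  }

  ## stage 2: greedy accept-only-improving swaps
  pairs <- if (C >= 2L) utils::combn(C, 2L) else matrix(integer(0), 2, 0)
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    try_swap <- function(rows_a, rows_b, per_modality) {
      cand <- score_move(state, ctx, rows_a, rows_b)
      if (cand$total < total - eps) {
        state$Y <<- cand$Y
        state$terms <<- cand$terms
        total <<- cand$total
        for (m in per_modality) {
          ia <- ((rows_a - 1L) %% C) + 1L
          ib <- ((rows_b - 1L) %% C) + 1L
          keep <- perms[[m]][ia]
          perms[[m]][ia] <- perms[[m]][ib]
          perms[[m]][ib] <- keep
        }
        TRUE
      } else FALSE
    }
    ## single-source swaps within each modality, then jointly
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      for (m in seq_len(M)) {
        if (try_swap(srow(m, i), srow(m, j), m)) improved <- TRUE
      }
      if (M > 1L) {
        ra <- vapply(seq_len(M), srow, 1L, i = i)
        rb <- vapply(seq_len(M), srow, 1L, i = j)
        if (try_swap(ra, rb, seq_len(M))) improved <- TRUE
      }
    }
    ## whole-block swaps between equal-size linked blocks
    if (length(linked) >= 2L) {
      for (a in seq_len(length(linked) - 1L)) {
        for (b in seq.int(a + 1L, length(linked))) {
          if (linked[[a]]$d != linked[[b]]$d) next
          for (m in seq_len(M)) {
            if (try_swap(srow(m, linked[[a]]$idx), srow(m, linked[[b]]$idx), m))
              improved <- TRUE
          }
          if (M > 1L) {
            ra <- unlist(lapply(seq_len(M), function(m) srow(m, linked[[a]]$idx)))
            rb <- unlist(lapply(seq_len(M), function(m) srow(m, linked[[b]]$idx)))
            if (try_swap(ra, rb, seq_len(M))) improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }

  W_new <- lapply(seq_len(M), function(m)
    W_list[[m]][perms[[m]], , drop = FALSE])
  list(W = W_new, loss = -base_ld + total, perms = perms)
}
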