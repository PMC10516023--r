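#' Subspace structures
#'
#' A subspace structure partitions the C sources of each modality into
#' *linked* cross-modal blocks (the i-th linked block of every modality has
#' the same dimension d_k and is statistically dependent across modalities)
#' and *unimodal* 1D blocks that are specific to one modality and independent
#' of everything else. Sources are ordered block-contiguously within each
#' modality: linked blocks first, in listed order, then unimodal blocks.
#'
#' @param linked integer vector of linked-block dimensions d_k (each >= 1).
#' @param unimodal integer: number of 1D unimodal blocks per modality.
#' @param M number of modalities (>= 1).
#' @param name optional label.
#' @return An object of class `msiva_structure` with fields `M`, `C`,
#'   `linked`, `unimodal`, `K` (total number of subspaces) and `name`.
#' @examples
#' subspace_structure(c(2, 2, 2, 2, 2), unimodal = 2, M = 2)
#' @export
subspace_structure <- function(linked, unimodal = 0L, M = 2L, name = NULL) {
  linked <- as.integer(linked)
  unimodal <- as.integer(unimodal)
  M <- as.integer(M)
  if (M < 1L) stop("M must be >= 1")
  if (length(linked) > 0 && any(linked < 1L)) stop("linked block sizes must be >= 1")
  if (length(unimodal) != 1L || unimodal < 0L) stop("unimodal must be a count >= 0")
  C <- sum(linked) + unimodal
  if (C < 1L) stop("structure has no sources")
  structure(
    list(
      M = M, C = C, linked = linked, unimodal = unimodal,
      K = length(linked) + M * unimodal,
      name = name %||% structure_grammar_string(linked, unimodal)
    ),
    class = "msiva_structure"
  )
}

structure_grammar_string <- function(linked, unimodal) {
  paste0(paste(linked, collapse = ","), "|",
         paste(rep(1L, unimodal), collapse = ","))
}

#' @export
print.msiva_structure <- function(x, ...) {
  cat("<msiva_structure> ", x$name, "\n", sep = "")
  cat("  modalities:", x$M, " sources/modality:", x$C, "\n")
  cat("  linked blocks: [", paste(x$linked, collapse = ", "), "]",
      "  unimodal blocks/modality:", x$unimodal, "\n")
  cat("  subspaces K =", x$K, "\n")
  invisible(x)
}

#' Candidate subspace structures S1-S5
#'
#' The five candidate structures considered for two modalities, all with
#' C = 12 sources per modality:
#' \describe{
#'   \item{S1}{linked blocks 2, 3, 4 plus three unimodal blocks}
#'   \item{S2}{five linked 2D blocks plus two unimodal blocks}
#'   \item{S3}{three linked 3D blocks plus three unimodal blocks}
#'   \item{S4}{two linked 4D blocks plus four unimodal blocks}
#'   \item{S5}{twelve linked 1D blocks, no unimodal blocks (the IVA case)}
#' }
#'
#' @param name one of `"S1"`..`"S5"`, or a grammar string
#'   `"d1,d2,...|1,1,..."` giving linked sizes and per-modality unimodal
#'   blocks (e.g. `"2,2,2,2,2|1,1"` is S2).
#' @param M number of modalities.
#' @return `msiva_structure`.
#' @export
make_candidate <- function(name, M = 2L) {
  candidates <- list(
    S1 = list(linked = c(2L, 3L, 4L), unimodal = 3L),
    S2 = list(linked = rep(2L, 5L), unimodal = 2L),
    S3 = list(linked = rep(3L, 3L), unimodal = 3L),
    S4 = list(linked = rep(4L, 2L), unimodal = 4L),
    S5 = list(linked = rep(1L, 12L), unimodal = 0L)
  )
  if (name %in% names(candidates)) {
    cand <- candidates[[name]]
    return(subspace_structure(cand$linked, cand$unimodal, M = M, name = name))
  }
  if (grepl("|", name, fixed = TRUE)) {
    return(parse_structure(name, M = M))
  }
  stop("unknown candidate '", name, "'; valid names: ",
       paste(names(candidates), collapse = ", "),
       ", or a grammar string like \"2,2,2,2,2|1,1\"")
}

#' Parse a structure grammar string
#'
#' `"linked|unimodal"`, each side a comma-separated list of block sizes;
#' unimodal sizes must all be 1. An empty side is allowed (`"1,1,1|"`).
#'
#' @param text grammar string.
#' @param M number of modalities.
#' @return `msiva_structure`.
#' @export
parse_structure <- function(text, M = 2L) {
  parts <- strsplit(text, "|", fixed = TRUE)[[1]]
  if (length(parts) < 1L || length(parts) > 2L) {
    stop("structure grammar must be \"linked|unimodal\", got: ", text)
  }
  num <- function(s) {
    s <- trimws(s)
    if (s == "") return(integer(0))
    as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  }
  linked <- num(parts[1])
  uni <- if (length(parts) == 2L) num(parts[2]) else integer(0)
  if (length(uni) > 0 && any(uni != 1L)) {
    stop("unimodal blocks must all be one-dimensional")
  }
  subspace_structure(linked, length(uni), M = M, name = text)
}

#' Per-modality block index map
#'
#' @param s `msiva_structure`.
#' @return list with one element per block (linked first, then unimodal),
#'   each a list of per-modality source index vectors (1-based, within
#'   modality). Unimodal blocks carry indices for their own modality only.
#' @keywords internal
structure_index_map <- function(s) {
  stopifnot(inherits(s, "msiva_structure"))
  blocks <- list()
  pos <- 1L
  for (k in seq_along(s$linked)) {
    idx <- seq.int(pos, length.out = s$linked[k])
    blocks[[length(blocks) + 1L]] <-
      list(type = "linked", d = s$linked[k], idx = idx)
    pos <- pos + s$linked[k]
  }
  for (u in seq_len(s$unimodal)) {
    blocks[[length(blocks) + 1L]] <-
      list(type = "unimodal", d = 1L, idx = pos)
    pos <- pos + 1L
  }
  blocks
}

#' Subspace assignment matrices
#'
#' Builds the binary matrices P_k (C_k x M*C) selecting each subspace's
#' sources from the stacked M*C source vector (modality-major ordering:
#' modality 1 sources 1..C, modality 2 sources C+1..2C, ...). A linked
#' subspace selects its d_k sources in every modality (C_k = M*d_k); each
#' unimodal block yields one 1-row matrix per modality (C_k = 1). Subspace
#' order: linked blocks, then modality 1's unimodal blocks, modality 2's, ...
#'
#' @param s `msiva_structure`.
#' @return list of K binary matrices; their vertical stack is a row
#'   permutation of the M*C identity.
#' @export
assignment_matrices <- function(s) {
  stopifnot(inherits(s, "msiva_structure"))
  MC <- s$M * s$C
  idx <- subspace_indices(s)
  lapply(idx, function(rows) {
    P <- matrix(0, nrow = length(rows), ncol = MC)
    P[cbind(seq_along(rows), rows)] <- 1
    P
  })
}

#' Stacked source indices of every subspace
#'
#' Same partition as [assignment_matrices()] but as plain index vectors into
#' the stacked M*C source vector; cheaper for loss evaluation.
#'
#' @param s `msiva_structure`.
#' @return list of K integer vectors.
#' @export
subspace_indices <- function(s) {
  blocks <- structure_index_map(s)
  out <- list()
  for (b in blocks) {
    if (b$type == "linked") {
      out[[length(out) + 1L]] <-
        as.integer(unlist(lapply(seq_len(s$M) - 1L, function(m) m * s$C + b$idx)))
    }
  }
  for (m in seq_len(s$M) - 1L) {
    for (b in blocks) {
      if (b$type == "unimodal") {
        out[[length(out) + 1L]] <- as.integer(m * s$C + b$idx)
      }
    }
  }
  out
}

#' Per-source subspace labels within one modality
#'
#' @param s `msiva_structure`.
#' @return integer vector of length C: for each source of a single modality,
#'   the index of the block (linked blocks 1..L, then unimodal blocks) it
#'   belongs to.
#' @export
source_block_labels <- function(s) {
  blocks <- structure_index_map(s)
  lab <- integer(s$C)
  for (i in seq_along(blocks)) lab[blocks[[i]]$idx] <- i
  lab
}

#' Serialize / deserialize structures as JSON
#'
#' @param s `msiva_structure`.
#' @return `structure_to_json`: a JSON string; `structure_from_json`: an
#'   `msiva_structure`.
#' @export
structure_to_json <- function(s) {
  stopifnot(inherits(s, "msiva_structure"))
  jsonlite::toJSON(
    list(name = s$name, M = s$M, linked = s$linked, unimodal = s$unimodal),
    auto_unbox = TRUE
  )
}

#' @rdname structure_to_json
#' @param json JSON string produced by `structure_to_json`.
#' @export
structure_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  subspace_structure(x$linked, x$unimodal, M = x$M, name = x$name)
}
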