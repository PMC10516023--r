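## Plain-text persistence: matrices as TSV, metadata as JSON sidecars.
## (No HDF5/NIfTI backend is assumed; everything round-trips through text.)

write_matrix_tsv <- function(X, path) {
  utils::write.table(X, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
}

read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("missing matrix file: ", path)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' Write / read a dataset as a plain-text directory
#'
#' The directory holds one TSV per matrix (`X1.tsv`, `A1.tsv`, `S1.tsv`,
#' ... per modality), optional `sites.tsv` and `phenotypes.tsv` tables, and
#' a `meta.json` sidecar with the structure and generator parameters.
#'
#' @param data `msiva_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; `read_msiva_dataset` returns the dataset.
#' @export
write_msiva_dataset <- function(data, dir) {
  stopifnot(inherits(data, "msiva_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  M <- length(data$X)
  for (m in seq_len(M)) {
    write_matrix_tsv(data$X[[m]], file.path(dir, paste0("X", m, ".tsv")))
    if (!is.null(data$A)) {
      write_matrix_tsv(data$A[[m]], file.path(dir, paste0("A", m, ".tsv")))
      write_matrix_tsv(data$S[[m]], file.path(dir, paste0("S", m, ".tsv")))
    }
  }
  if (!is.null(data$site_labels)) {
    utils::write.table(
      data.frame(sample_id = seq_along(data$site_labels),
                 site = data$site_labels),
      file.path(dir, "sites.tsv"), sep = "\t", row.names = FALSE
    )
  }
  if (!is.null(data$phenotypes)) {
    utils::write.table(data$phenotypes, file.path(dir, "phenotypes.tsv"),
                       sep = "\t", row.names = FALSE)
  }
  meta <- list(
    M = M, has_truth = !is.null(data$A), seed = data$seed,
    structure = if (!is.null(data$structure)) {
      jsonlite::fromJSON(structure_to_json(data$structure))
    },
    target_corr = data$target_corr
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_msiva_dataset
#' @export
read_msiva_dataset <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("missing meta.json in ", dir)
  meta <- jsonlite::fromJSON(meta_path)
  M <- meta$M
  X <- lapply(seq_len(M), function(m)
    read_matrix_tsv(file.path(dir, paste0("X", m, ".tsv"))))
  A <- S <- NULL
  if (isTRUE(meta$has_truth)) {
    A <- lapply(seq_len(M), function(m)
      read_matrix_tsv(file.path(dir, paste0("A", m, ".tsv"))))
    S <- lapply(seq_len(M), function(m)
      read_matrix_tsv(file.path(dir, paste0("S", m, ".tsv"))))
  }
  s <- if (!is.null(meta$structure)) {
    subspace_structure(meta$structure$linked, meta$structure$unimodal,
                       M = meta$structure$M, name = meta$structure$name)
  }
  site_path <- file.path(dir, "sites.tsv")
  sites <- if (file.exists(site_path)) {
    utils::read.table(site_path, sep = "\t", header = TRUE)$site
  }
  pheno_path <- file.path(dir, "phenotypes.tsv")
  pheno <- if (file.exists(pheno_path)) {
    utils::read.table(pheno_path, sep = "\t", header = TRUE)
  }
  structure(
    list(X = X, A = A, S = S, structure = s,
         target_corr = meta$target_corr, site_labels = sites,
         phenotypes = pheno, seed = meta$seed %||% NA_integer_),
    class = "msiva_dataset"
  )
}

#' Write / read a fitted model as a plain-text directory
#'
#' Per-modality TSVs for the square unmixing, whitening and composite
#' transforms plus a `model.json` sidecar (structure, workflow, loss trace,
#' Kotz parameters, seed). Sources are recomputed on read when data is
#' supplied to [read_msiva_model()].
#'
#' @param model `msiva_model`.
#' @param dir output directory.
#' @return `dir` invisibly; `read_msiva_model` returns the model (without
#'   source estimates, which depend on the data).
#' @export
write_msiva_model <- function(model, dir) {
  stopifnot(inherits(model, "msiva_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  M <- length(model$W)
  for (m in seq_len(M)) {
    write_matrix_tsv(model$W[[m]], file.path(dir, paste0("W", m, ".tsv")))
    write_matrix_tsv(model$whitening[[m]],
                     file.path(dir, paste0("whitening", m, ".tsv")))
  }
  meta <- list(
    structure = jsonlite::fromJSON(structure_to_json(model$structure)),
    workflow = model$workflow,
    loss_trace = model$loss_trace,
    kotz = model$kotz[c("beta", "eta", "lam")],
    seed = model$seed
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_msiva_model
#' @export
read_msiva_model <- function(dir) {
  meta_path <- file.path(dir, "model.json")
  if (!file.exists(meta_path)) stop("missing model.json in ", dir)
  meta <- jsonlite::fromJSON(meta_path)
  s <- subspace_structure(meta$structure$linked, meta$structure$unimodal,
                          M = meta$structure$M, name = meta$structure$name)
  M <- s$M
  W <- lapply(seq_len(M), function(m)
    read_matrix_tsv(file.path(dir, paste0("W", m, ".tsv"))))
  whitening <- lapply(seq_len(M), function(m)
    read_matrix_tsv(file.path(dir, paste0("whitening", m, ".tsv"))))
  composite <- Map(`%*%`, W, whitening)
  structure(
    list(W = W, whitening = whitening, composite = composite, S = NULL,
         structure = s, workflow = meta$workflow,
         loss_trace = meta$loss_trace,
         loss = meta$loss_trace[length(meta$loss_trace)],
         kotz = kotz_params(meta$kotz$beta, meta$kotz$eta,
                            meta$kotz$lam),
         seed = meta$seed),
    class = "msiva_model"
  )
}
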