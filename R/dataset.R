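#' Multimodal single-cell dataset
#'
#' Bundles one cell-by-feature matrix per modality over a single shared cell
#' order. The cell order is the source of truth: every downstream matrix
#' (weights, Markov chain, embedding) indexes cells by their position here.
#'
#' @param modalities List of numeric matrices (dense or `Matrix` sparse), one
#'   per modality, all with the same number of rows (cells) in the same order.
#' @param modality_names Character vector naming the modalities; defaults to
#'   `names(modalities)` or `modality1..M`.
#' @param cell_ids Character vector of unique cell identifiers; defaults to
#'   the rownames of the first modality.
#' @param obs Optional data.frame of per-cell annotations (labels,
#'   timestamps, pseudotime) with one row per cell.
#' @param counts Logical; if `TRUE`, entries are validated as nonnegative.
#' @return An object of class `multimodal_dataset`.
#' @export
multimodal_dataset <- function(modalities, modality_names = NULL,
                               cell_ids = NULL, obs = NULL, counts = FALSE) {
  if (!is.list(modalities) || length(modalities) < 1L)
    stop("at least one modality matrix is required")
  C <- nrow(modalities[[1L]])
  for (m in seq_along(modalities)) {
    if (nrow(modalities[[m]]) != C)
      stop("modality ", m, " has ", nrow(modalities[[m]]),
           " rows; expected ", C)
    if (ncol(modalities[[m]]) < 1L)
      stop("modality ", m, " has no features")
    check_finite(modalities[[m]], paste0("modality ", m))
    if (counts) {
      xs <- if (is(modalities[[m]], "sparseMatrix")) modalities[[m]]@x
            else modalities[[m]]
      if (length(xs) && min(xs) < 0)
        stop("modality ", m, " declared as counts but has negative entries")
    }
  }
  modality_names <- modality_names %||% names(modalities) %||%
    paste0("modality", seq_along(modalities))
  cell_ids <- cell_ids %||% rownames(modalities[[1L]]) %||%
    paste0("cell", seq_len(C))
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids are not allowed")
  if (length(cell_ids) != C) stop("cell_ids length does not match cell count")
  if (!is.null(obs) && nrow(obs) != C)
    stop("obs must have one row per cell")
  names(modalities) <- modality_names
  structure(list(modalities = modalities, modality_names = modality_names,
                 cell_ids = cell_ids, obs = obs),
            class = "multimodal_dataset")
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat("multimodal_dataset:", length(x$cell_ids), "cells,",
      length(x$modalities), "modalities\n")
  for (m in seq_along(x$modalities))
    cat("  ", x$modality_names[m], ": ", ncol(x$modalities[[m]]),
        " features\n", sep = "")
  invisible(x)
}

#' Cell-to-cell developmental transition probabilities
#'
#' Wraps an externally inferred sparse transition-probability matrix (RNA
#' velocity, optimal transport, lineage tracing) aligned to a cell order.
#' Rows may be all-zero for cells without inferred transitions.
#'
#' @param probs Square sparse (or dense) matrix of nonnegative transition
#'   probabilities, cells in rows and columns.
#' @param cell_ids Cell identifiers matching the dataset order.
#' @return Object of class `transition_matrix`.
#' @export
transition_matrix <- function(probs, cell_ids = NULL) {
  probs <- as_dgc(probs)
  if (nrow(probs) != ncol(probs)) stop("transition matrix must be square")
  if (length(probs@x) && min(probs@x) < 0)
    stop("transition probabilities must be nonnegative")
  cell_ids <- cell_ids %||% rownames(probs) %||%
    paste0("cell", seq_len(nrow(probs)))
  structure(list(probs = probs, cell_ids = cell_ids),
            class = "transition_matrix")
}

#' Assemble a multimodal dataset from per-modality matrices
#'
#' @param matrices List of cell-by-feature matrices with cell ids as rownames
#'   (or supplied via `cell_ids`).
#' @param cell_ids Optional list of per-matrix cell id vectors.
#' @param align If `TRUE`, restrict all modalities to the intersection of
#'   their cell ids (in the order of the first matrix) and reorder each
#'   modality to that shared order. If `FALSE`, ids must already be identical.
#' @param ... Passed to [multimodal_dataset()].
#' @return A `multimodal_dataset`.
#' @export
assemble_dataset <- function(matrices, cell_ids = NULL, align = FALSE, ...) {
  ids <- cell_ids %||% lapply(matrices, rownames)
  if (any(vapply(ids, is.null, logical(1L))))
    stop("every matrix needs cell ids (rownames or the cell_ids argument)")
  for (m in seq_along(matrices)) {
    if (anyDuplicated(ids[[m]]))
      stop("duplicate cell ids in matrix ", m)
    rownames(matrices[[m]]) <- ids[[m]]
  }
  if (!align) {
    if (!all(vapply(ids, identical, logical(1L), y = ids[[1L]])))
      stop("cell ids differ across matrices; use align = TRUE")
    shared <- ids[[1L]]
  } else {
    shared <- Reduce(intersect, ids)
    if (length(shared) == 0L)
      stop("alignment error: the intersection of cell ids is empty")
    matrices <- lapply(matrices, function(m) m[shared, , drop = FALSE])
  }
  multimodal_dataset(matrices, cell_ids = shared, ...)
}

mtx_companions <- function(path) {
  stem <- sub("\\.mtx$", "", path)
  list(cells = paste0(stem, ".cells.tsv"),
       features = paste0(stem, ".features.tsv"))
}

#' Read one modality matrix from disk
#'
#' Supported formats: Matrix Market coordinate (`mtx`, with companion
#' `<stem>.cells.tsv` / `<stem>.features.tsv` id files, one id per line),
#' tab-delimited text (`delimited`: header row of feature ids, first column
#' of cell ids), and a minimal `h5ad` annotated matrix (dense or CSR/CSC
#' `X`, ids in `obs/_index` and `var/_index`; requires the rhdf5 package).
#'
#' @param path File path.
#' @param format One of `"auto"`, `"mtx"`, `"delimited"`, `"h5ad"`; `"auto"`
#'   dispatches on the file extension.
#' @return Cell-by-feature matrix with cell ids as rownames and feature ids
#'   as colnames; sparse input stays sparse.
#' @export
read_modality <- function(path, format = c("auto", "mtx", "delimited", "h5ad")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- switch(tools::file_ext(path), mtx = "mtx", h5ad = "h5ad",
                     "delimited")
  if (format == "mtx") {
    m <- tryCatch(as(Matrix::readMM(path), "CsparseMatrix"),
                  error = function(e) stop("malformed MTX file '", path,
                                           "': ", conditionMessage(e)))
    comp <- mtx_companions(path)
    for (f in unlist(comp))
      if (!file.exists(f)) stop("missing MTX companion id file: ", f)
    cells <- readLines(comp$cells)
    feats <- readLines(comp$features)
    if (length(cells) != nrow(m))
      stop("dimension error: ", length(cells), " cell ids for ",
           nrow(m), " matrix rows")
    if (length(feats) != ncol(m))
      stop("dimension error: ", length(feats), " feature ids for ",
           ncol(m), " matrix columns")
    if (anyDuplicated(cells)) stop("duplicate cell ids in ", comp$cells)
    dimnames(m) <- list(cells, feats)
    return(m)
  }
  if (format == "delimited") {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("malformed delimited file '", path,
                             "': need a cell id column plus features")
    ids <- as.character(tab[[1L]])
    if (anyDuplicated(ids))
      stop("dimension/uniqueness error: duplicate cell id '",
           ids[duplicated(ids)][1L], "' in ", path)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("malformed delimited file '", path,
                             "': non-numeric feature values")
    rownames(m) <- ids
    return(m)
  }
  read_h5ad_matrix(path)
}

#' Write one modality matrix to disk
#'
#' Inverse of [read_modality()]; `read_modality(write_modality(x))`
#' reproduces integer matrices bit-exactly in all formats.
#'
#' @param mat Cell-by-feature matrix with dimnames.
#' @param path Output path.
#' @param format `"mtx"`, `"delimited"`, or `"h5ad"`.
#' @return `path`, invisibly.
#' @export
write_modality <- function(mat, path, format = c("mtx", "delimited", "h5ad")) {
  format <- match.arg(format)
  cells <- rownames(mat) %||% paste0("cell", seq_len(nrow(mat)))
  feats <- colnames(mat) %||% paste0("feature", seq_len(ncol(mat)))
  if (format == "mtx") {
    Matrix::writeMM(as_dgc(mat), path)
    comp <- mtx_companions(path)
    writeLines(cells, comp$cells)
    writeLines(feats, comp$features)
  } else if (format == "delimited") {
    tab <- data.frame(cell = cells, as.matrix(mat), check.names = FALSE,
                      stringsAsFactors = FALSE)
    colnames(tab) <- c("cell", feats)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write_h5ad_matrix(mat, path)
  }
  invisible(path)
}

#' Write an embedding as tab-delimited text
#'
#' One row per cell: the cell id column followed by one column per dimension
#' (`DIM1..DIMn`). An empty matrix yields a header-only file.
#'
#' @param coords Cell-by-dimension numeric matrix.
#' @param path Output path.
#' @param cell_ids Cell ids; default rownames of `coords`.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(coords, path, cell_ids = NULL) {
  coords <- as.matrix(coords)
  cell_ids <- cell_ids %||% rownames(coords) %||%
    (if (nrow(coords)) paste0("cell", seq_len(nrow(coords))) else character())
  if (length(cell_ids) != nrow(coords))
    stop("dimension error: ", length(cell_ids), " cell ids for ",
         nrow(coords), " embedding rows")
  dims <- paste0("DIM", seq_len(ncol(coords)))
  header <- paste(c("cell", dims), collapse = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(coords)) {
    body <- apply(format(coords, digits = 15, trim = TRUE, scientific = FALSE),
                  1L, paste, collapse = "\t")
    writeLines(paste(cell_ids, body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read an embedding written by [write_embedding()]
#' @param path File path.
#' @return Numeric matrix with cell ids as rownames.
#' @export
read_embedding <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  m
}

# ---- minimal h5ad support (rhdf5 in Suggests) -------------------------------

need_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("h5ad support requires the rhdf5 package")
}

read_h5ad_matrix <- function(path) {
  need_rhdf5()
  idx <- rhdf5::h5ls(path)
  xinfo <- idx[idx$group == "/" & idx$name == "X", , drop = FALSE]
  obs <- as.character(rhdf5::h5read(path, "obs/_index"))
  var <- as.character(rhdf5::h5read(path, "var/_index"))
  if (nrow(xinfo) && xinfo$otype == "H5I_DATASET") {
    # h5ad stores X row-major as (obs, var); it arrives transposed in R
    m <- t(rhdf5::h5read(path, "X"))
  } else {
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    enc <- tryCatch(rhdf5::h5readAttributes(path, "X")[["encoding-type"]],
                    error = function(e) NULL) %||% "csr_matrix"
    dims <- c(length(obs), length(var))
    m <- if (grepl("csr", enc)) {
      # CSR over cells == CSC of the transposed matrix
      Matrix::t(Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                                     dims = rev(dims)))
    } else {
      Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data, dims = dims)
    }
  }
  if (nrow(m) != length(obs) || ncol(m) != length(var))
    stop("dimension error: X is ", nrow(m), "x", ncol(m), " but ids are ",
         length(obs), "/", length(var))
  if (anyDuplicated(obs)) stop("duplicate cell ids in obs/_index")
  dimnames(m) <- list(obs, var)
  m
}

write_h5ad_matrix <- function(mat, path) {
  need_rhdf5()
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  cells <- rownames(mat) %||% paste0("cell", seq_len(nrow(mat)))
  feats <- colnames(mat) %||% paste0("feature", seq_len(ncol(mat)))
  if (is(mat, "sparseMatrix")) {
    # store CSR over cells: CSC slots of t(mat)
    tm <- as(Matrix::t(mat), "CsparseMatrix")
    rhdf5::h5createGroup(path, "X")
    rhdf5::h5write(tm@x, path, "X/data")
    rhdf5::h5write(tm@i, path, "X/indices")
    rhdf5::h5write(tm@p, path, "X/indptr")
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, "X")
    rhdf5::h5writeAttribute("csr_matrix", gid, "encoding-type")
    rhdf5::h5writeAttribute(dim(mat), gid, "shape")
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
  } else {
    rhdf5::h5write(t(as.matrix(mat)), path, "X")
  }
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5createGroup(path, "var")
  rhdf5::h5write(cells, path, "obs/_index")
  rhdf5::h5write(feats, path, "var/_index")
  rhdf5::h5closeAll()
  invisible(path)
}
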