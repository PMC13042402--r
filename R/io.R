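#' Read an expression matrix from disk
#'
#' Supports the three formats single-cell expression tables commonly arrive
#' in: delimited text (comma or tab, auto-detected; first column holds row
#' identifiers), Matrix Market triplets with companion feature/barcode lists,
#' and AnnData HDF5 containers (`.h5ad`). Whatever the on-disk orientation,
#' the result is stored samples (cells) x genes. Values are never rescaled:
#' `norm_state` records what the caller says the numbers are, it is not
#' guessed from them.
#'
#' @param path file path. For `format = "mtx"` this is the `.mtx` file;
#'   feature/barcode lists are looked up next to it
#'   (`features.tsv`/`genes.tsv` and `barcodes.tsv`) unless given explicitly.
#' @param format one of `"auto"`, `"delimited"`, `"mtx"`, `"anndata"`.
#'   `"auto"` picks by file extension (`.mtx`, `.h5ad`, otherwise delimited).
#' @param orientation orientation of the file on disk. Defaults:
#'   `"genes_by_cells"` for delimited and Matrix Market files (the 10x
#'   convention), `"cells_by_genes"` for AnnData containers (the AnnData
#'   default).
#' @param norm_state normalization-state tag recorded on the result; see
#'   [expression_matrix()].
#' @param features,barcodes optional explicit paths to the Matrix Market
#'   companion files.
#' @return an [expression_matrix()], samples x genes.
#' @export
read_expression <- function(path,
                            format = c("auto", "delimited", "mtx", "anndata"),
                            orientation = NULL,
                            norm_state = "raw_counts",
                            features = NULL, barcodes = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", h5ad = "anndata", h5 = "anndata",
                     "delimited")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(orientation)) {
    orientation <- if (format == "anndata") "cells_by_genes" else
      "genes_by_cells"
  }
  orientation <- match.arg(orientation, c("genes_by_cells", "cells_by_genes"))
  values <- switch(format,
    delimited = read_delimited_matrix(path),
    mtx = read_mtx_matrix(path, features, barcodes),
    anndata = read_h5ad_matrix(path)
  )
  if (orientation == "genes_by_cells") values <- t(values)
  expression_matrix(values, norm_state = norm_state)
}

read_delimited_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L) stop("unparseable delimited matrix: ", path)
  ids <- as.character(dt[[1L]])
  values <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric entries in ", path)
  rownames(values) <- ids
  values
}

read_mtx_matrix <- function(path, features = NULL, barcodes = NULL) {
  m <- as.matrix(Matrix::readMM(path))
  dir <- dirname(path)
  if (is.null(features)) {
    for (cand in c("features.tsv", "genes.tsv")) {
      f <- file.path(dir, cand)
      if (file.exists(f)) { features <- f; break }
    }
  }
  if (is.null(barcodes)) {
    f <- file.path(dir, "barcodes.tsv")
    if (file.exists(f)) barcodes <- f
  }
  if (is.null(features) || is.null(barcodes)) {
    stop("Matrix Market input needs features.tsv/genes.tsv and barcodes.tsv ",
         "next to ", path, " (or explicit `features=`/`barcodes=` paths)")
  }
  feat <- data.table::fread(features, header = FALSE, data.table = FALSE)
  barc <- data.table::fread(barcodes, header = FALSE, data.table = FALSE)
  if (nrow(feat) != nrow(m) || nrow(barc) != ncol(m)) {
    stop("feature/barcode lists do not match matrix dimensions ",
         nrow(m), " x ", ncol(m))
  }
  # 10x features files carry id/symbol columns; use the last character column
  sym_col <- max(which(vapply(feat, is.character, logical(1L))))
  rownames(m) <- make.unique(as.character(feat[[sym_col]]))
  colnames(m) <- as.character(barc[[1L]])
  m
}

# Minimal AnnData (.h5ad) support: X stored dense or CSR/CSC, identifiers in
# obs/_index and var/_index (or the attribute-named index column).
read_h5ad_matrix <- function(path) {
  contents <- rhdf5::h5ls(path)
  obs <- read_h5ad_index(path, "obs")
  var <- read_h5ad_index(path, "var")
  x_rows <- contents[contents$group == "/" & contents$name == "X", ]
  if (nrow(x_rows) && x_rows$otype[1L] == "H5I_DATASET") {
    values <- rhdf5::h5read(path, "X")
    # HDF5 is row-major; rhdf5 returns the transposed (var x obs) array
    values <- t(values)
  } else {
    enc <- tryCatch(rhdf5::h5readAttributes(path, "X")$`encoding-type`,
                    error = function(e) NULL)
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    n_obs <- length(obs); n_var <- length(var)
    if (identical(enc, "csc_matrix")) {
      sm <- Matrix::sparseMatrix(i = indices + 1L, p = indptr,
                                 x = data, dims = c(n_obs, n_var))
    } else { # csr: row-compressed over obs
      sm <- Matrix::sparseMatrix(j = indices + 1L, p = indptr,
                                 x = data, dims = c(n_obs, n_var),
                                 repr = "R")
    }
    values <- as.matrix(sm)
  }
  if (nrow(values) != length(obs) || ncol(values) != length(var)) {
    stop("h5ad dimensions (", nrow(values), " x ", ncol(values),
         ") do not match obs/var index lengths")
  }
  rownames(values) <- obs
  colnames(values) <- var
  values
}

read_h5ad_index <- function(path, group) {
  idx_name <- tryCatch(rhdf5::h5readAttributes(path, group)$`_index`,
                       error = function(e) NULL)
  if (is.null(idx_name)) idx_name <- "_index"
  as.character(rhdf5::h5read(path, paste0(group, "/", idx_name)))
}

#' Write an expression matrix to disk
#'
#' Counterparts of the [read_expression()] formats. Delimited output is a
#' samples-x-genes table with row identifiers in the first column; Matrix
#' Market output writes `<stem>.mtx` plus `features.tsv` and `barcodes.tsv`
#' (genes x cells, the 10x convention); AnnData output writes a minimal
#' `.h5ad` with a dense `X` (cells x genes) and `obs`/`var` indices that
#' [read_expression()] and `anndata`/`scanpy` can both read.
#'
#' @param x an [expression_matrix()] or plain samples-x-genes matrix with
#'   dimnames.
#' @param path output path. For `format = "mtx"` the `.mtx` path; companions
#'   are written next to it.
#' @param format one of `"delimited"`, `"mtx"`, `"anndata"`.
#' @param sep field separator for delimited output.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path,
                             format = c("delimited", "mtx", "anndata"),
                             sep = ",") {
  format <- match.arg(format)
  values <- as_matrix(x)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("dimnames are required to write an expression matrix")
  }
  switch(format,
    delimited = {
      dt <- data.table::data.table(sample_id = rownames(values))
      dt <- cbind(dt, data.table::as.data.table(values))
      data.table::fwrite(dt, path, sep = sep)
    },
    mtx = {
      dir <- dirname(path)
      Matrix::writeMM(Matrix::Matrix(t(values), sparse = TRUE), path)
      writeLines(colnames(values), file.path(dir, "features.tsv"))
      writeLines(rownames(values), file.path(dir, "barcodes.tsv"))
    },
    anndata = write_h5ad_matrix(values, path)
  )
  invisible(path)
}

write_h5ad_matrix <- function(values, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  # transpose so the row-major file holds obs x var, matching anndata
  rhdf5::h5write(t(values), path, "X")
  for (group in c("obs", "var")) {
    rhdf5::h5createGroup(path, group)
    ids <- if (group == "obs") rownames(values) else colnames(values)
    rhdf5::h5write(ids, path, paste0(group, "/_index"))
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, group)
    rhdf5::h5writeAttribute("_index", gid, "_index",
                            variableLengthString = TRUE, asScalar = TRUE)
    rhdf5::h5writeAttribute("dataframe", gid, "encoding-type",
                            variableLengthString = TRUE, asScalar = TRUE)
    rhdf5::h5writeAttribute("0.2.0", gid, "encoding-version",
                            variableLengthString = TRUE, asScalar = TRUE)
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
  }
  invisible(path)
}
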