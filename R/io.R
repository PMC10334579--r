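# Readers/writers for the supported matrix formats. Orientation is fixed as
# cells x features everywhere: delimited text carries feature ids in the
# header and cell ids in the first column; matrix-market files carry their
# ids in two sidecar text files.

mtx_sidecars <- function(path) {
  stem <- sub("\\.mtx$", "", path)
  list(cells = paste0(stem, "_cells.txt"), features = paste0(stem, "_features.txt"))
}

#' Read a cells-by-features matrix
#'
#' Supports delimited text (header row = feature ids, first column = cell
#' ids) and matrix-market sparse triplets with `<stem>_cells.txt` /
#' `<stem>_features.txt` id sidecars. `format = "auto"` sniffs from the
#' file extension (`.mtx` vs anything delimited).
#'
#' @param path File path.
#' @param format `"auto"`, `"csv"`, or `"mtx"`.
#' @param modality Modality tag for the returned matrix.
#' @return A [modality_matrix()].
#' @export
load_matrix <- function(path, format = c("auto", "csv", "mtx"),
                        modality = "other") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "csv"
  }
  if (format == "csv") {
    dt <- data.table::fread(path, header = TRUE)
    ids <- as.character(dt[[1]])
    v <- as.matrix(dt[, -1, drop = FALSE])
    if (anyDuplicated(ids)) stop("duplicate cell ids in ", path)
    modality_matrix(v, cell_ids = ids, feature_ids = colnames(v),
                    modality = modality)
  } else {
    side <- mtx_sidecars(path)
    for (f in unlist(side)) {
      if (!file.exists(f)) {
        stop("missing id sidecar for matrix-market file: expected ", f)
      }
    }
    v <- as.matrix(Matrix::readMM(path))
    cells <- readLines(side$cells)
    feats <- readLines(side$features)
    if (length(cells) != nrow(v) || length(feats) != ncol(v)) {
      stop("sidecar id counts (", length(cells), " cells, ", length(feats),
           " features) do not match matrix dimensions ",
           nrow(v), " x ", ncol(v))
    }
    modality_matrix(v, cell_ids = cells, feature_ids = feats,
                    modality = modality)
  }
}

#' Write a cells-by-features matrix
#'
#' Inverse of [load_matrix()]; both formats round-trip float64 values
#' losslessly.
#'
#' @param m A [modality_matrix()].
#' @param path Output path.
#' @param format `"auto"` (from extension), `"csv"`, or `"mtx"`.
#' @export
write_matrix <- function(m, path, format = c("auto", "csv", "mtx")) {
  format <- match.arg(format)
  m <- as_modality(m)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "csv"
  }
  if (format == "csv") {
    dt <- data.table::data.table(cell_id = m$cell_ids)
    dt <- cbind(dt, data.table::as.data.table(m$values))
    data.table::fwrite(dt, path)
  } else {
    Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE), path)
    side <- mtx_sidecars(path)
    writeLines(m$cell_ids, side$cells)
    writeLines(m$feature_ids, side$features)
  }
  invisible(path)
}
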