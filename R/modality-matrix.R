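#' Cells-by-features matrix with identifiers and a modality tag
#'
#' The basic data container of the package: a dense numeric matrix of
#' `cells x features` together with unique cell and feature identifiers and a
#' tag naming the molecular modality the values come from. All pipeline
#' stages accept and return this container so identifiers are carried
#' through alignment, transport and inference.
#'
#' @param values Numeric matrix (cells in rows, features in columns). All
#'   entries must be finite.
#' @param cell_ids Character vector of unique cell identifiers; defaults to
#'   `rownames(values)` or `cell1..cellN`.
#' @param feature_ids Character vector of unique feature identifiers;
#'   defaults to `colnames(values)` or `f1..fM`.
#' @param modality One of `"other"`, `"rna"`, `"atac"`, `"protein"`.
#'
#' @return An object of class `ModalityMatrix`: a list with elements
#'   `values`, `cell_ids`, `feature_ids`, `modality`.
#' @examples
#' m <- modality_matrix(matrix(rpois(12, 5), 3, 4), modality = "rna")
#' dim(m)
#' @export
modality_matrix <- function(values,
                            cell_ids = rownames(values),
                            feature_ids = colnames(values),
                            modality = c("other", "rna", "atac", "protein")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  feature_ids <- as.character(feature_ids)
  if (length(cell_ids) != nrow(values)) {
    stop("length(cell_ids) [", length(cell_ids), "] != number of rows [",
         nrow(values), "]")
  }
  if (length(feature_ids) != ncol(values)) {
    stop("length(feature_ids) [", length(feature_ids), "] != number of columns [",
         ncol(values), "]")
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (anyDuplicated(feature_ids)) stop("duplicate feature_ids")
  if (!all(is.finite(values))) stop("values contain NaN/Inf/NA entries")
  dimnames(values) <- list(cell_ids, feature_ids)
  structure(
    list(values = values, cell_ids = cell_ids, feature_ids = feature_ids,
         modality = modality),
    class = "ModalityMatrix"
  )
}

#' @export
as.matrix.ModalityMatrix <- function(x, ...) x$values

#' @export
dim.ModalityMatrix <- function(x) dim(x$values)

#' @export
print.ModalityMatrix <- function(x, ...) {
  cat(sprintf("<ModalityMatrix> %d cells x %d features, modality = %s\n",
              nrow(x$values), ncol(x$values), x$modality))
  invisible(x)
}

# Coerce plain matrices on the way into pipeline stages.
as_modality <- function(x, modality = "other") {
  if (inherits(x, "ModalityMatrix")) return(x)
  modality_matrix(as.matrix(x), modality = modality)
}

# Rebuild a ModalityMatrix around new values, keeping ids/modality.
mm_replace <- function(m, values) {
  modality_matrix(values, cell_ids = m$cell_ids, feature_ids = m$feature_ids,
                  modality = m$modality)
}

#' Subset a ModalityMatrix to a set of features, by identifier
#'
#' Used to re-apply a feature selection computed on a reference matrix
#' (e.g., highly variable features of a training set) to another matrix.
#' Features are returned in the order of `feature_ids`.
#'
#' @param m A [modality_matrix()].
#' @param feature_ids Character vector of features to keep, all present in `m`.
#' @return A `ModalityMatrix` restricted (and reordered) to `feature_ids`.
#' @export
subset_features <- function(m, feature_ids) {
  m <- as_modality(m)
  missing <- setdiff(feature_ids, m$feature_ids)
  if (length(missing)) {
    stop("features not present in matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  modality_matrix(m$values[, feature_ids, drop = FALSE], cell_ids = m$cell_ids,
                  feature_ids = feature_ids, modality = m$modality)
}

#' Subset a ModalityMatrix to a set of cells
#'
#' @param m A [modality_matrix()].
#' @param cells Integer indices or cell identifiers.
#' @return A `ModalityMatrix` restricted to the requested cells.
#' @export
subset_cells <- function(m, cells) {
  m <- as_modality(m)
  v <- m$values[cells, , drop = FALSE]
  modality_matrix(v, cell_ids = rownames(v), feature_ids = m$feature_ids,
                  modality = m$modality)
}
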