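#' Select highly variable features
#'
#' Ranks features by their variance across cells and keeps the top
#' `n_features`. For count-like (nonnegative) input the variance is computed
#' on `log1p`-transformed values, which keeps a handful of extreme cells from
#' dominating the ranking; already-signed data (e.g., residuals) is ranked on
#' the raw values. The returned matrix has features ordered by descending
#' variance with ties broken lexicographically by feature id, so the
#' selection is fully deterministic and permutation-invariant in cell order.
#'
#' The selected `feature_ids` can be re-applied to a second matrix with
#' [subset_features()], e.g., to subset an evaluation dataset by the highly
#' variable features of a reference/training dataset.
#'
#' @param m A [modality_matrix()].
#' @param n_features Number of features to keep (1..ncol).
#' @param use_log1p `NULL` (auto: `TRUE` when all values are nonnegative),
#'   or an explicit logical.
#' @return A `ModalityMatrix` with `n_features` columns in variance order.
#' @export
select_highly_variable <- function(m, n_features, use_log1p = NULL) {
  m <- as_modality(m)
  p <- ncol(m$values)
  if (n_features < 1 || n_features > p) {
    stop("n_features [", n_features, "] must be between 1 and the number of features [",
         p, "]")
  }
  x <- m$values
  if (is.null(use_log1p)) use_log1p <- all(x >= 0)
  if (use_log1p) {
    if (any(x < 0)) stop("log1p transform requested on negative values")
    x <- log1p(x)
  }
  v <- col_vars(x)
  if (all(v == 0)) {
    warning("all features have zero variance; returning the first ",
            n_features, " features in lexicographic id order")
  }
  ord <- order(-v, m$feature_ids)
  keep <- ord[seq_len(n_features)]
  modality_matrix(m$values[, keep, drop = FALSE], cell_ids = m$cell_ids,
                  feature_ids = m$feature_ids[keep], modality = m$modality)
}

#' TF-IDF transform for peak count matrices
#'
#' Standard reweighting of chromatin-accessibility counts: term frequency
#' `TF(i,j) = x[i,j] / rowsum(i)` scaled by inverse document frequency
#' `IDF(j) = log(1 + n_cells / (1 + n_cells_with_nonzero_j))`. Cells with no
#' counts map to all-zero rows.
#'
#' @param m A nonnegative [modality_matrix()] (typically `modality = "atac"`).
#' @return A `ModalityMatrix` of the same shape.
#' @export
tfidf_transform <- function(m) {
  m <- as_modality(m)
  x <- m$values
  if (any(x < 0)) stop("tfidf_transform requires nonnegative values")
  rs <- rowSums(x)
  rs[rs == 0] <- 1  # all-zero rows stay all-zero
  tf <- x / rs
  idf <- log(1 + nrow(x) / (1 + colSums(x > 0)))
  mm_replace(m, sweep(tf, 2, idf, `*`))
}

#' Centered log-ratio normalization, per cell
#'
#' The convention used for antibody-derived protein counts: per cell,
#' `out[i,j] = log1p(x[i,j]) - mean_j log1p(x[i,j])`. Every output row sums
#' to zero.
#'
#' @param m A nonnegative [modality_matrix()].
#' @return A `ModalityMatrix` whose rows are centered on the log scale.
#' @export
clr_normalize <- function(m) {
  m <- as_modality(m)
  if (any(m$values < 0)) stop("clr_normalize requires nonnegative values")
  lx <- log1p(m$values)
  mm_replace(m, lx - rowMeans(lx))
}

#' Library-size log-normalization
#'
#' Scales each cell to a fixed library size (default 1e4 total counts) and
#' applies `log1p`. Scale-invariant per cell: multiplying a cell's counts by
#' a constant leaves its output unchanged. All-zero cells are left as zeros
#' with a warning naming them.
#'
#' @param m A nonnegative count [modality_matrix()].
#' @param scale_factor Target library size (default `1e4`).
#' @return A log-normalized `ModalityMatrix`.
#' @export
lognorm <- function(m, scale_factor = 1e4) {
  m <- as_modality(m)
  x <- m$values
  if (any(x < 0)) stop("lognorm requires nonnegative counts")
  rs <- rowSums(x)
  zero <- rs == 0
  if (any(zero)) {
    warning("all-zero cells left unscaled: ",
            paste(m$cell_ids[zero], collapse = ", "))
    rs[zero] <- 1
  }
  mm_replace(m, log1p(x / rs * scale_factor))
}

#' Binarize a matrix at a cutoff
#'
#' Values at or above `cutoff` become 1, the rest 0. `strict = TRUE` uses a
#' strictly-greater comparison instead, which with `cutoff = 0` gives the
#' usual presence/absence indicator for raw peak counts.
#'
#' @param m A [modality_matrix()].
#' @param cutoff Finite threshold (default 0.5).
#' @param strict Use `>` instead of `>=`.
#' @return A 0/1 `ModalityMatrix`. Idempotent at `cutoff = 0.5` on its own
#'   output.
#' @export
binarize <- function(m, cutoff = 0.5, strict = FALSE) {
  m <- as_modality(m)
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  b <- if (strict) m$values > cutoff else m$values >= cutoff
  mm_replace(m, b + 0)
}

#' Drop features observed in too few cells
#'
#' Generic minimum-cells filter: keeps features with a nonzero value in at
#' least `min_cells` cells.
#'
#' @param m A [modality_matrix()].
#' @param min_cells Minimum number of cells a feature must appear in.
#' @return A filtered `ModalityMatrix`.
#' @export
filter_min_cells <- function(m, min_cells = 3) {
  m <- as_modality(m)
  keep <- colSums(m$values != 0) >= min_cells
  if (!any(keep)) stop("no feature occurs in at least ", min_cells, " cells")
  subset_features(m, m$feature_ids[keep])
}
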