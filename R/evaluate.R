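# Metric suite for judging inferred modalities against measurements.

eval_values <- function(x) if (inherits(x, "ModalityMatrix")) x$values else as.matrix(x)

check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b))) {
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  }
}

# Row-wise Pearson correlation between two equal-shape matrices; rows with
# zero variance on either side come back NA.
rowwise_pearson <- function(a, b) {
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  sa <- sqrt(rowSums(ac * ac))
  sb <- sqrt(rowSums(bc * bc))
  r <- rowSums(ac * bc) / (sa * sb)
  r[sa == 0 | sb == 0] <- NA_real_
  r
}

#' Cell-wise Pearson correlation
#'
#' Correlation between the inferred and measured profile of each cell
#' (across features). Cells whose inferred or measured profile has zero
#' variance are undefined and returned as `NA`, with their count in
#' attribute `n_undefined`.
#'
#' @param inferred,measured Matrices or [modality_matrix()] objects of
#'   identical shape (cells x features, >= 2 features).
#' @return Numeric vector of per-cell correlations in [-1, 1].
#' @export
cellwise_pearson <- function(inferred, measured) {
  a <- eval_values(inferred); b <- eval_values(measured)
  check_same_shape(a, b)
  if (ncol(a) < 2) stop("need at least 2 features")
  r <- rowwise_pearson(a, b)
  attr(r, "n_undefined") <- sum(is.na(r))
  r
}

#' Feature-wise (gene-wise) Pearson correlation
#'
#' Correlation between inferred and measured values of each feature across
#' cells. Zero-variance features are `NA` (counted in `n_undefined`).
#'
#' @inheritParams cellwise_pearson
#' @return Numeric vector of per-feature correlations.
#' @seealso [count_improved()] for the "number of features with improved
#'   correlation" comparison between two methods.
#' @export
featurewise_pearson <- function(inferred, measured) {
  a <- eval_values(inferred); b <- eval_values(measured)
  check_same_shape(a, b)
  if (nrow(a) < 2) stop("need at least 2 cells")
  r <- rowwise_pearson(t(a), t(b))
  attr(r, "n_undefined") <- sum(is.na(r))
  r
}

#' Count features on which method A beats method B
#'
#' @param r_a,r_b Per-feature scores (e.g., from [featurewise_pearson()]).
#' @return Number of features with `r_a > r_b` (NA pairs dropped).
#' @export
count_improved <- function(r_a, r_b) {
  sum(r_a > r_b, na.rm = TRUE)
}

#' One-sided Wilcoxon rank-sum test
#'
#' Tests whether scores `a` are stochastically greater than scores `b`
#' using the normal approximation to the rank-sum statistic with tie
#' correction and continuity correction. Completely tied inputs return
#' p = 0.5 with a warning.
#'
#' @param a,b Numeric score vectors (>= 3 values each).
#' @return One-sided p-value for the alternative `a > b`.
#' @export
wilcoxon_onesided <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) stop("need at least 3 values per group")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  rk <- rank(c(a, b))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(rk)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 == 0) {
    warning("all values tied; returning p = 0.5")
    return(0.5)
  }
  z <- (U - n1 * n2 / 2 - 0.5) / sqrt(sigma2)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Area under the precision-recall curve, one-vs-all
#'
#' Sweeps thresholds down the score range, computing precision and recall
#' at every distinct score, and accumulates the area by step interpolation
#' (`sum(precision_i * (recall_i - recall_{i-1}))`, no linear
#' interpolation). The baseline is the positive rate `n_pos / n_total` —
#' the AUPRC of an uninformative scorer.
#'
#' @param scores Numeric score per cell (higher = more positive).
#' @param positives Logical (or 0/1) label per cell; both classes must be
#'   present.
#' @return List with `auprc` and `baseline`.
#' @export
auprc_one_vs_all <- function(scores, positives) {
  positives <- as.logical(positives)
  if (length(scores) != length(positives)) stop("shape mismatch")
  n_pos <- sum(positives); n_neg <- sum(!positives)
  if (n_pos == 0 || n_neg == 0) stop("need at least one positive and one negative")
  ord <- order(-scores)
  s <- scores[ord]; y <- positives[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each distinct score
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  auprc <- sum(precision * diff(c(0, recall)))
  list(auprc = auprc, baseline = n_pos / length(scores))
}

# AUROC of scores against binary labels via the rank (Mann-Whitney)
# statistic; NA when only one class is present.
auroc_rank <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  rk <- rank(scores)
  (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Peak-wise AUROC of inferred accessibility against measured binary peaks
#'
#' For every peak (column), the AUROC of the inferred scores against the
#' measured 0/1 profile across cells, computed from the rank statistic
#' (equivalent to the Mann-Whitney U divided by `n1 * n0`, which handles
#' ties by midranks). Peaks observed in only one class are `NA`.
#'
#' @param inferred Matrix of inferred peak scores (cells x peaks); may be
#'   pre-binarization values in [0, 1].
#' @param measured Matrix of measured binary peaks, entries in {0, 1}.
#' @return Numeric vector of per-peak AUROCs.
#' @export
peakwise_auroc <- function(inferred, measured) {
  a <- eval_values(inferred); b <- eval_values(measured)
  check_same_shape(a, b)
  if (!all(b %in% c(0, 1))) stop("measured entries must be 0/1")
  vapply(seq_len(ncol(a)), function(j) auroc_rank(a[, j], b[, j]), numeric(1))
}

#' Silhouette scores
#'
#' Per-cell silhouette \deqn{S(m) = \frac{E(m) - e(m)}{\max(E(m), e(m))}}
#' where `e(m)` is the average distance of cell m to the other members of
#' its own cluster and `E(m)` is the average distance to the closest other
#' cluster. Cells in singleton clusters score 0 by convention. Euclidean
#' distances.
#'
#' @param x Embedding or data matrix (cells x dims), or a
#'   [modality_matrix()].
#' @param labels Cluster label per cell; at least two clusters.
#' @return List with per-cell `scores` and their `median`.
#' @export
silhouette_scores <- function(x, labels) {
  x <- eval_values(x)
  labels <- as.vector(labels)
  cl <- unique(labels)
  if (length(cl) < 2) stop("need at least 2 clusters")
  d <- sqrt(sq_dist(x, x))
  n <- nrow(x)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { scores[i] <- 0; next }
    e_m <- sum(d[i, own]) / (sum(own) - 1)       # excludes d[i,i] = 0
    E_m <- min(vapply(cl[cl != labels[i]], function(g) {
      mean(d[i, labels == g])
    }, numeric(1)))
    denom <- max(E_m, e_m)
    scores[i] <- if (denom == 0) 0 else (E_m - e_m) / denom
  }
  list(scores = scores, median = stats::median(scores))
}

#' Select the most predictive cells per class by cell-wise correlation
#'
#' Ranks cells within each class by their cell-wise Pearson correlation and
#' keeps the top `n_per_class`, supporting class-balanced downstream
#' classification metrics when class sizes are disproportionate.
#'
#' @param cellwise_r Per-cell correlations (e.g., [cellwise_pearson()]).
#' @param classes Class label per cell.
#' @param n_per_class Cells to keep from each class (default 8).
#' @return Integer indices of the selected cells.
#' @export
top_predictive_cells <- function(cellwise_r, classes, n_per_class = 8) {
  idx <- split(seq_along(cellwise_r), classes)
  unlist(lapply(idx, function(i) {
    i[order(-cellwise_r[i])][seq_len(min(n_per_class, length(i)))]
  }), use.names = FALSE)
}
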