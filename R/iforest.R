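# Minimal isolation forest: random axis-aligned splits isolate anomalous
# rows in few steps; the anomaly score is 2^(-E[path length]/c(psi)).

# average path length of an unsuccessful BST search among n points
if_avg_path <- function(n) {
  ifelse(n <= 1, 0, 2 * (log(n - 1) + 0.5772156649015329) - 2 * (n - 1) / n)
}

if_build <- function(x, depth, limit) {
  n <- nrow(x)
  if (n <= 1 || depth >= limit) {
    return(list(leaf = TRUE, size = n))
  }
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  splittable <- which(hi > lo)
  if (!length(splittable)) return(list(leaf = TRUE, size = n))
  q <- if (length(splittable) == 1) splittable else sample(splittable, 1)
  s <- stats::runif(1, lo[q], hi[q])
  left <- x[, q] < s
  list(leaf = FALSE, q = q, s = s,
       left = if_build(x[left, , drop = FALSE], depth + 1, limit),
       right = if_build(x[!left, , drop = FALSE], depth + 1, limit))
}

# path length of every row of x through one tree
if_paths <- function(tree, x, depth = 0) {
  out <- numeric(nrow(x))
  if (tree$leaf) {
    out[] <- depth + if_avg_path(tree$size)
    return(out)
  }
  left <- x[, tree$q] < tree$s
  if (any(left)) out[left] <- if_paths(tree$left, x[left, , drop = FALSE], depth + 1)
  if (any(!left)) out[!left] <- if_paths(tree$right, x[!left, , drop = FALSE], depth + 1)
  out
}

#' Isolation-forest anomaly scores
#'
#' Fits an ensemble of isolation trees on random subsamples of the rows and
#' scores every row by `2^(-mean path length / c(sample_size))`. Scores near
#' 1 indicate easily isolated (anomalous) rows; scores well below 0.5
#' indicate ordinary rows.
#'
#' @param x Numeric matrix (rows = samples).
#' @param n_trees Number of trees (default 100).
#' @param sample_size Subsample size per tree (default `min(256, nrow(x))`).
#' @param seed Integer seed for the ensemble.
#' @return Numeric vector of anomaly scores in (0, 1).
#' @export
iforest_score <- function(x, n_trees = 100, sample_size = min(256L, nrow(x)),
                          seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 rows")
  limit <- ceiling(log2(max(sample_size, 2)))
  paths <- with_seed(seed, {
    acc <- matrix(0, n, n_trees)
    for (t in seq_len(n_trees)) {
      idx <- sample.int(n, sample_size)
      tree <- if_build(x[idx, , drop = FALSE], 0, limit)
      acc[, t] <- if_paths(tree, x)
    }
    acc
  })
  2^(-rowMeans(paths) / if_avg_path(sample_size))
}

#' Flag poorly mapped target cells
#'
#' Target cells whose distribution differs from every source cell (e.g., a
#' cell type absent from the source data) cannot be inferred reliably. They
#' are detected from the element-wise product \eqn{P = \pi^{*T} \circ C^T}
#' (`s_Yhat x s_Y`): each target cell's row records where its coupling mass
#' went and how costly those assignments were. `P` is projected onto the
#' smallest set of principal components explaining at least `variance_keep`
#' of the variance, and an isolation forest is run on the projected rows.
#' A warning reports the percentage of target cells flagged as poorly
#' mapped, which the caller may choose to drop before inference.
#'
#' @param plan A `TransportPlan`.
#' @param variance_keep Cumulative explained-variance threshold of the PCA
#'   projection (default 0.95).
#' @param contamination `"auto"` (flag anomaly scores above 0.5) or a
#'   fraction in (0, 0.5): flag that proportion of highest-scoring cells.
#' @param seed Integer seed for the isolation forest.
#' @param n_trees Trees in the ensemble.
#' @return An `OutlierReport`: logical `flags`, numeric `score`,
#'   `fraction_flagged`, and `skipped` (TRUE when fewer than 5 target cells).
#' @export
flag_outlier_targets <- function(plan, variance_keep = 0.95,
                                 contamination = "auto", seed = 1,
                                 n_trees = 100) {
  n <- ncol(plan$pi)
  if (n < 5) {
    warning("fewer than 5 target cells; outlier detection skipped")
    return(structure(list(flags = rep(FALSE, n), score = rep(NA_real_, n),
                          fraction_flagged = 0, skipped = TRUE),
                     class = "OutlierReport"))
  }
  P <- t(plan$pi) * t(plan$cost)
  pc <- stats::prcomp(P, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) == 0) {
    flags <- rep(FALSE, n)
    return(structure(list(flags = flags, score = rep(0, n),
                          fraction_flagged = 0, skipped = FALSE),
                     class = "OutlierReport"))
  }
  ncomp <- which(cumsum(v) / sum(v) >= variance_keep)[1]
  Z <- pc$x[, seq_len(ncomp), drop = FALSE]
  score <- iforest_score(Z, n_trees = n_trees, seed = seed)
  if (identical(contamination, "auto")) {
    flags <- score > 0.5
  } else {
    contamination <- as.numeric(contamination)
    if (!(contamination > 0 && contamination < 0.5)) {
      stop("contamination must be 'auto' or a fraction in (0, 0.5)")
    }
    k <- ceiling(contamination * n)
    flags <- rep(FALSE, n)
    flags[order(-score)[seq_len(k)]] <- TRUE
  }
  frac <- mean(flags)
  if (any(flags)) {
    warning(sprintf("%.1f%% of target cells are poorly mapped and may be removed",
                    100 * frac))
  }
  structure(list(flags = flags, score = score, fraction_flagged = frac,
                 skipped = FALSE),
            class = "OutlierReport")
}
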