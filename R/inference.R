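#' Weighted k-nearest-neighbour inference of the missing modality
#'
#' For each target cell \eqn{\hat y_j}, finds its k nearest transported
#' source cells in \eqn{Y^{(t)}} by Euclidean distance (optionally
#' restricted to a feature subset such as the top highly variable features),
#' weights them by \eqn{w_j^l \propto e^{-\|\hat y_j - y^l\|}} normalized to
#' sum to 1, and returns the weighted average of their missing-modality
#' profiles. Weights are computed with the smallest distance subtracted
#' before exponentiation, which leaves the normalized weights unchanged but
#' avoids underflow for distant neighbour sets.
#'
#' @param Yt Transported source cells (`s_Y x d_Y`), from
#'   [barycentric_map()].
#' @param Yhat Target cells on the shared modality (`s_Yhat x d_Y`).
#' @param X_aligned Missing-modality profiles row-aligned with `Yt` (same
#'   source cells, same order).
#' @param k Number of neighbours, `k <= s_Y`.
#' @param search_features Optional feature ids used for the neighbour
#'   search (default: all shared features).
#' @return An `InferenceResult`: `Xhat` (`s_Yhat x d_X` [modality_matrix()]),
#'   integer `neighbors` (`s_Yhat x k`), `weights` (`s_Yhat x k`, rows sum
#'   to 1) and `outlier_flags` (`NULL` here; filled by [run_cmot()]).
#' @export
knn_infer <- function(Yt, Yhat, X_aligned, k, search_features = NULL) {
  Yt <- as_modality(Yt); Yhat <- as_modality(Yhat)
  X_aligned <- as_modality(X_aligned)
  s_Y <- nrow(Yt$values)
  if (nrow(X_aligned$values) != s_Y) {
    stop("Yt and X_aligned must be row-aligned (same source cells)")
  }
  if (k > s_Y) stop("k [", k, "] exceeds the number of source cells [", s_Y, "]")
  if (!is.null(search_features)) {
    if (!length(search_features)) stop("search_features is empty")
    Yt_s <- subset_features(Yt, search_features)$values
    Yh_s <- subset_features(Yhat, search_features)$values
  } else {
    if (!identical(Yt$feature_ids, Yhat$feature_ids)) {
      stop("Yt and Yhat must share identical feature_ids")
    }
    Yt_s <- Yt$values; Yh_s <- Yhat$values
  }
  d <- sqrt(sq_dist(Yh_s, Yt_s))  # targets x sources
  n_t <- nrow(d)
  neighbors <- matrix(0L, n_t, k)
  weights <- matrix(0, n_t, k)
  Xhat <- matrix(0, n_t, ncol(X_aligned$values))
  for (j in seq_len(n_t)) {
    ord <- order(d[j, ])[seq_len(k)]  # stable ties -> lower source index
    dj <- d[j, ord]
    w <- exp(-(dj - dj[1]))
    w <- w / sum(w)
    neighbors[j, ] <- ord
    weights[j, ] <- w
    Xhat[j, ] <- w %*% X_aligned$values[ord, , drop = FALSE]
  }
  structure(list(
    Xhat = modality_matrix(Xhat, cell_ids = Yhat$cell_ids,
                           feature_ids = X_aligned$feature_ids,
                           modality = X_aligned$modality),
    neighbors = neighbors,
    weights = weights,
    outlier_flags = NULL
  ), class = "InferenceResult")
}

#' @export
print.InferenceResult <- function(x, ...) {
  cat(sprintf("<InferenceResult> inferred %d cells x %d features (k = %d)\n",
              nrow(x$Xhat$values), ncol(x$Xhat$values), ncol(x$neighbors)))
  if (!is.null(x$outlier_flags) && any(x$outlier_flags)) {
    cat(sprintf("  %d target cells flagged as poorly mapped\n",
                sum(x$outlier_flags)))
  }
  invisible(x)
}

#' Full cross-modality inference pipeline
#'
#' Orchestrates the three stages: (A) manifold alignment of the source
#' modalities when correspondence is partial (`p < 1`), after which each
#' shared-modality cell is re-keyed to its nearest missing-modality cell in
#' the joint embedding; (B) entropic optimal transport with label
#' regularization between source and target cells on the shared modality,
#' followed by isolation-forest flagging of poorly mapped targets and
#' barycentric mapping of source cells into target space; (C) weighted
#' k-nearest-neighbour inference of the missing modality. With `p = 1`
#' (fully corresponding source cells) alignment is skipped and the
#' missing-modality rows are used directly, keyed by the shared row order.
#'
#' Default parameters follow a typical chromatin-to-expression
#' configuration (`K = 5`, `d = 20`, `lambda = 200`, `eta = 1`, `k = 600`);
#' on small datasets pass smaller `d` and `k`. The user-facing `lambda` is
#' converted to the solver's entropic weight as `epsilon = 1 / lambda`
#' (large `lambda` gives sharp, near-LP couplings on the max-normalized
#' cost scale); pass `epsilon` to override the mapping.
#'
#' @param X Source missing-modality [modality_matrix()] (`s_X` cells).
#' @param Y Source shared-modality `ModalityMatrix` (`s_Y` cells; with full
#'   correspondence rows match `X`).
#' @param Yhat Target shared-modality `ModalityMatrix` (same features as `Y`).
#' @param labels Optional class id per source cell; if `NULL` and `eta > 0`,
#'   labels are induced by [induce_labels()] with `n_clusters` clusters.
#' @param p Correspondence fraction in (0, 1]; `p < 1` triggers alignment.
#' @param K,d,mu Alignment parameters (see [align_modalities()]).
#' @param lambda Entropic regularization weight on the sharp-coupling scale
#'   (larger `lambda`, sharper coupling).
#' @param eta Label regularization weight (0 disables).
#' @param k Neighbours for modality inference.
#' @param search_features Optional feature ids (e.g., top HVGs) used for
#'   both the transport cost and the neighbour search.
#' @param n_clusters Clusters for induced labels (default 2).
#' @param epsilon Optional explicit entropic weight overriding `1 / lambda`.
#' @param max_iter,tol Inner Sinkhorn controls.
#' @param flag_outliers Run the isolation-forest target filter.
#' @param contamination Passed to [flag_outlier_targets()].
#' @param seed Seed for correspondence subsampling and the outlier filter.
#' @param log Optional run log from [run_log_open()].
#' @return An `InferenceResult` with `outlier_flags` filled in, plus the
#'   `plan` (`TransportPlan`), `embedding` (or `NULL`), `labels` used, and
#'   `Yt` (transported source cells). Flagged cells are inferred anyway and
#'   only marked; removal is left to the caller.
#' @export
run_cmot <- function(X, Y, Yhat, labels = NULL, p = 1,
                     K = 5, d = 20, mu = 0.5,
                     lambda = 200, eta = 1, k = 600,
                     search_features = NULL, n_clusters = 2,
                     epsilon = NULL, max_iter = 1000L, tol = 1e-9,
                     flag_outliers = TRUE, contamination = "auto",
                     seed = 1, log = NULL) {
  X <- as_modality(X); Y <- as_modality(Y); Yhat <- as_modality(Yhat)
  if (!identical(Y$feature_ids, Yhat$feature_ids)) {
    stop("transport stage: Y and Yhat must share identical feature_ids")
  }
  eps <- epsilon %||% (1 / lambda)

  # --- Step A: alignment (only needed for partial correspondence) ---------
  embedding <- NULL
  if (p < 1) {
    if (nrow(X$values) != nrow(Y$values)) {
      stop("alignment stage: X and Y must profile the same source cells")
    }
    pairs <- subsample_correspondence(full_pairing(nrow(Y$values)), p, seed)
    embedding <- align_modalities(X, Y, pairs, K = K, d = d, mu = mu)
    xa <- match_aligned(embedding)
    # re-key to Y's cell order: row j now holds the X profile matched to y_j
    X_aligned <- modality_matrix(X$values[xa, , drop = FALSE],
                                 cell_ids = Y$cell_ids,
                                 feature_ids = X$feature_ids,
                                 modality = X$modality)
    log_event(log, "align", message = "manifold alignment",
              params = list(p = p, K = K, d = d, mu = mu,
                            objective = embedding$objective))
  } else {
    if (nrow(X$values) != nrow(Y$values)) {
      stop("with p = 1, X and Y must be row-aligned (same source cells)")
    }
    X_aligned <- X
  }

  # --- Step B: optimal transport ------------------------------------------
  if (is.null(labels) && eta > 0) {
    labels <- induce_labels(Y, n_clusters)
    log_event(log, "transport", message = "induced labels by hierarchical clustering",
              params = list(n_clusters = n_clusters))
  }
  Y_c <- if (is.null(search_features)) Y else subset_features(Y, search_features)
  Yh_c <- if (is.null(search_features)) Yhat else subset_features(Yhat, search_features)
  C <- cost_matrix(Y_c, Yh_c)
  plan <- if (eta > 0) {
    sinkhorn_label_reg(C, labels = labels, epsilon = eps, eta = eta,
                       max_iter = max_iter, tol = tol)
  } else {
    sinkhorn(C, epsilon = eps, max_iter = max_iter, tol = tol)
  }
  log_event(log, "transport",
            params = list(lambda = lambda, eta = eta, epsilon = eps,
                          n_iter = plan$n_iter, converged = plan$converged,
                          residual = plan$marginal_residual))

  flags <- rep(FALSE, nrow(Yhat$values))
  if (flag_outliers && nrow(Yhat$values) >= 5) {
    report <- withCallingHandlers(
      flag_outlier_targets(plan, contamination = contamination, seed = seed),
      warning = function(w) {
        log_event(log, "outliers", type = "warning",
                  message = conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    flags <- report$flags
    log_event(log, "outliers",
              params = list(fraction_flagged = report$fraction_flagged))
  }

  Yt <- barycentric_map(plan, Yhat)

  # --- Step C: kNN inference ----------------------------------------------
  res <- knn_infer(Yt, Yhat, X_aligned, k = k,
                   search_features = search_features)
  res$outlier_flags <- flags
  res$plan <- plan
  res$embedding <- embedding
  res$labels <- labels
  res$Yt <- Yt
  log_event(log, "infer", params = list(k = k))
  res
}
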