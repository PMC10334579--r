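#' Scale-normalized squared-Euclidean cost matrix
#'
#' Pairwise cost of mapping each source cell onto each target cell on the
#' shared modality: squared Euclidean distance divided by its maximum, so
#' costs live in [0, 1] and are invariant to a global rescaling of the
#' input. Requires the two matrices to carry the same features in the same
#' order.
#'
#' @param Y Source [modality_matrix()] (shared modality).
#' @param Yhat Target `ModalityMatrix` with identical `feature_ids`.
#' @return A `s_Y x s_Yhat` matrix in [0, 1] (all zero if every pair is
#'   identical), with cell ids as dimnames.
#' @export
cost_matrix <- function(Y, Yhat) {
  Y <- as_modality(Y); Yhat <- as_modality(Yhat)
  if (!identical(Y$feature_ids, Yhat$feature_ids)) {
    stop("source and target must share identical feature_ids (same order)")
  }
  stopifnot_finite(Y$values, "Y"); stopifnot_finite(Yhat$values, "Yhat")
  C <- sq_dist(Y$values, Yhat$values)
  mx <- max(C)
  if (mx > 0) C <- C / mx
  dimnames(C) <- list(Y$cell_ids, Yhat$cell_ids)
  C
}

new_transport_plan <- function(pi, C, a, b, n_iter, converged, log_domain,
                               residual, potentials = NULL) {
  dimnames(pi) <- dimnames(C)
  structure(list(pi = pi, cost = C, a = a, b = b, n_iter = n_iter,
                 converged = converged, log_domain = log_domain,
                 marginal_residual = residual, potentials = potentials),
            class = "TransportPlan")
}

#' @export
print.TransportPlan <- function(x, ...) {
  cat(sprintf(
    "<TransportPlan> %d x %d, %d iterations, converged = %s (residual %.2e)%s\n",
    nrow(x$pi), ncol(x$pi), x$n_iter, x$converged, x$marginal_residual,
    if (x$log_domain) ", log-domain" else ""))
  invisible(x)
}

#' Entropic optimal transport by Sinkhorn scaling
#'
#' Solves \deqn{\min_{\pi \in \Pi(a,b)} \langle \pi, C\rangle
#'   + \epsilon \sum_{ij} \pi_{ij} \log \pi_{ij}}
#' by alternating row/column scaling. `epsilon` is the entropic weight: the
#' larger it is the denser (higher entropy) the coupling, while
#' `epsilon -> 0` approaches the sharp linear-programming optimum. For small
#' `epsilon` (below `1e-2 * mean(C)` by default) iterations run in the log
#' domain with epsilon-scaling warm starts to avoid numerical underflow.
#'
#' The returned coupling has exact row marginals `a` (final row scaling) and
#' column marginals within the reported residual; `converged` is `TRUE` when
#' that residual dropped below `tol`.
#'
#' @param C Nonnegative cost matrix (`n x m`).
#' @param a,b Strictly positive marginals summing to 1; default uniform.
#' @param epsilon Entropic regularization weight (> 0).
#' @param max_iter Maximum Sinkhorn iterations at the final epsilon.
#' @param tol Convergence tolerance on the max-norm marginal violation.
#' @param log_domain `"auto"` (default), `"on"`, or `"off"`.
#' @param init Optional warm-start dual potentials `list(f, g)` (on the
#'   cost scale), e.g., the `potentials` element of a previous plan on the
#'   same marginals.
#' @return A `TransportPlan`: `pi`, `cost`, `a`, `b`, `n_iter`, `converged`,
#'   `log_domain`, `marginal_residual`, `potentials`.
#' @export
sinkhorn <- function(C, a = NULL, b = NULL, epsilon = 0.01,
                     max_iter = 1000L, tol = 1e-9,
                     log_domain = c("auto", "on", "off"), init = NULL) {
  log_domain <- match.arg(log_domain)
  C <- as.matrix(C)
  stopifnot_finite(C, "cost matrix")
  n <- nrow(C); m <- ncol(C)
  a <- a %||% rep(1 / n, n)
  b <- b %||% rep(1 / m, m)
  if (any(a <= 0) || any(b <= 0)) stop("marginals must be strictly positive")
  if (abs(sum(a) - 1) > 1e-8 || abs(sum(b) - 1) > 1e-8) {
    stop("marginals must each sum to 1")
  }
  if (epsilon <= 0) stop("epsilon must be > 0 (entropic weight)")
  # scale heuristics use the median cost: a minority of near-prohibitive
  # entries (e.g., linearized group penalties) must not inflate the scale
  use_log <- switch(log_domain,
                    on = TRUE, off = FALSE,
                    auto = epsilon < 1e-2 * stats::median(C))
  if (use_log) {
    sinkhorn_log(C, a, b, epsilon, max_iter, tol, init)
  } else {
    sinkhorn_std(C, a, b, epsilon, max_iter, tol, init)
  }
}

# Iterations end on the row update, so the coupling handed back (rows exactly
# a) is the object whose column violation the convergence test measured.
sinkhorn_std <- function(C, a, b, epsilon, max_iter, tol, init = NULL) {
  K <- exp(-C / epsilon)
  if (any(rowSums(K) == 0) || any(colSums(K) == 0)) {
    return(sinkhorn_log(C, a, b, epsilon, max_iter, tol, init))
  }
  u <- rep(1, length(a)); v <- rep(1, length(b))
  if (!is.null(init)) {
    u0 <- exp((init$f - max(init$f)) / epsilon)
    v0 <- exp((init$g - min(init$g)) / epsilon)
    if (all(is.finite(u0)) && all(u0 > 0) && all(is.finite(v0)) && all(v0 > 0)) {
      u <- u0; v <- v0
    }
  }
  it <- 0L; res <- Inf
  while (it < max_iter) {
    it <- it + 1L
    v <- b / as.vector(crossprod(K, u))
    u <- a / as.vector(K %*% v)
    if (!all(is.finite(u)) || !all(is.finite(v))) {
      return(sinkhorn_log(C, a, b, epsilon, max_iter, tol, init))
    }
    if (it %% 10L == 0L || it == max_iter) {
      res <- max(abs(v * as.vector(crossprod(K, u)) - b))
      if (res <= tol) break
    }
  }
  pi <- (u * K) %*% diag(v, length(v))
  pi <- pi * (a / rowSums(pi))  # exact rows; columns hold the residual
  res <- max(abs(colSums(pi) - b))
  new_transport_plan(pi, C, a, b, it, res <= tol, FALSE, res,
                     potentials = list(f = epsilon * log(u), g = epsilon * log(v)))
}

# Stabilized scaling iterations: plain u/v updates on the kernel
# exp((f + g - C)/eps), absorbing the scalings into the dual potentials
# f, g whenever they threaten the double range. Handles arbitrarily small
# epsilon (and effectively prohibited entries) without freezing.
sinkhorn_log <- function(C, a, b, epsilon, max_iter, tol, init = NULL) {
  n <- nrow(C)
  f <- if (!is.null(init)) init$f else rep(0, length(a))
  g <- if (!is.null(init)) init$g else rep(0, length(b))
  tiny <- .Machine$double.xmin
  absorb_at <- 1e100
  # epsilon-scaling ladder: approach small epsilon through a geometric
  # sequence of levels, carrying the dual potentials down as warm starts
  eps0 <- max(stats::median(C), epsilon)
  eps_seq <- epsilon
  if (eps0 > 2 * epsilon) {
    k <- ceiling(log(eps0 / epsilon) / log(4))
    eps_seq <- c(eps0 * (1 / 4)^(seq_len(k) - 1), epsilon)
  }
  total_it <- 0L; res <- Inf
  for (s in seq_along(eps_seq)) {
    eps <- eps_seq[s]
    final <- s == length(eps_seq)
    budget <- if (final) max_iter else 200L
    level_tol <- if (final) tol else max(tol, 1e-4)
    kernel <- function() exp(pmin((rep(g, each = n) - C + f) / eps, 700))
    K <- kernel()
    u <- rep(1, length(a)); v <- rep(1, length(b))
    it <- 0L
    while (it < budget) {
      it <- it + 1L
      Ku <- as.vector(crossprod(K, u))
      v <- ifelse(Ku > 0, b / Ku, absorb_at)
      Kv <- as.vector(K %*% v)
      u <- ifelse(Kv > 0, a / Kv, absorb_at)
      if (max(u, v) > absorb_at || it %% 50L == 0L || it == budget) {
        f <- f + eps * log(pmax(u, tiny))
        g <- g + eps * log(pmax(v, tiny))
        K <- kernel()
        u[] <- 1; v[] <- 1
        pi0 <- K * (a / pmax(rowSums(K), tiny))
        res <- max(abs(colSums(pi0) - b))
        if (res <= level_tol) break
      }
    }
    f <- f + eps * log(pmax(u, tiny))
    g <- g + eps * log(pmax(v, tiny))
    total_it <- total_it + it
  }
  K <- exp(pmin((rep(g, each = n) - C + f) / epsilon, 700))
  pi <- K * (a / pmax(rowSums(K), tiny))
  res <- max(abs(colSums(pi) - b))
  new_transport_plan(pi, C, a, b, total_it, res <= tol, TRUE, res,
                     potentials = list(f = f, g = g))
}

#' Label-regularized entropic optimal transport
#'
#' Adds a group-lasso penalty \deqn{\Omega_c(\pi) = \sum_j \sum_c
#'   \|\pi(I_c, j)\|_1^{1/2}} to the entropic transport objective, where
#' `I_c` indexes the source cells of class `c`. The penalty promotes group
#' sparsity within each coupling column so that every target cell draws its
#' mass from a single source class (known cell types, or clusters induced by
#' [induce_labels()]).
#'
#' Solved by majorization-minimization: at each outer iteration the penalty
#' is linearized around the previous coupling, giving the adjusted cost
#' `C' = C + eta * G` with
#' `G[i, j] = q * (||pi_prev(I_c(i), j)||_1 + delta)^(q - 1)` (`q = 0.5`),
#' which is handed to plain [sinkhorn()]. `eta = 0` skips the loop and
#' returns the plain Sinkhorn solution unchanged.
#'
#' @inheritParams sinkhorn
#' @param labels Class id per source cell (length `nrow(C)`).
#' @param eta Nonnegative weight of the label regularizer.
#' @param q Exponent of the group norm (default 0.5).
#' @param outer_iter Maximum majorization-minimization iterations.
#' @param outer_tol Stop when successive couplings differ by less than this
#'   in max-norm.
#' @param delta Small guard added to group masses before the (negative)
#'   power (default 1e-16).
#' @return A `TransportPlan`; `cost` is the original, unadjusted `C`.
#' @export
sinkhorn_label_reg <- function(C, a = NULL, b = NULL, labels,
                               epsilon = 0.01, eta = 1, q = 0.5,
                               max_iter = 1000L, tol = 1e-9,
                               outer_iter = 10L, outer_tol = 1e-9,
                               delta = 1e-16,
                               log_domain = c("auto", "on", "off")) {
  log_domain <- match.arg(log_domain)
  C <- as.matrix(C)
  if (length(labels) != nrow(C)) {
    stop("need one label per source cell: ", length(labels), " labels for ",
         nrow(C), " cells")
  }
  if (anyNA(labels)) stop("unknown (NA) label id")
  if (eta < 0) stop("eta must be >= 0")
  plan <- sinkhorn(C, a, b, epsilon, max_iter, tol, log_domain)
  if (eta == 0) return(plan)
  groups <- split(seq_len(nrow(C)), labels)
  n_iter <- plan$n_iter
  for (t in seq_len(outer_iter - 1L)) {
    G <- matrix(0, nrow(C), ncol(C))
    for (idx in groups) {
      mass <- colSums(plan$pi[idx, , drop = FALSE])
      G[idx, ] <- rep(q * (mass + delta)^(q - 1), each = length(idx))
    }
    prev <- plan$pi
    plan <- sinkhorn(C + eta * G, plan$a, plan$b, epsilon, max_iter, tol,
                     log_domain, init = plan$potentials)
    n_iter <- n_iter + plan$n_iter
    if (max(abs(plan$pi - prev)) < outer_tol) break
  }
  new_transport_plan(plan$pi, C, plan$a, plan$b, n_iter, plan$converged,
                     plan$log_domain, plan$marginal_residual)
}

#' Induce source-cell labels by hierarchical clustering
#'
#' When no cell-type annotation is available, labels for the transport
#' regularizer are induced by agglomerative clustering (Ward linkage on
#' Euclidean distances) of the shared-modality profiles. Deterministic.
#'
#' @param m A [modality_matrix()].
#' @param n_clusters Number of clusters (default 2, the usual choice when
#'   inducing coarse labels).
#' @return Integer vector of cluster labels, one per cell.
#' @export
induce_labels <- function(m, n_clusters = 2) {
  m <- as_modality(m)
  n <- nrow(m$values)
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  if (n_clusters > n) stop("n_clusters [", n_clusters, "] exceeds cells [", n, "]")
  hc <- stats::hclust(stats::dist(m$values), method = "ward.D2")
  unname(stats::cutree(hc, k = n_clusters))
}

#' Barycentric mapping of source cells into target space
#'
#' Transports each source cell to the coupling-weighted average of target
#' cells: \eqn{Y^{(t)} = diag(\pi 1)^{-1} \pi \hat Y}. Rows of the coupling
#' are normalized so each transported cell is a convex combination of target
#' cells (with unit row mass this reduces to \eqn{\pi \hat Y} exactly).
#'
#' @param plan A `TransportPlan`.
#' @param Yhat Target [modality_matrix()] (the coupling's columns).
#' @return A `ModalityMatrix` of transported source cells (`s_Y` rows,
#'   target features).
#' @export
barycentric_map <- function(plan, Yhat) {
  Yhat <- as_modality(Yhat)
  if (ncol(plan$pi) != nrow(Yhat$values)) {
    stop("coupling has ", ncol(plan$pi), " columns but Yhat has ",
         nrow(Yhat$values), " cells")
  }
  rs <- rowSums(plan$pi)
  if (any(rs == 0)) {
    stop("coupling has all-zero rows; cannot map unmatched source cells: ",
         paste(utils::head(which(rs == 0), 5), collapse = ", "))
  }
  Yt <- (plan$pi / rs) %*% Yhat$values
  modality_matrix(Yt,
                  cell_ids = rownames(plan$pi) %||% paste0("src", seq_len(nrow(Yt))),
                  feature_ids = Yhat$feature_ids, modality = Yhat$modality)
}
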