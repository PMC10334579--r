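#' Cell-to-cell correspondence between two source modalities
#'
#' Records which cells of modality X are the same physical cells as cells of
#' modality Y (jointly profiled cells). `p` is the fraction of cells for
#' which this pairing is known.
#'
#' @param pairs Two-column integer matrix (or data.frame) of
#'   `(x_index, y_index)` pairs, 1-based. No index may repeat on either side.
#' @param p Correspondence fraction in (0, 1].
#' @return An object of class `CorrespondenceMap`.
#' @export
correspondence_map <- function(pairs, p = 1) {
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0) pairs <- matrix(integer(), 0, 2)
  if (ncol(pairs) != 2) stop("pairs must have two columns (x_index, y_index)")
  storage.mode(pairs) <- "integer"
  if (anyDuplicated(pairs[, 1]) || anyDuplicated(pairs[, 2])) {
    stop("a cell index appears in more than one pair")
  }
  if (!(p > 0 && p <= 1)) stop("p must lie in (0, 1]")
  structure(list(pairs = pairs, p = p), class = "CorrespondenceMap")
}

#' Full identity pairing for jointly profiled source cells
#'
#' @param n_cells Number of source cells (same cells in both modalities, in
#'   the same row order).
#' @return A `CorrespondenceMap` with `p = 1` pairing cell i with cell i.
#' @export
full_pairing <- function(n_cells) {
  correspondence_map(cbind(seq_len(n_cells), seq_len(n_cells)), p = 1)
}

#' Binary correspondence matrix W
#'
#' Expands a [correspondence_map()] into the binary `s_X x s_Y` matrix with
#' `W[i, j] = 1` iff cells i (modality X) and j (modality Y) correspond.
#' With a full pairing in matched order this is the identity matrix.
#'
#' @param map A `CorrespondenceMap`.
#' @param s_X,s_Y Numbers of source cells in each modality.
#' @return Binary matrix of dimension `s_X x s_Y`.
#' @export
correspondence_matrix <- function(map, s_X, s_Y) {
  W <- matrix(0, s_X, s_Y)
  if (nrow(map$pairs)) {
    if (any(map$pairs[, 1] < 1 | map$pairs[, 1] > s_X) ||
        any(map$pairs[, 2] < 1 | map$pairs[, 2] > s_Y)) {
      stop("pair index out of range for ", s_X, " x ", s_Y, " cells")
    }
    W[map$pairs] <- 1
  }
  W
}

#' Randomly retain a fraction p of known correspondences
#'
#' Emulates partially corresponding multi-omic data: keeps a uniform random
#' subset of `round(p * n_pairs)` pairs; the remaining cells are treated as
#' non-corresponding. Reproducible under `seed`.
#'
#' @param full A `CorrespondenceMap` (typically [full_pairing()]).
#' @param p Fraction in (0, 1].
#' @param seed Integer seed.
#' @return A `CorrespondenceMap` with fraction `p`.
#' @export
subsample_correspondence <- function(full, p, seed = 1) {
  if (!(p > 0 && p <= 1)) stop("p must lie in (0, 1]")
  n <- nrow(full$pairs)
  keep_n <- round(p * n)
  keep <- with_seed(seed, sort(sample.int(n, keep_n)))
  correspondence_map(full$pairs[keep, , drop = FALSE], p = p)
}

#' Binary K-nearest-neighbour similarity graph
#'
#' Connects each cell to its K nearest neighbours by Euclidean distance
#' (ties broken deterministically towards the lower cell index; duplicated
#' cells at distance zero are picked first) and symmetrizes the adjacency by
#' `max(A, t(A))`.
#'
#' @param m A [modality_matrix()] or numeric matrix.
#' @param K Number of neighbours, `K < n_cells`.
#' @return An object of class `SimilarityGraph`: list with a symmetric 0/1
#'   `weights` matrix (zero diagonal) and `k_neighbors`.
#' @export
build_knn_similarity <- function(m, K) {
  x <- as.matrix(as_modality(m))
  n <- nrow(x)
  if (K >= n) stop("K [", K, "] must be smaller than the number of cells [", n, "]")
  d <- sq_dist(x, x)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf                       # never self
    nn <- order(di)[seq_len(K)]        # stable: ties -> lower index
    A[i, nn] <- 1
  }
  A <- pmax(A, t(A))
  structure(list(weights = A, k_neighbors = K), class = "SimilarityGraph")
}

#' Nonlinear manifold alignment of two source modalities
#'
#' Projects the two source modalities X and Y into a common d-dimensional
#' space that preserves the K-NN geometry within each modality and pulls
#' corresponding cells together. The embedding minimizes
#' \deqn{\mu \sum_{ik} \|\phi_X(x_i)-\phi_X(x_k)\|^2 W_{X,ik}
#'   + \mu \sum_{jm} \|\phi_Y(y_j)-\phi_Y(y_m)\|^2 W_{Y,jm}
#'   + (1-\mu) \sum_{ij} \|\phi_X(x_i)-\phi_Y(y_j)\|^2 W_{ij}}
#' subject to \eqn{P^T D P = I}, where P stacks the X embedding over the Y
#' embedding and D is the degree diagonal of the joint similarity graph.
#' This is solved as the generalized eigenproblem \eqn{L v = \gamma D v} on
#' the joint graph Laplacian; eigenvectors at (numerically) zero eigenvalues
#' — the constant directions, one per connected component — are discarded
#' and the next `d` eigenvectors form the embedding.
#'
#' Each eigenvector's sign is fixed so its largest-magnitude coordinate is
#' positive, which makes the output invariant to the sign ambiguity of
#' eigensolvers and equivariant under swapping the two modality roles.
#'
#' @param X,Y Source [modality_matrix()] objects (`s_X` and `s_Y` cells).
#' @param map A [correspondence_map()] linking X cells to Y cells.
#' @param K Neighbourhood size of the within-modality similarity graphs.
#' @param d Embedding dimension, much smaller than either feature count.
#' @param mu Trade-off in [0, 1] between preserving within-modality geometry
#'   (weight `mu`) and cross-modality correspondence (weight `1 - mu`);
#'   default 0.5 gives both equal importance.
#' @return An object of class `JointEmbedding`: `coords_X` (`s_X x d`),
#'   `coords_Y` (`s_Y x d`), ascending `eigenvalues`, `mu`, `objective`
#'   (sum of retained eigenvalues), and the joint `degree` vector.
#' @export
align_modalities <- function(X, Y, map, K = 5, d = 20, mu = 0.5) {
  X <- as_modality(X); Y <- as_modality(Y)
  stopifnot_finite(X$values, "X"); stopifnot_finite(Y$values, "Y")
  s_X <- nrow(X$values); s_Y <- nrow(Y$values)
  if (nrow(map$pairs) == 0) {
    warning("no correspondence pairs: the joint graph is disconnected across modalities")
  }
  W_X <- build_knn_similarity(X, K)$weights
  W_Y <- build_knn_similarity(Y, K)$weights
  W <- correspondence_matrix(map, s_X, s_Y)
  W_joint <- rbind(cbind(mu * W_X, (1 - mu) * W),
                   cbind((1 - mu) * t(W), mu * W_Y))
  deg <- rowSums(W_joint)
  if (any(deg <= 0)) stop("isolated cells in the joint graph (zero degree)")
  # L v = gamma D v  via the symmetric form  D^{-1/2} L D^{-1/2}
  dis <- 1 / sqrt(deg)
  S <- -W_joint * tcrossprod(dis)
  diag(S) <- diag(S) + 1
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  gamma <- rev(eig$values)
  V <- eig$vectors[, rev(seq_along(gamma)), drop = FALSE]
  tol <- 1e-9 * max(abs(gamma), 1)
  trivial <- gamma <= tol
  n_comp <- sum(trivial)
  if (n_comp > 1) {
    warning(n_comp, " connected components in the joint graph; ",
            "their null directions are dropped")
  }
  usable <- which(!trivial)
  if (length(usable) < d) {
    stop("only ", length(usable), " usable eigenpairs; choose d <= ",
         length(usable))
  }
  keep <- usable[seq_len(d)]
  P <- V[, keep, drop = FALSE] * dis   # D^{-1/2} v, columns satisfy P'DP = I
  # deterministic sign: largest-magnitude coordinate positive
  for (j in seq_len(d)) {
    s <- sign(P[which.max(abs(P[, j])), j])
    if (s < 0) P[, j] <- -P[, j]
  }
  structure(list(
    coords_X = P[seq_len(s_X), , drop = FALSE],
    coords_Y = P[s_X + seq_len(s_Y), , drop = FALSE],
    eigenvalues = gamma[keep],
    mu = mu,
    objective = sum(gamma[keep]),
    degree = deg
  ), class = "JointEmbedding")
}

#' Match each Y cell to its nearest X cell in the joint embedding
#'
#' After alignment the two modalities live in the same space and can be
#' compared with Euclidean distances; for every cell of modality Y this
#' returns the index of its closest modality-X cell (ties towards the lower
#' index). Used to re-key the missing-modality profiles to Y's cell order
#' when correspondence is partial.
#'
#' @param emb A `JointEmbedding` from [align_modalities()].
#' @return Integer vector of length `s_Y`: for each Y cell, the matched X
#'   cell index.
#' @export
match_aligned <- function(emb) {
  stopifnot_finite(emb$coords_X, "embedding")
  d <- sq_dist(emb$coords_Y, emb$coords_X)
  apply(d, 1, which.min)  # which.min returns the first (lowest) index on ties
}
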