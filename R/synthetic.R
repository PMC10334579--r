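#' Specification of a coupled two-modality synthetic dataset
#'
#' Describes the generative model of [generate_multiome()]: cells live on a
#' shared low-dimensional latent manifold with cluster (cell-type)
#' structure; each modality observes a fixed random linear readout of a
#' pointwise nonlinearity of the latent coordinates, plus Gaussian noise
#' and optional dropout. Because both modalities are deterministic images
#' of the same latent cell state, the ground-truth missing modality of
#' every target cell is known.
#'
#' @param n_source,n_target Numbers of source and target cells.
#' @param n_clusters Number of latent clusters (cell types).
#' @param latent_dim Dimension of the shared latent space (must be smaller
#'   than both feature counts).
#' @param d_X,d_Y Feature counts of the two modalities.
#' @param noise_sd Standard deviation of additive Gaussian noise on every
#'   observed entry.
#' @param nonlinearity `"tanh"` (default), `"linear"`, or `"quadratic"`
#'   (elementwise square), applied to latent coordinates before the linear
#'   readout.
#' @param dropout_rate Probability of zeroing an observed entry in X, Y and
#'   Yhat (default 0).
#' @param cluster_sep Scale of the cluster centers in latent space.
#' @param cluster_sd Within-cluster standard deviation in latent space.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A validated `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_source = 200, n_target = 100, n_clusters = 2,
                           latent_dim = 4, d_X = 50, d_Y = 50,
                           noise_sd = 0.1,
                           nonlinearity = c("tanh", "linear", "quadratic"),
                           dropout_rate = 0, cluster_sep = 3,
                           cluster_sd = 0.5, seed = 1) {
  nonlinearity <- match.arg(nonlinearity)
  counts <- c(n_source = n_source, n_target = n_target,
              n_clusters = n_clusters, latent_dim = latent_dim,
              d_X = d_X, d_Y = d_Y)
  if (any(counts < 1)) stop("all counts must be positive")
  if (latent_dim >= min(d_X, d_Y)) {
    stop("latent_dim [", latent_dim, "] must be smaller than min(d_X, d_Y) [",
         min(d_X, d_Y), "]")
  }
  if (!(dropout_rate >= 0 && dropout_rate < 1)) stop("dropout_rate must be in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(n_source = n_source, n_target = n_target,
                 n_clusters = n_clusters, latent_dim = latent_dim,
                 d_X = d_X, d_Y = d_Y, noise_sd = noise_sd,
                 nonlinearity = nonlinearity, dropout_rate = dropout_rate,
                 cluster_sep = cluster_sep, cluster_sd = cluster_sd,
                 seed = seed),
            class = "SyntheticSpec")
}

apply_nonlinearity <- function(z, kind) {
  switch(kind, linear = z, tanh = tanh(z), quadratic = z * z)
}

#' Generate coupled two-modality single-cell data with known ground truth
#'
#' Draws cluster centers and latent cell states, maps them through the two
#' modality readouts and returns source matrices X and Y (same cells, fully
#' paired), a target matrix Yhat, and the held-out ground-truth missing
#' modality Xhat_true of the target cells. Deterministic under the spec's
#' seed (R's Mersenne-Twister stream).
#'
#' @param spec A [synthetic_spec()].
#' @return List with `X`, `Y`, `Yhat`, `Xhat_true` ([modality_matrix()]
#'   objects), integer `labels` (source clusters), `target_labels`,
#'   `full_pairs` (identity [correspondence_map()]), and the latent states
#'   `z_source`, `z_target`.
#' @export
generate_multiome <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  with_seed(spec$seed, {
    centers <- matrix(stats::rnorm(spec$n_clusters * spec$latent_dim),
                      spec$n_clusters) * spec$cluster_sep
    draw_cells <- function(n) {
      # every cluster gets at least one cell, the rest are assigned uniformly
      cl <- c(seq_len(min(spec$n_clusters, n)),
              sample.int(spec$n_clusters, max(0, n - spec$n_clusters),
                         replace = TRUE))
      z <- centers[cl, , drop = FALSE] +
        matrix(stats::rnorm(n * spec$latent_dim, sd = spec$cluster_sd), n)
      list(cl = cl, z = z)
    }
    src <- draw_cells(spec$n_source)
    tgt <- draw_cells(spec$n_target)
    A_X <- matrix(stats::rnorm(spec$latent_dim * spec$d_X), spec$latent_dim) /
      sqrt(spec$latent_dim)
    A_Y <- matrix(stats::rnorm(spec$latent_dim * spec$d_Y), spec$latent_dim) /
      sqrt(spec$latent_dim)
    observe <- function(z, A) {
      f <- apply_nonlinearity(z, spec$nonlinearity)
      f %*% A + matrix(stats::rnorm(nrow(z) * ncol(A), sd = spec$noise_sd),
                       nrow(z))
    }
    X <- observe(src$z, A_X)
    Y <- observe(src$z, A_Y)
    Yhat <- observe(tgt$z, A_Y)
    Xhat_true <- observe(tgt$z, A_X)
    if (spec$dropout_rate > 0) {
      drop_mask <- function(m) {
        m * (matrix(stats::runif(length(m)), nrow(m)) >= spec$dropout_rate)
      }
      X <- drop_mask(X); Y <- drop_mask(Y); Yhat <- drop_mask(Yhat)
    }
    sid <- paste0("s", seq_len(spec$n_source))
    tid <- paste0("t", seq_len(spec$n_target))
    fx <- paste0("gx", seq_len(spec$d_X))
    fy <- paste0("gy", seq_len(spec$d_Y))
    list(
      X = modality_matrix(X, sid, fx, "other"),
      Y = modality_matrix(Y, sid, fy, "other"),
      Yhat = modality_matrix(Yhat, tid, fy, "other"),
      Xhat_true = modality_matrix(Xhat_true, tid, fx, "other"),
      labels = src$cl,
      target_labels = tgt$cl,
      full_pairs = full_pairing(spec$n_source),
      z_source = src$z,
      z_target = tgt$z
    )
  })
}

#' Replace a fraction of target cells with noise
#'
#' Plants outliers for testing the poorly-mapped-cell filter: replaces
#' `ceiling(fraction * n)` randomly chosen target rows with
#' amplitude-scaled Gaussian noise.
#'
#' @param Yhat Target [modality_matrix()].
#' @param fraction Fraction of cells to replace, in (0, 0.5).
#' @param amplitude Standard deviation of the replacement noise.
#' @param seed Integer seed.
#' @return List with the corrupted `Yhat` and the logical `planted_mask`.
#' @export
plant_outliers <- function(Yhat, fraction, amplitude, seed = 1) {
  Yhat <- as_modality(Yhat)
  if (!(fraction > 0 && fraction < 0.5)) stop("fraction must be in (0, 0.5)")
  n <- nrow(Yhat$values)
  n_out <- ceiling(fraction * n)
  with_seed(seed, {
    idx <- sample.int(n, n_out)
    v <- Yhat$values
    v[idx, ] <- matrix(stats::rnorm(n_out * ncol(v), sd = amplitude), n_out)
    mask <- rep(FALSE, n)
    mask[idx] <- TRUE
    list(Yhat = mm_replace(Yhat, v), planted_mask = mask)
  })
}
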