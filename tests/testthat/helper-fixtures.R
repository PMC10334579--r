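# Shared fixtures and independent oracles, all generated in code.

mm <- function(v, modality = "other") modality_matrix(as.matrix(v), modality = modality)

# Cells along a 1-D manifold embedded in `dims` dimensions: a connected,
# elongated dataset whose K-NN graph has many slowly-mixing directions.
line_modality <- function(n = 40, dims = 5, noise = 0.02, seed = 1) {
  withr::with_seed(seed, {
    t <- seq(0, 1, length.out = n)
    basis <- matrix(rnorm(2 * dims), 2)
    v <- cbind(t, t^2) %*% basis + matrix(rnorm(n * dims, sd = noise), n)
    mm(v)
  })
}

# Two Gaussian classes on both the source and target side, geometry chosen
# so a smooth coupling leaks mass across classes.
two_class_toy <- function(seed = 1, off = 1.5, sd = 0.5,
                          n_source = 40, n_target = 30) {
  withr::with_seed(seed, {
    cl_s <- rep(1:2, each = n_source / 2)
    Y <- matrix(rnorm(n_source * 5, sd = sd), n_source) + off * (cl_s == 2)
    cl_t <- rep(1:2, each = n_target / 2)
    Yh <- matrix(rnorm(n_target * 5, sd = sd), n_target) + off * (cl_t == 2)
    list(Y = mm(Y), Yhat = mm(Yh), cl_s = cl_s, cl_t = cl_t)
  })
}

# All permutations of 1..n (Birkhoff extreme points of the square
# doubly-stochastic polytope), for the exact-LP transport oracle.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- all_perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) out <- rbind(out, cbind(i, p + (p >= i)))
  out
}

# Exact optimum of the square uniform-marginal transport LP.
lp_transport_cost <- function(C) {
  n <- nrow(C)
  stopifnot(ncol(C) == n)
  min(apply(all_perms(n), 1, function(pp) mean(C[cbind(seq_len(n), pp)])))
}

# Same-class column mass concentration of a coupling.
class_concentration <- function(pi, cl_s, cl_t) {
  vapply(seq_along(cl_t), function(j) {
    sum(pi[cl_s == cl_t[j], j]) / sum(pi[, j])
  }, numeric(1))
}

marginal_residual <- function(plan) {
  max(max(abs(rowSums(plan$pi) - plan$a)), max(abs(colSums(plan$pi) - plan$b)))
}
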