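test_that("cost matrix is max-normalized squared Euclidean distance", {
  one <- mm(matrix(1, 1, 3))
  expect_equal(cost_matrix(one, one), matrix(0, 1, 1), ignore_attr = TRUE)
  Y <- mm(matrix(c(0, 1), 2, 1))
  expect_equal(unname(cost_matrix(Y, Y)), rbind(c(0, 1), c(1, 0)))
  # global rescaling leaves the normalized cost unchanged
  m <- withr::with_seed(1, mm(matrix(rnorm(12), 4, 3)))
  m3 <- mm_like_scaled <- modality_matrix(3 * m$values, m$cell_ids, m$feature_ids)
  expect_equal(cost_matrix(m3, m3), cost_matrix(m, m))
  expect_error(cost_matrix(mm(matrix(1, 2, 2)), mm(matrix(1, 2, 3))),
               "feature_ids")
})

test_that("sinkhorn returns the independence coupling for flat costs", {
  a <- rep(1 / 3, 3); b <- rep(1 / 4, 4)
  plan <- sinkhorn(matrix(0, 3, 4), epsilon = 0.1)
  expect_equal(plan$pi, outer(a, b), ignore_attr = TRUE)
  # entropy-dominated limit: large epsilon pulls any cost to independence
  C <- withr::with_seed(2, matrix(runif(12), 3, 4))
  plan2 <- sinkhorn(C, epsilon = 1e3, max_iter = 5000, tol = 1e-12)
  expect_equal(plan2$pi, outer(a, b), tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("near-LP sinkhorn matches exact linear-program optima", {
  withr::with_seed(10, {
    for (t in 1:3) {
      C <- matrix(runif(25), 5)
      plan <- sinkhorn(C, epsilon = 1e-3, max_iter = 50000, tol = 1e-9)
      expect_lt(abs(sum(plan$pi * C) - lp_transport_cost(C)) / lp_transport_cost(C),
                0.01)
    }
  })
})

test_that("couplings conserve marginals and respond monotonically to epsilon", {
  C <- withr::with_seed(3, matrix(runif(30), 6, 5))
  eps_grid <- c(0.005, 0.02, 0.1, 0.5)
  ent <- function(pi) { p <- pi[pi > 0]; -sum(p * log(p)) }
  plans <- lapply(eps_grid, function(e) sinkhorn(C, epsilon = e, max_iter = 20000))
  for (p in plans) expect_lt(marginal_residual(p), 1e-6)
  H <- vapply(plans, function(p) ent(p$pi), numeric(1))
  cost <- vapply(plans, function(p) sum(p$pi * C), numeric(1))
  expect_true(all(diff(H) >= -1e-9))      # denser coupling as epsilon grows
  expect_true(all(diff(cost) >= -1e-9))   # transport cost shrinks toward LP
})

test_that("log-domain and standard-domain iterations agree", {
  C <- withr::with_seed(4, matrix(runif(48), 6, 8))
  pa <- sinkhorn(C, epsilon = 0.05, log_domain = "off", tol = 1e-12, max_iter = 20000)
  pb <- sinkhorn(C, epsilon = 0.05, log_domain = "on", tol = 1e-12, max_iter = 20000)
  expect_equal(pa$pi, pb$pi, tolerance = 1e-10)
  expect_true(pb$log_domain)
  expect_false(pa$log_domain)
})

test_that("sinkhorn validates inputs", {
  C <- matrix(1, 2, 2)
  expect_error(sinkhorn(C, a = c(0.5, 0.5), b = c(1, 0.1)), "sum to 1")
  expect_error(sinkhorn(C, a = c(1.5, -0.5), b = c(0.5, 0.5)), "strictly positive")
  expect_error(sinkhorn(C, epsilon = 0), "epsilon")
  expect_error(sinkhorn(matrix(c(1, Inf), 1)), "non-finite")
})

test_that("label regularization reduces to plain sinkhorn when off", {
  tt <- two_class_toy(1)
  C <- cost_matrix(tt$Y, tt$Yhat)
  plain <- sinkhorn(C, epsilon = 0.3)
  off <- sinkhorn_label_reg(C, labels = tt$cl_s, epsilon = 0.3, eta = 0)
  expect_identical(off$pi, plain$pi)
  # one class for every cell: the penalty is constant per column mass
  single <- sinkhorn_label_reg(C, labels = rep(1, 40), epsilon = 0.3, eta = 1)
  expect_equal(single$pi, plain$pi, tolerance = 1e-6)
  expect_error(sinkhorn_label_reg(C, labels = c(tt$cl_s[-1], NA), epsilon = 0.3),
               "label")
  expect_error(sinkhorn_label_reg(C, labels = tt$cl_s[-1], epsilon = 0.3),
               "one label per source cell")
})

test_that("label regularization concentrates column mass within one class", {
  tt <- two_class_toy(1)
  C <- cost_matrix(tt$Y, tt$Yhat)
  conc_plain <- class_concentration(sinkhorn(C, epsilon = 0.3)$pi, tt$cl_s, tt$cl_t)
  reg <- sinkhorn_label_reg(C, labels = tt$cl_s, epsilon = 0.3, eta = 10)
  conc_reg <- class_concentration(reg$pi, tt$cl_s, tt$cl_t)
  expect_lt(min(conc_plain), 0.99)   # the smooth coupling leaks across classes
  expect_gt(min(conc_reg), 0.99)     # the penalty locks each column to a class
  expect_lt(marginal_residual(reg), 1e-6)
})

test_that("induced labels recover planted clusters", {
  tt <- two_class_toy(2, off = 4, sd = 0.3)
  lab <- induce_labels(tt$Y, 2)
  expect_equal(length(unique(lab)), 2)
  # identical partition up to label names
  expect_true(all(rowSums(table(lab, tt$cl_s) > 0) == 1))
  expect_equal(sort(unique(induce_labels(tt$Y, nrow(tt$Y$values)))),
               seq_len(nrow(tt$Y$values)))
  expect_error(induce_labels(tt$Y, 1), ">= 2")
  expect_error(induce_labels(tt$Y, 99), "exceeds")
})

test_that("barycentric mapping is a convex recombination of target cells", {
  Yhat <- withr::with_seed(5, mm(matrix(rnorm(12), 4, 3)))
  id_plan <- structure(list(pi = diag(4) / 4, cost = matrix(0, 4, 4)),
                       class = "TransportPlan")
  expect_equal(barycentric_map(id_plan, Yhat)$values, Yhat$values,
               ignore_attr = TRUE)
  perm <- c(2, 1, 4, 3)
  perm_plan <- structure(list(pi = diag(4)[perm, ] / 4), class = "TransportPlan")
  expect_equal(barycentric_map(perm_plan, Yhat)$values, Yhat$values[perm, ],
               ignore_attr = TRUE)
  # arbitrary couplings stay within the per-feature hull of the targets
  C <- cost_matrix(Yhat, Yhat)
  plan <- sinkhorn(C, epsilon = 0.2)
  Yt <- barycentric_map(plan, Yhat)$values
  for (j in 1:3) {
    expect_gte(min(Yt[, j]), min(Yhat$values[, j]) - 1e-12)
    expect_lte(max(Yt[, j]), max(Yhat$values[, j]) + 1e-12)
  }
  bad <- structure(list(pi = rbind(rep(0, 4), diag(4)[1:3, ])),
                   class = "TransportPlan")
  expect_error(barycentric_map(bad, Yhat), "all-zero rows")
})

test_that("outlier flagging finds planted noise cells and is seed-stable", {
  sim <- generate_multiome(synthetic_spec(n_source = 120, n_target = 80, seed = 4))
  pl <- plant_outliers(sim$Yhat, 0.05, amplitude = 5, seed = 42)
  plan <- sinkhorn(cost_matrix(sim$Y, pl$Yhat), epsilon = 0.02)
  rep1 <- suppressWarnings(flag_outlier_targets(plan, seed = 4))
  rep2 <- suppressWarnings(flag_outlier_targets(plan, seed = 4))
  expect_identical(rep1$flags, rep2$flags)
  expect_gte(sum(rep1$flags & pl$planted_mask) / sum(pl$planted_mask), 0.8)
  expect_equal(rep1$fraction_flagged, mean(rep1$flags))
  expect_warning(flag_outlier_targets(plan, seed = 4), "poorly mapped")
})

test_that("outlier flagging respects a contamination bound on clean data", {
  sim <- generate_multiome(synthetic_spec(n_source = 80, n_target = 60, seed = 6))
  plan <- sinkhorn(cost_matrix(sim$Y, sim$Yhat), epsilon = 0.02)
  rep <- suppressWarnings(flag_outlier_targets(plan, contamination = 0.1, seed = 1))
  expect_lte(rep$fraction_flagged, ceiling(0.1 * 60) / 60)
  # degenerate small target sets are skipped with a warning
  tiny <- structure(list(pi = matrix(1 / 12, 4, 3), cost = matrix(0, 4, 3)),
                    class = "TransportPlan")
  expect_warning(skip_rep <- flag_outlier_targets(tiny), "skipped")
  expect_true(skip_rep$skipped)
  expect_false(any(skip_rep$flags))
})
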