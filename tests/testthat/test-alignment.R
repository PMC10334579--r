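test_that("knn similarity graph handles chains, complete graphs, and ties", {
  # three collinear equally spaced points, K = 1: middle linked to both ends
  pts <- mm(matrix(c(0, 1, 2), 3, 1))
  g <- build_knn_similarity(pts, 1)
  expect_equal(unname(g$weights),
               rbind(c(0, 1, 0), c(1, 0, 0), c(0, 1, 0)) |>
                 (\(A) pmax(A, t(A)))())
  expect_equal(diag(g$weights), rep(0, 3))
  # K = n - 1 gives the complete graph minus the diagonal
  m <- withr::with_seed(1, mm(matrix(rnorm(10), 5, 2)))
  gc <- build_knn_similarity(m, 4)
  expect_equal(unname(gc$weights), 1 - diag(5))
  expect_error(build_knn_similarity(m, 5), "smaller than")
})

test_that("knn edges match an exhaustive distance ranking", {
  m <- withr::with_seed(2, mm(matrix(rnorm(12), 6, 2)))
  g <- build_knn_similarity(m, 2)
  d <- as.matrix(dist(m$values))
  A <- matrix(0, 6, 6)
  for (i in 1:6) {
    nn <- setdiff(order(d[i, ]), i)[1:2]
    A[i, nn] <- 1
  }
  expect_equal(unname(g$weights), pmax(A, t(A)))
})

test_that("correspondence matrices encode pairings", {
  expect_equal(correspondence_matrix(full_pairing(3), 3, 3), diag(3))
  expect_equal(correspondence_matrix(correspondence_map(matrix(integer(), 0, 2)), 2, 2),
               matrix(0, 2, 2))
  W <- correspondence_matrix(correspondence_map(rbind(c(1, 3), c(2, 1))), 2, 3)
  expect_equal(sum(W), 2)
  expect_equal(W[1, 3], 1)
  expect_equal(W[2, 1], 1)
  expect_error(correspondence_matrix(correspondence_map(rbind(c(1, 9))), 2, 3),
               "out of range")
  expect_error(correspondence_map(rbind(c(1, 1), c(1, 2))), "more than one pair")
})

test_that("correspondence subsampling is exact and reproducible", {
  full <- full_pairing(100)
  half <- subsample_correspondence(full, 0.5, seed = 9)
  expect_equal(nrow(half$pairs), 50)
  expect_equal(half$pairs, subsample_correspondence(full, 0.5, seed = 9)$pairs)
  expect_equal(subsample_correspondence(full, 1, seed = 1)$pairs, full$pairs)
  expect_error(subsample_correspondence(full, 0), "0, 1")
  expect_error(subsample_correspondence(full, 1.5), "0, 1")
})

test_that("alignment satisfies the degree-normalization constraint", {
  sim <- generate_multiome(synthetic_spec(n_source = 30, seed = 5))
  for (seed in 1:3) {
    pairs <- subsample_correspondence(full_pairing(30), 0.6, seed)
    emb <- suppressWarnings(align_modalities(sim$X, sim$Y, pairs, K = 4, d = 3))
    P <- rbind(emb$coords_X, emb$coords_Y)
    expect_lt(max(abs(crossprod(P, emb$degree * P) - diag(3))), 1e-6)
    expect_true(all(emb$eigenvalues >= -1e-9))
    expect_false(is.unsorted(emb$eigenvalues))
  }
})

test_that("identical inputs with full pairing co-locate corresponding cells", {
  m <- line_modality(n = 40, seed = 11)
  emb <- align_modalities(m, m, full_pairing(40), K = 2, d = 3, mu = 0.5)
  expect_lt(max(sqrt(rowSums((emb$coords_X - emb$coords_Y)^2))), 1e-6)
  # each Y cell's matched X cell is at (numerically) zero distance
  matched <- match_aligned(emb)
  expect_lt(max(sqrt(rowSums((emb$coords_X[matched, ] - emb$coords_Y)^2))), 1e-6)
})

test_that("alignment eigenvalues match a dense generalized eigensolver", {
  sim <- generate_multiome(synthetic_spec(n_source = 8, n_target = 8, d_X = 10,
                                          d_Y = 10, latent_dim = 3, seed = 7))
  map <- full_pairing(8)
  emb <- align_modalities(sim$X, sim$Y, map, K = 3, d = 2, mu = 0.5)
  W_X <- build_knn_similarity(sim$X, 3)$weights
  W_Y <- build_knn_similarity(sim$Y, 3)$weights
  W <- correspondence_matrix(map, 8, 8)
  WJ <- rbind(cbind(0.5 * W_X, 0.5 * W), cbind(0.5 * t(W), 0.5 * W_Y))
  D <- diag(rowSums(WJ))
  # independent route: non-symmetric solver on D^{-1} L
  ev <- sort(Re(eigen(solve(D) %*% (D - WJ))$values))
  ev <- ev[ev > 1e-9][1:2]
  expect_equal(emb$eigenvalues, ev, tolerance = 1e-10)
  expect_equal(emb$objective, sum(ev), tolerance = 1e-10)
})

test_that("alignment is equivariant under cell permutation and role swap", {
  sim <- generate_multiome(synthetic_spec(n_source = 20, seed = 13))
  map <- full_pairing(20)
  emb <- suppressWarnings(align_modalities(sim$X, sim$Y, map, K = 3, d = 2))
  # consistent permutation of X cells permutes coords_X (max-abs sign rule
  # keeps the sign anchored to the same entry)
  perm <- withr::with_seed(1, sample(20))
  Xp <- subset_cells(sim$X, perm)
  mapp <- correspondence_map(cbind(order(perm), 1:20))
  embp <- suppressWarnings(align_modalities(Xp, sim$Y, mapp, K = 3, d = 2))
  expect_equal(embp$coords_X, emb$coords_X[perm, ], tolerance = 1e-8)
  expect_equal(embp$eigenvalues, emb$eigenvalues, tolerance = 1e-10)
  # swapping modality roles swaps the two coordinate blocks
  embs <- suppressWarnings(align_modalities(sim$Y, sim$X, map, K = 3, d = 2))
  expect_equal(embs$coords_X, emb$coords_Y, tolerance = 1e-8)
  expect_equal(embs$coords_Y, emb$coords_X, tolerance = 1e-8)
})

test_that("alignment rejects infeasible dimensions and warns on no pairs", {
  sim <- generate_multiome(synthetic_spec(n_source = 10, seed = 2))
  expect_error(suppressWarnings(align_modalities(sim$X, sim$Y, full_pairing(10),
                                                 K = 3, d = 19)),
               "usable eigenpairs")
  w <- capture_warnings(align_modalities(sim$X, sim$Y,
                                         correspondence_map(matrix(integer(), 0, 2)),
                                         K = 3, d = 2))
  expect_true(any(grepl("no correspondence pairs", w)))
})

test_that("match_aligned finds nearest cross-modality cells", {
  emb <- structure(list(
    coords_X = matrix(c(0, 0, 5, 5, 10, 10), 3, 2, byrow = TRUE),
    coords_Y = matrix(c(4.9, 5, 0.1, 0), 2, 2, byrow = TRUE)), class = "JointEmbedding")
  expect_equal(match_aligned(emb), c(2L, 1L))
  # single X cell attracts everything
  emb$coords_X <- matrix(c(1, 1), 1, 2)
  expect_equal(match_aligned(emb), c(1L, 1L))
  # random instance against brute force
  withr::with_seed(5, {
    ex <- matrix(rnorm(10), 5, 2); ey <- matrix(rnorm(10), 5, 2)
  })
  emb2 <- structure(list(coords_X = ex, coords_Y = ey), class = "JointEmbedding")
  brute <- apply(as.matrix(dist(rbind(ey, ex)))[1:5, 6:10], 1, which.min)
  expect_equal(match_aligned(emb2), unname(brute))
})
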