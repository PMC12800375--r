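test_that("combined KL cost matches a direct double summation", {
  gen <- make_scalar_data(planted_design(4, 3, 2, 2, seed = 61))
  aff <- build_affinities(gen$data, 2, 1.8)
  set.seed(61)
  Y <- array(stats::rnorm(4 * 3 * 2), c(4, 3, 2))
  for (alpha in c(0, 0.3, 1)) {
    direct <- 0
    for (axis in c("row", "col")) {
      P <- aff[[axis]]$P
      Q <- lowdim_affinity(Y, if (axis == "row") "row" else "column")$Q
      term <- 0
      for (i in seq_len(nrow(P))) for (j in seq_len(nrow(P)))
        if (P[i, j] > 0) term <- term + P[i, j] * log(P[i, j] / Q[i, j])
      direct <- direct + (if (axis == "row") alpha else 1 - alpha) * term
    }
    expect_equal(kl_cost(aff$row, aff$col, Y, alpha), direct,
                 tolerance = 1e-10)
  }
  # I = K = 2: normalisation forces Q = P = 1/2 off-diagonal, so the KL of
  # identical distributions is exactly zero whatever the configuration
  sym <- array(stats::rnorm(8), c(2, 2, 2))
  P2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(kl_cost(P2, P2, sym, 0.7), 0, tolerance = 1e-12)
})

test_that("cost-consistent gradient equals finite differences; printed variant scales by alpha", {
  set.seed(62)
  for (rep in 1:3) {
    gen <- make_scalar_data(planted_design(5, 4, 2, 2, separation = 3,
                                           noise_sd = 1, seed = 62 + rep))
    aff <- build_affinities(gen$data, 2, 1.8)
    Y <- array(stats::rnorm(5 * 4 * 2), c(5, 4, 2)) * 0.8
    alpha <- stats::runif(1, 0.1, 0.9)
    g <- tsne_gradient(aff$row, aff$col, Y, alpha)
    fd <- fd_gradient(aff$row, aff$col, Y, alpha)
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)
    # gradient components sum to the zero vector
    expect_equal(c(sum(g[, , 1]), sum(g[, , 2])), c(0, 0), tolerance = 1e-12)
    # as-printed variant: leading factors 4 a^2 / 4 (1-a)^2 instead of 4a / 4(1-a)
    g1 <- tsne_gradient(aff$row, aff$col, Y, 1, "as_printed")
    gc1 <- tsne_gradient(aff$row, aff$col, Y, 1, "cost_consistent")
    expect_equal(g1, gc1, tolerance = 1e-12)   # coincide at the boundary
    # at alpha = 0.5 the printed factors are 4 * 0.25 = 1 on each term,
    # i.e. one quarter of each boundary gradient
    ga <- tsne_gradient(aff$row, aff$col, Y, 0.5, "as_printed")
    grow <- tsne_gradient(aff$row, aff$col, Y, 1, "cost_consistent")
    gcol <- tsne_gradient(aff$row, aff$col, Y, 0, "cost_consistent")
    expect_equal(ga, 0.25 * grow + 0.25 * gcol, tolerance = 1e-10)
  }
  # boundary: the row term vanishes identically at alpha = 0
  gen <- tiny_scalar(seed = 65)
  aff <- build_affinities(gen$data, 2, 2)
  Y <- array(stats::rnorm(6 * 5 * 2), c(6, 5, 2))
  g0 <- tsne_gradient(aff$row, aff$col, Y, 0)
  swapped <- tsne_gradient(matrix(0, 6, 6), aff$col, Y, 0)
  expect_equal(g0, swapped, tolerance = 1e-14)
})

test_that("the optimiser is deterministic, descends, and keeps boundary structure", {
  gen <- make_scalar_data(planted_design(8, 7, 2, 3, separation = 8,
                                         noise_sd = 1, seed = 66))
  aff <- build_affinities(gen$data)
  cfg <- fast_config(seed = 66)
  f1 <- matrix_tsne(aff, 0.5, cfg)
  f2 <- matrix_tsne(aff, 0.5, cfg)
  expect_identical(f1$embedding$Y, f2$embedding$Y)   # bit-identical rerun
  expect_length(f1$trace, cfg$iterations + 1L)

  # alpha = 1 with the equal-across-columns start: columns stay equal exactly
  fr <- matrix_tsne(aff, 1, cfg)
  for (k in 2:7) {
    expect_identical(fr$embedding$Y[, k, 1], fr$embedding$Y[, 1, 1])
    expect_identical(fr$embedding$Y[, k, 2], fr$embedding$Y[, 1, 2])
  }
  # and symmetrically at alpha = 0
  fc <- matrix_tsne(aff, 0, cfg)
  expect_identical(fc$embedding$Y[2, , 1], fc$embedding$Y[1, , 1])

  # cost decreases from start to finish in >= 9/10 seeds
  descended <- vapply(1:10, function(s) {
    f <- matrix_tsne(aff, 0.5, fast_config(seed = 100 + s))
    f$trace[length(f$trace)] < f$trace[1L]
  }, logical(1))
  expect_gte(sum(descended), 9L)
})

test_that("classical t-SNE respects symmetry and separates planted element clusters", {
  # three mutually equidistant points embed as a near-equilateral triangle
  D <- matrix(1, 3, 3); diag(D) <- 0
  ratios <- vapply(1:5, function(s) {
    fit <- classical_tsne(D, perplexity = 1.7,
                          config = fast_config(seed = s, iterations = 400))
    e <- c(dist(fit$Y))
    max(e) / min(e)
  }, numeric(1))
  expect_true(all(ratios < 1.05))

  # determinism under a fixed seed
  f1 <- classical_tsne(D, 1.7, fast_config(seed = 3))
  f2 <- classical_tsne(D, 1.7, fast_config(seed = 3))
  expect_identical(f1$Y, f2$Y)

  # two well-separated element clusters: K-means(2) on the embedding is
  # exact (full-length runs; at 250 iterations the clusters have not yet
  # contracted enough for an exact partition)
  set.seed(67)
  pts <- c(stats::rnorm(10, 0, 0.1), stats::rnorm(10, 50, 0.1))
  D2 <- outer(pts, pts, "-")^2
  hits <- vapply(1:10, function(s) {
    fit <- classical_tsne(D2, 5, tsne_config(seed = 200 + s), squared = TRUE)
    ari(kmeans_labels(fit$Y, 2, seed = s), rep(1:2, each = 10)) == 1
  }, logical(1))
  expect_gte(sum(hits), 9L)
})

test_that("convex-combination baseline collapses rows at alpha = 1 and differs from the matrix objective", {
  gen <- make_scalar_data(planted_design(5, 4, 2, 2, separation = 5,
                                         noise_sd = 0.8, seed = 68))
  dr <- row_distance_matrix(gen$data)$D2
  dc <- col_distance_matrix(gen$data)$D2
  idx_i <- rep(1:5, each = 4); idx_k <- rep(1:4, times = 5)
  # alpha = 1: element-pair distances depend only on the row indices
  D2_1 <- 1 * dr[idx_i, idx_i] + 0 * dc[idx_k, idx_k]
  same_row <- outer(idx_i, idx_i, "==")
  expect_true(all(D2_1[same_row] == 0))
  # swapping alpha <-> 1 - alpha and transposing gives the same distances
  # up to the flattening permutation
  a <- 0.3
  D2_a <- a * dr[idx_i, idx_i] + (1 - a) * dc[idx_k, idx_k]
  tr <- t(gen$data)
  drT <- row_distance_matrix(tr)$D2; dcT <- col_distance_matrix(tr)$D2
  jdx_i <- rep(1:4, each = 5); jdx_k <- rep(1:5, times = 4)
  D2_swap <- (1 - a) * drT[jdx_i, jdx_i] + a * dcT[jdx_k, jdx_k]
  perm <- order(jdx_k, jdx_i)   # map transposed flatten to original flatten
  expect_equal(D2_swap[perm, perm], D2_a, tolerance = 1e-10)

  # distinct cost functions: each method is better under its own objective
  cfg <- fast_config(seed = 68)
  fit_m <- matrix_tsne(gen$data, 0.5, cfg)
  fit_c <- convex_distance_tsne(gen$data, 0.5, perplexity = 5, config = cfg)
  Yc <- array(0, c(5, 4, 2))
  Yc[, , 1] <- matrix(fit_c$Y[, 1], 5, 4, byrow = TRUE)
  Yc[, , 2] <- matrix(fit_c$Y[, 2], 5, 4, byrow = TRUE)
  aff <- fit_m$affinities
  expect_lt(kl_cost(aff$row, aff$col, fit_m$embedding$Y, 0.5),
            kl_cost(aff$row, aff$col, Yc, 0.5))
})

test_that("divergence and invalid configurations raise informative errors", {
  gen <- tiny_scalar(seed = 69)
  expect_error(matrix_tsne(gen$data, 1.2), "alpha")
  expect_error(tsne_config(iterations = 0), "iterations")
  expect_error(matrix_tsne(gen$data, 0.5,
                           fast_config(seed = 1, iterations = 50L,
                                       eta = 1e300)),
               "diverged")
})

test_that("per-iteration operation count grows as I K (I + K)", {
  base <- count_iteration_ops(10, 10)
  for (K in c(20, 40)) {
    measured <- count_iteration_ops(10, K) / base
    predicted <- (10 * K * (10 + K)) / (10 * 10 * 20)
    expect_lt(abs(measured / predicted - 1), 0.2)
  }
})
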