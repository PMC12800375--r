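test_that("SSB/SST matches hand arithmetic and hits its extremes", {
  pts <- cbind(c(0, 2, 10, 12), 0)
  expect_equal(ssb_sst_ratio(pts, c("A", "A", "B", "B")), 100 / 104)
  set.seed(71)
  rnd <- matrix(stats::rnorm(20), 10, 2)
  expect_equal(ssb_sst_ratio(rnd, rep(1, 10)), 0)            # one cluster
  expect_equal(ssb_sst_ratio(rnd, 1:10), 1)                  # singletons
  r <- ssb_sst_ratio(rnd, sample(1:3, 10, replace = TRUE))
  expect_gte(r, 0); expect_lte(r, 1)
  expect_error(ssb_sst_ratio(matrix(1, 4, 2), rep(1:2, 2)), "SST = 0")
})

test_that("K-means labelling is deterministic and exact on separated blobs", {
  set.seed(72)
  blob_at <- function(cx, cy) cbind(stats::rnorm(10, cx), stats::rnorm(10, cy))
  blobs <- rbind(blob_at(0, 0), blob_at(10, 10), blob_at(0, 20))
  truth <- rep(1:3, each = 10)
  lab <- kmeans_labels(blobs, 3, seed = 7)
  expect_equal(ari(lab, truth), 1)
  expect_identical(lab, kmeans_labels(blobs, 3, seed = 7))
  expect_identical(kmeans_labels(blobs, 1, seed = 1), rep(1L, 30))
  # g = n: every point its own label (objective zero)
  expect_length(unique(kmeans_labels(blobs[1:5, ], 5, seed = 1)), 5L)
  expect_error(kmeans_labels(blobs[1:4, ], 5), "g <= n")
})

test_that("marginal cluster-count selection follows the threshold rule", {
  # points collapsed to two distinct locations: g = 1 scores 0, g = 2 scores 1
  two <- rbind(matrix(0, 3, 2), matrix(5, 4, 2))
  expect_equal(as.integer(select_marginal_G(two, seed = 2)), 2L)

  # five equal blobs at the vertices of a regular pentagon: merging any
  # two adjacent blobs leaves SSB/SST below 0.9, so the smallest-g rule
  # lands exactly on 5
  set.seed(73)
  theta <- 2 * pi * (0:4) / 5
  centers <- 10 * cbind(cos(theta), sin(theta))
  got <- vapply(1:10, function(s) {
    pts <- centers[rep(1:5, each = 8), ] + matrix(stats::rnorm(80, 0, 0.3),
                                                  40, 2)
    as.integer(select_marginal_G(pts, g_max = 10, seed = s))
  }, integer(1))
  expect_equal(as.integer(names(which.max(table(got)))), 5L)

  # definitional oracle on a single blob: first g whose ratio exceeds 0.9
  set.seed(74)
  blob <- matrix(stats::rnorm(60, sd = 1), 30, 2)
  g_sel <- select_marginal_G(blob, g_max = 12, seed = 5)
  ratios <- vapply(1:12, function(g)
    ssb_sst_ratio(blob, kmeans_labels(blob, g, seed = 5)), numeric(1))
  expect_equal(as.integer(g_sel), which(ratios > 0.9)[1L])

  expect_warning(got1 <- select_marginal_G(matrix(1, 5, 2), seed = 1),
                 "identical")
  expect_equal(as.integer(got1), 1L)
})

test_that("cross-product labels enumerate the pairing and feed the metrics", {
  lab <- cross_product_labels(c(1, 2), c(1, 2, 3))
  expect_length(lab, 6L)
  expect_length(unique(lab), 6L)
  expect_length(unique(cross_product_labels(c(1, 1), c(1, 2, 3))), 3L)
  set.seed(75)
  rl <- sample(1:3, 5, TRUE); cl <- sample(1:2, 4, TRUE)
  got <- cross_product_labels(rl, cl)
  # direct pairing oracle in the same row-major order
  pairs <- as.vector(t(outer(rl, cl, paste)))
  expect_equal(as.integer(factor(got)),
               as.integer(factor(pairs, levels = unique(pairs))))

  # metric sanity: permutation invariance and identity
  expect_equal(ari(got, got), 1)
  expect_equal(nmi(got, got), 1)
  relab <- match(got, sample(unique(got)))
  expect_equal(ari(got, relab), 1)
  skip_if_not_installed("mclust")
  set.seed(76)
  a <- sample(1:4, 40, TRUE); b <- sample(1:3, 40, TRUE)
  expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
})

test_that("weight selection maximises the separability curve on planted data", {
  gen <- make_scalar_data(planted_design(10, 9, 2, 3, separation = 8,
                                         noise_sd = 0.8, seed = 77))
  cfg <- fast_config(seed = 77)
  # single-value grid returns that value
  one <- select_alpha(gen$data, alpha_grid = 0.4, config = cfg,
                      known_row_labels = gen$design$row_assignment,
                      known_col_labels = gen$design$col_assignment)
  expect_equal(one$alpha_star, 0.4)

  sel <- select_alpha(gen$data, alpha_grid = seq(0.1, 0.9, by = 0.1),
                      config = cfg,
                      known_row_labels = gen$design$row_assignment,
                      known_col_labels = gen$design$col_assignment)
  expect_equal(sel$G0, 3L); expect_equal(sel$G1, 2L); expect_equal(sel$G, 6L)
  expect_true(sel$alpha_star %in% sel$alphas)
  expect_equal(max(sel$scores), sel$scores[match(sel$alpha_star, sel$alphas)])
  expect_true(all(sel$scores <= max(sel$scores)))
  # deterministic given (data, grid, seed)
  sel2 <- select_alpha(gen$data, alpha_grid = seq(0.1, 0.9, by = 0.1),
                       config = cfg,
                       known_row_labels = gen$design$row_assignment,
                       known_col_labels = gen$design$col_assignment)
  expect_identical(sel$scores, sel2$scores)
  expect_error(select_alpha(gen$data, numeric(0)), "empty")
})

test_that("seed-perturbation evaluation has the right shape and is reproducible", {
  gen <- make_scalar_data(planted_design(8, 6, 2, 2, separation = 8,
                                         noise_sd = 0.8, seed = 78))
  res <- seed_perturbation_eval(gen$data, 0.5, gen$design$row_assignment,
                                gen$design$col_assignment, n_seeds = 3,
                                config = fast_config(seed = 1),
                                metrics = c("ari", "ssb_sst"))
  expect_equal(nrow(res), 3L * 2L * 2L)   # seeds x methods x metrics
  expect_setequal(unique(res$method), c("matrix_tsne", "classical_tsne"))
  res2 <- seed_perturbation_eval(gen$data, 0.5, gen$design$row_assignment,
                                 gen$design$col_assignment, n_seeds = 3,
                                 config = fast_config(seed = 1),
                                 metrics = c("ari", "ssb_sst"))
  expect_identical(res$value, res2$value)
  expect_s3_class(attr(res, "summary"), "data.frame")
})
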