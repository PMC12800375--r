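#' Cluster separability: between-cluster over total sum of squares
#'
#' `SSB = sum_g n_g ||mean_g - mean||^2`, `SST = sum_x ||x - mean||^2`;
#' the ratio lies in `[0, 1]`, equals 0 when all cluster means coincide
#' with the grand mean, and 1 when within-cluster scatter is zero.
#'
#' @param points `n x d` numeric matrix (a vector is treated as 1-D).
#' @param labels cluster assignment of length `n`.
#' @return `SSB / SST`.  All points identical (`SST = 0`) is an error.
#' @export
ssb_sst_ratio <- function(points, labels) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 2L, nrow(points) == length(labels))
  centre <- colMeans(points)
  dev <- sweep(points, 2L, centre)
  sst <- sum(dev * dev)
  if (sst == 0) stop("all points identical: SST = 0")
  ssb <- 0
  for (g in split(seq_along(labels), labels)) {
    mg <- colMeans(points[g, , drop = FALSE])
    ssb <- ssb + length(g) * sum((mg - centre)^2)
  }
  ssb / sst
}

#' Deterministic best-of-restarts K-means labels
#'
#' Squared-Euclidean K-means with `restarts` random starts, seeded so the
#' result is reproducible.  When the number of distinct points does not
#' exceed `g`, every distinct location gets its own label (objective 0).
#'
#' @param points `n x d` numeric matrix.
#' @param g number of clusters, `1 <= g <= n`.
#' @param restarts number of random starts.
#' @param seed integer seed.
#' @return Integer labels of length `n`.
#' @export
kmeans_labels <- function(points, g, restarts = 20L, seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(g >= 1L, g <= n)
  if (g == 1L) return(rep(1L, n))
  distinct <- unique(points)
  if (nrow(distinct) <= g) {
    key <- apply(points, 1L, paste, collapse = "\r")
    return(as.integer(factor(key, levels = unique(key))))
  }
  set.seed(seed)
  stats::kmeans(points, centers = g, nstart = restarts, iter.max = 100L)$cluster
}

#' Select a marginal cluster count by the separability threshold
#'
#' Returns the smallest `g` whose K-means partition exceeds the
#' `SSB/SST > threshold` rule, scanning `g = 1, 2, ..., g_max`.  This is
#' applied to the distinct margin points of a boundary embedding
#' (one point per row at `alpha = 1`, one per column at `alpha = 0`).
#'
#' @param points `n x 2` margin coordinates.
#' @param g_max largest cluster count scanned; default `min(n - 1, 15)`.
#' @param threshold separability cut-off (default 0.9).
#' @param restarts,seed passed to [kmeans_labels()].
#' @return Integer `G` with attributes `ratios` (per-`g` separability) and
#'   `reached` (`FALSE` with a warning when no `g` qualifies, in which case
#'   `g_max` is returned; degenerate all-identical points return 1).
#' @export
select_marginal_G <- function(points, g_max = NULL, threshold = 0.9,
                              restarts = 20L, seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (is.null(g_max)) g_max <- min(n - 1L, 15L)
  g_max <- min(g_max, n)
  if (nrow(unique(points)) == 1L) {
    warning("all margin points identical; returning G = 1")
    return(structure(1L, ratios = NA_real_, reached = FALSE))
  }
  ratios <- numeric(g_max)
  for (g in seq_len(g_max)) {
    lab <- kmeans_labels(points, g, restarts, seed)
    ratios[g] <- ssb_sst_ratio(points, lab)
    if (ratios[g] > threshold)
      return(structure(as.integer(g), ratios = ratios[seq_len(g)],
                       reached = TRUE))
  }
  warning("no g <= ", g_max, " exceeds SSB/SST threshold ", threshold,
          "; returning g_max")
  structure(as.integer(g_max), ratios = ratios, reached = FALSE)
}

#' Cross-product labels of matrix elements
#'
#' Element `(i, k)` is labelled by the pair (row group of `i`, column group
#' of `k`), encoded as one integer.  Output follows the row-major element
#' order used throughout the package.
#'
#' @param row_labels length-`I` group labels.
#' @param col_labels length-`K` group labels.
#' @return Integer vector of length `I * K` with at most
#'   `length(unique(row_labels)) * length(unique(col_labels))` distinct
#'   values.
#' @export
cross_product_labels <- function(row_labels, col_labels) {
  I <- length(row_labels); K <- length(col_labels)
  pair <- paste(rep(row_labels, each = K), rep(col_labels, times = I),
                sep = "\r")
  as.integer(factor(pair, levels = unique(pair)))
}

#' Adjusted Rand index and normalised mutual information
#'
#' Partition agreement measures: `ari()` is the permutation-model adjusted
#' Rand index; `nmi()` is mutual information normalised by the arithmetic
#' mean of the two partition entropies.  Both are invariant to label
#' permutation and equal 1 for identical partitions.
#'
#' @param a,b two label vectors of equal length.
#' @return A number; ARI can be slightly negative for adversarial
#'   partitions, NMI lies in `[0, 1]`.
#' @export
ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  igraph::compare(as.integer(factor(a)), as.integer(factor(b)),
                  method = "adjusted.rand")
}

#' @rdname ari
#' @export
nmi <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  one_a <- length(unique(a)) == 1L; one_b <- length(unique(b)) == 1L
  if (one_a && one_b) return(1)   # both degenerate: identical partitions
  if (one_a || one_b) return(0)   # zero entropy on one side only
  igraph::compare(a, b, method = "nmi")
}

## distinct margin points of a boundary run: at alpha = 1 all columns of the
## embedding coincide, so take column 1 (and symmetrically for alpha = 0)
margin_points <- function(fit, axis = c("row", "column")) {
  axis <- match.arg(axis)
  Y <- fit$embedding$Y
  if (axis == "row") cbind(Y[, 1L, 1L], Y[, 1L, 2L])
  else cbind(Y[1L, , 1L], Y[1L, , 2L])
}

#' Select the row/column weight by embedded cluster separability
#'
#' Implements the full selection flow: (1) boundary runs at `alpha = 1`
#' (row margin) and `alpha = 0` (column margin); (2) marginal cluster
#' counts `G1` (rows) and `G0` (columns) from the `SSB/SST > 0.9` rule —
#' or taken from supplied known group labels, skipping the marginal
#' K-means; row and column labels then come from K-means on the margin
#' points (or the known labels); (3) for each candidate weight the full
#' embedding is scored on its `I * K` points: metric `"ssb_sst"` scores the
#' cross-product labels directly, `"ari"`/`"nmi"` compare a fresh K-means
#' at `G = G0 * G1` against the cross-product labels; (4) the selected
#' weight maximises the score (ties take the smallest weight).
#'
#' @param data a `matrix_framed` dataset.
#' @param alpha_grid candidate weights in `(0, 1)`; default
#'   `seq(0.02, 0.98, by = 0.02)`.
#' @param config a [tsne_config()]; its seed controls every run.
#' @param metric `"ssb_sst"` (default), `"ari"`, or `"nmi"`.
#' @param perp_r,perp_c margin perplexities (`NULL`: `min(n/3, 30)` rule).
#' @param known_row_labels,known_col_labels optional known group
#'   memberships; when given, `G1`/`G0` and the margin labels are taken
#'   from them directly.
#' @param scoring `"cross_product"` (score the cross-product partition,
#'   the default) or `"fresh_kmeans"` (score a K-means partition at `G`)
#'   for the `ssb_sst` metric.
#' @param step DTW step pattern (series data only).
#' @param g_max,threshold passed to [select_marginal_G()].
#' @return A list of class `alpha_selection`: `G0`, `G1`, `G`, `alphas`,
#'   `scores`, `alpha_star`, `metric`, `row_labels`, `col_labels`,
#'   `embeddings` (the boundary fits), `best_fit` (the run at
#'   `alpha_star`), `seed`.
#' @export
select_alpha <- function(data, alpha_grid = seq(0.02, 0.98, by = 0.02),
                         config = tsne_config(),
                         metric = c("ssb_sst", "ari", "nmi"),
                         perp_r = NULL, perp_c = NULL,
                         known_row_labels = NULL, known_col_labels = NULL,
                         scoring = c("cross_product", "fresh_kmeans"),
                         step = "symmetric2", g_max = NULL, threshold = 0.9) {
  metric <- match.arg(metric)
  scoring <- match.arg(scoring)
  if (length(alpha_grid) == 0L) stop("empty alpha grid")
  stopifnot(all(alpha_grid > 0 & alpha_grid < 1))
  aff <- build_affinities(data, perp_r, perp_c, step)
  I <- length(data$row_ids); K <- length(data$col_ids)

  fit_row <- matrix_tsne(aff, alpha = 1, config = config)
  fit_col <- matrix_tsne(aff, alpha = 0, config = config)
  pts_row <- margin_points(fit_row, "row")
  pts_col <- margin_points(fit_col, "column")

  if (is.null(known_row_labels)) {
    G1 <- as.integer(select_marginal_G(pts_row, g_max, threshold,
                                       seed = config$seed))
    row_labels <- kmeans_labels(pts_row, G1, seed = config$seed)
  } else {
    stopifnot(length(known_row_labels) == I)
    row_labels <- as.integer(factor(known_row_labels))
    G1 <- length(unique(row_labels))
  }
  if (is.null(known_col_labels)) {
    G0 <- as.integer(select_marginal_G(pts_col, g_max, threshold,
                                       seed = config$seed))
    col_labels <- kmeans_labels(pts_col, G0, seed = config$seed)
  } else {
    stopifnot(length(known_col_labels) == K)
    col_labels <- as.integer(factor(known_col_labels))
    G0 <- length(unique(col_labels))
  }
  G <- G0 * G1
  truth <- cross_product_labels(row_labels, col_labels)

  scores <- numeric(length(alpha_grid))
  fits <- vector("list", length(alpha_grid))
  for (s in seq_along(alpha_grid)) {
    fit <- matrix_tsne(aff, alpha = alpha_grid[s], config = config)
    pts <- flatten_coords(fit$embedding$Y)
    scores[s] <- score_embedding(pts, truth, G, metric, scoring, config$seed)
    fits[[s]] <- fit
  }
  best <- which(scores == max(scores))[1L]   # ties: smallest alpha
  structure(list(G0 = G0, G1 = G1, G = G, alphas = alpha_grid,
                 scores = scores, alpha_star = alpha_grid[best],
                 metric = metric, row_labels = row_labels,
                 col_labels = col_labels,
                 boundary_fits = list(row = fit_row, col = fit_col),
                 best_fit = fits[[best]], seed = config$seed),
            class = "alpha_selection")
}

score_embedding <- function(pts, truth, G, metric, scoring, seed) {
  if (metric == "ssb_sst") {
    labels <- if (scoring == "fresh_kmeans")
      kmeans_labels(pts, min(G, nrow(pts)), seed = seed) else truth
    ssb_sst_ratio(pts, labels)
  } else {
    found <- kmeans_labels(pts, min(G, nrow(pts)), seed = seed)
    if (metric == "ari") ari(found, truth) else nmi(found, truth)
  }
}

#' @export
print.alpha_selection <- function(x, ...) {
  cat(sprintf("weight selection (%s): G1 = %d row groups, G0 = %d column groups, G = %d\n",
              x$metric, x$G1, x$G0, x$G))
  cat(sprintf("alpha* = %.2f (score %.4f over %d candidates)\n",
              x$alpha_star, max(x$scores), length(x$alphas)))
  invisible(x)
}

#' Stability of the embedding under random restarts
#'
#' Re-runs the embedding under `n_seeds` different initialisation seeds and
#' scores each run against the cross-product labels: ARI and NMI compare a
#' K-means partition at `G` with the cross-product partition; SSB/SST
#' scores the cross-product partition directly.  Optionally the classical
#' unstructured-distance baseline is evaluated on the same seeds.
#'
#' @param data a `matrix_framed` dataset.
#' @param alpha weight for the structure-preserving runs.
#' @param row_labels,col_labels margin group labels defining the
#'   cross-product truth.
#' @param n_seeds number of random restarts (seeds `base_seed + 1:n_seeds`).
#' @param config a [tsne_config()] (its seed is the base seed).
#' @param metrics subset of `c("ari", "nmi", "ssb_sst")`.
#' @param include_baseline also run classical t-SNE on the unstructured
#'   element distances.
#' @param baseline_perplexity perplexity of the baseline (default 30,
#'   clamped to `n - 1`).
#' @param perp_r,perp_c,step as in [matrix_tsne()].
#' @return A data frame with columns `seed`, `method`, `metric`, `value`
#'   (one row per seed, method and metric), with a `summary` attribute
#'   holding per-method/metric medians and IQRs.
#' @export
seed_perturbation_eval <- function(data, alpha, row_labels, col_labels,
                                   n_seeds = 10L, config = tsne_config(),
                                   metrics = c("ari", "nmi", "ssb_sst"),
                                   include_baseline = TRUE,
                                   baseline_perplexity = NULL,
                                   perp_r = NULL, perp_c = NULL,
                                   step = "symmetric2") {
  stopifnot(n_seeds >= 2L)
  metrics <- match.arg(metrics, several.ok = TRUE)
  truth <- cross_product_labels(as.integer(factor(row_labels)),
                                as.integer(factor(col_labels)))
  G <- length(unique(truth))
  aff <- build_affinities(data, perp_r, perp_c, step)
  ed <- if (include_baseline) element_distance_matrix(data, step)
  seeds <- config$seed + seq_len(n_seeds)
  out <- list()
  for (s in seeds) {
    cfg <- config; cfg$seed <- as.integer(s)
    fit <- matrix_tsne(aff, alpha = alpha, config = cfg)
    out[[length(out) + 1L]] <-
      eval_points(flatten_coords(fit$embedding$Y), truth, G, metrics, s,
                  "matrix_tsne")
    if (include_baseline) {
      base <- classical_tsne(ed, baseline_perplexity, cfg)
      out[[length(out) + 1L]] <-
        eval_points(base$Y, truth, G, metrics, s, "classical_tsne")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  summ <- stats::aggregate(value ~ method + metric, res, function(v)
    c(median = stats::median(v), iqr = stats::IQR(v)))
  attr(res, "summary") <- summ
  res
}

eval_points <- function(pts, truth, G, metrics, seed, method) {
  vals <- vapply(metrics, function(m) {
    if (m == "ssb_sst") ssb_sst_ratio(pts, truth)
    else {
      found <- kmeans_labels(pts, min(G, nrow(pts)), seed = seed)
      if (m == "ari") ari(found, truth) else nmi(found, truth)
    }
  }, numeric(1))
  data.frame(seed = seed, method = method, metric = metrics, value = vals,
             stringsAsFactors = FALSE)
}
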