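# Independent oracles used across the suite.  These deliberately use naive
# algorithms (exhaustive enumeration, quadrature, double loops) so they share
# no code with the implementation paths they check.

# DTW by exhaustive enumeration of every monotone warping path (steps down,
# right, diagonal); tractable for sequence lengths <= 6 or so.
dtw_brute <- function(a, b, diag_weight = 2) {
  n <- length(a); m <- length(b)
  best <- Inf
  recurse <- function(i, j, acc) {
    if (acc >= best) return(invisible())
    if (i == n && j == m) { best <<- acc; return(invisible()) }
    if (i < n) recurse(i + 1L, j, acc + abs(a[i + 1L] - b[j]))
    if (j < m) recurse(i, j + 1L, acc + abs(a[i] - b[j + 1L]))
    if (i < n && j < m)
      recurse(i + 1L, j + 1L, acc + diag_weight * abs(a[i + 1L] - b[j + 1L]))
  }
  recurse(1L, 1L, abs(a[1L] - b[1L]))
  best
}

# histogram quantile at a vector of mass values, by bin search (piecewise
# uniform density => piecewise linear quantile)
hist_quantile <- function(h, t) {
  cum <- c(0, cumsum(h$masses))
  b <- findInterval(t, cum, rightmost.closed = TRUE, all.inside = TRUE)
  lo <- cum[b]; hi <- cum[b + 1L]
  frac <- ifelse(hi > lo, (t - lo) / (hi - lo), 0)
  h$breaks[b] + frac * (h$breaks[b + 1L] - h$breaks[b])
}

# L2-Wasserstein by midpoint quadrature of the quantile difference
wasserstein_quadrature <- function(h1, h2, n_grid = 2e5) {
  tt <- (seq_len(n_grid) - 0.5) / n_grid
  sqrt(mean((hist_quantile(h1, tt) - hist_quantile(h2, tt))^2))
}

# margin squared distances by a plain double loop over elements
row_d2_brute <- function(data) {
  I <- length(data$row_ids); K <- length(data$col_ids)
  D2 <- matrix(0, I, I)
  for (i in seq_len(I)) for (j in seq_len(I)) {
    s <- 0
    for (k in seq_len(K)) {
      x <- get_element(data, i, k); y <- get_element(data, j, k)
      s <- s + switch(data$kind,
                      scalar = (x - y)^2,
                      series = series_sq_distance(x, y),
                      histogram = wasserstein(x, y)^2)
    }
    D2[i, j] <- s
  }
  D2
}

# central finite differences of the combined KL cost
fd_gradient <- function(Pr, Pc, Y, alpha, eps = 1e-6) {
  g <- array(0, dim(Y))
  for (i in seq_len(dim(Y)[1])) for (k in seq_len(dim(Y)[2])) for (d in 1:2) {
    Yp <- Y; Yp[i, k, d] <- Yp[i, k, d] + eps
    Ym <- Y; Ym[i, k, d] <- Ym[i, k, d] - eps
    g[i, k, d] <- (kl_cost(Pr, Pc, Yp, alpha) -
                   kl_cost(Pr, Pc, Ym, alpha)) / (2 * eps)
  }
  g
}

# random histogram on a random grid; masses kept away from zero so the
# quantile slopes stay bounded (keeps the quadrature oracle accurate)
random_histogram <- function(bins = sample(2:6, 1)) {
  breaks <- sort(stats::runif(bins + 1, -2, 4))
  while (any(diff(breaks) < 1e-3)) breaks <- sort(stats::runif(bins + 1, -2, 4))
  masses <- stats::rgamma(bins, shape = 1) + 0.05
  list(breaks = breaks, masses = masses / sum(masses))
}

# small planted scalar dataset used by several files
tiny_scalar <- function(seed = 5L, I = 6L, K = 5L, R = 2L, C = 2L,
                        separation = 4, noise_sd = 0.5) {
  make_scalar_data(planted_design(I, K, R, C, separation, noise_sd, seed))
}

fast_config <- function(seed = 1L, iterations = 250L, ...) {
  tsne_config(seed = seed, iterations = iterations,
              exaggeration_iters = min(100L, iterations %/% 2L), ...)
}
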