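#' Planted row-group by column-group design
#'
#' Describes the ground truth of a synthetic matrix-framed dataset:
#' `I` rows split round-robin into `R` groups and `K` columns into `C`
#' groups, a `separation` controlling how far apart group mean profiles
#' sit, a `noise_sd` for the additive Gaussian noise, and a `row_scale`
#' multiplying the row-margin effect relative to the column-margin effect
#' (values far from 1 reproduce the scale-mismatch regime in which a
#' single-perplexity unstructured embedding loses one margin).
#'
#' @param I,K grid dimensions.
#' @param R,C row- and column-group counts, `R <= I`, `C <= K`.
#' @param separation minimum distance between adjacent group mean levels.
#' @param noise_sd standard deviation of the element noise.
#' @param seed integer seed; every generator is deterministic given it.
#' @param row_scale relative scale of row-margin separation.
#' @return A `planted_design` list with the fields above plus
#'   `row_assignment` and `col_assignment`.
#' @export
planted_design <- function(I, K, R, C, separation = 10, noise_sd = 1,
                           seed = 1L, row_scale = 1) {
  stopifnot(R >= 1L, C >= 1L, R <= I, C <= K, separation > 0, noise_sd >= 0,
            row_scale > 0)
  structure(list(I = as.integer(I), K = as.integer(K), R = as.integer(R),
                 C = as.integer(C),
                 row_assignment = rep_len(seq_len(R), I),
                 col_assignment = rep_len(seq_len(C), K),
                 separation = separation, noise_sd = noise_sd,
                 seed = as.integer(seed), row_scale = row_scale),
            class = "planted_design")
}

#' Synthetic scalar matrix with planted biclusters
#'
#' `X[i, k] = mu[r(i), c(k)] + noise`, with additive group means
#' `mu[r, c] = row_scale * separation * (r - 1) + separation * (c - 1)`:
#' the row effect is constant across every column and vice versa, so the
#' two margins are orthogonally recoverable, and the minimum distance
#' between distinct row (column) mean profiles is at least
#' `separation * sqrt(K)` (`sqrt(I)`).
#'
#' @param design a [planted_design()].
#' @return List with `data` (a scalar `matrix_framed`) and `design`.
#' @export
make_scalar_data <- function(design) {
  stopifnot(inherits(design, "planted_design"))
  set.seed(design$seed)
  mu <- outer(design$row_scale * design$separation *
                (design$row_assignment - 1),
              design$separation * (design$col_assignment - 1), "+")
  X <- mu + matrix(stats::rnorm(design$I * design$K, sd = design$noise_sd),
                   design$I, design$K)
  list(data = scalar_data(X), design = design)
}

#' Synthetic time-series matrix with planted biclusters
#'
#' Element `(i, k)` is a `T x P` sinusoid: the frequency is set by the row
#' group, the phase by the column group, amplitude equal to
#' `design$separation`, plus Gaussian noise (`design$noise_sd`) and a
#' random per-element integer time shift of up to `shift_max` frames —
#' a misalignment that dynamic time warping absorbs but a rigid
#' per-time-point comparison would not.
#'
#' @param design a [planted_design()].
#' @param T_len number of time points (at least 4).
#' @param P number of coordinates per time point.
#' @param shift_max largest per-element start-frame shift.
#' @return List with `data` (a series `matrix_framed`) and `design`.
#' @export
make_series_data <- function(design, T_len = 30L, P = 3L, shift_max = 2L) {
  stopifnot(inherits(design, "planted_design"), T_len >= 4L, P >= 1L)
  set.seed(design$seed)
  I <- design$I; K <- design$K
  amp <- design$separation * design$row_scale
  elements <- matrix(vector("list", I * K), I, K)
  for (i in seq_len(I)) for (k in seq_len(K)) {
    r <- design$row_assignment[i]; cgrp <- design$col_assignment[k]
    shift <- if (shift_max > 0) sample.int(shift_max + 1L, 1L) - 1L else 0L
    tt <- (seq_len(T_len) - 1L) + shift
    e <- matrix(0, T_len, P)
    for (p in seq_len(P)) {
      e[, p] <- amp * sin(2 * pi * r * tt / T_len +
                          2 * pi * (cgrp - 1) / design$C +
                          pi * (p - 1) / (2 * P)) +
        stats::rnorm(T_len, sd = design$noise_sd)
    }
    elements[[i, k]] <- e
  }
  list(data = series_data(elements), design = design)
}

#' Synthetic histogram matrix with planted biclusters
#'
#' Element `(i, k)` is the `B`-bin histogram (on one shared bin grid) of
#' `n_samples` Gaussian draws with mean
#' `row_scale * separation * (r(i) - 1) + separation * (c(k) - 1)` and
#' standard deviation `design$noise_sd` — the row groups emulate location
#' groups and the column groups period-wise mean shifts.
#'
#' @param design a [planted_design()]; `noise_sd` must be positive here.
#' @param B number of bins (at least 2).
#' @param n_samples draws per histogram.
#' @return List with `data` (a histogram `matrix_framed`) and `design`.
#' @export
make_histogram_data <- function(design, B = 20L, n_samples = 500L) {
  stopifnot(inherits(design, "planted_design"), B >= 2L, n_samples >= 1L,
            design$noise_sd > 0)
  set.seed(design$seed)
  I <- design$I; K <- design$K
  mu_row <- design$row_scale * design$separation * (design$row_assignment - 1)
  mu_col <- design$separation * (design$col_assignment - 1)
  lo <- min(mu_row) + min(mu_col) - 4 * design$noise_sd
  hi <- max(mu_row) + max(mu_col) + 4 * design$noise_sd
  breaks <- seq(lo, hi, length.out = B + 1L)
  elements <- matrix(vector("list", I * K), I, K)
  for (i in seq_len(I)) for (k in seq_len(K)) {
    x <- stats::rnorm(n_samples, mean = mu_row[i] + mu_col[k],
                      sd = design$noise_sd)
    x <- pmin(pmax(x, lo), hi)   # clamp tail draws onto the shared grid
    counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                    all.inside = TRUE), nbins = B)
    elements[[i, k]] <- list(breaks = breaks, masses = counts / n_samples)
  }
  list(data = histogram_data(elements), design = design)
}
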