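#' Embedding of a matrix-framed dataset
#'
#' An `I x K` grid of 2-D coordinates: element `(i, k)` is embedded at
#' `Y[i, k, ]`.
#'
#' @param Y numeric array of dimension `c(I, K, 2)`, all finite.
#' @param row_ids,col_ids labels.
#' @return A `matrix_embedding` object.
#' @export
matrix_embedding <- function(Y, row_ids = NULL, col_ids = NULL) {
  stopifnot(is.array(Y), length(dim(Y)) == 3L, dim(Y)[3L] == 2L)
  if (is.null(row_ids)) row_ids <- paste0("r", seq_len(dim(Y)[1L]))
  if (is.null(col_ids)) col_ids <- paste0("c", seq_len(dim(Y)[2L]))
  structure(list(Y = Y, row_ids = as.character(row_ids),
                 col_ids = as.character(col_ids)),
            class = "matrix_embedding")
}

#' @export
dim.matrix_embedding <- function(x) dim(x$Y)[1:2]

#' Flatten an embedding to a data frame
#'
#' Row-major element order (all columns of row 1, then row 2, ...), matching
#' the flattening of [element_distance_matrix()] and
#' [cross_product_labels()].
#'
#' @param x a `matrix_embedding`.
#' @param ... unused.
#' @export
as.data.frame.matrix_embedding <- function(x, ...) {
  I <- dim(x$Y)[1L]; K <- dim(x$Y)[2L]
  data.frame(row_id = rep(x$row_ids, each = K),
             col_id = rep(x$col_ids, times = I),
             y1 = as.vector(t(x$Y[, , 1L])),
             y2 = as.vector(t(x$Y[, , 2L])),
             stringsAsFactors = FALSE)
}

## flattened n x 2 coordinate matrix, row-major element order
flatten_coords <- function(Y) {
  cbind(as.vector(t(Y[, , 1L])), as.vector(t(Y[, , 2L])))
}

#' Optimiser configuration for the structure-preserving embedding
#'
#' Defaults follow the classical t-SNE reference optimiser the method
#' adopts: 1000 iterations, momentum 0.5 before iteration 250 and 0.8
#' after, learning rate 100, Gaussian initialisation with scale `1e-4` at
#' interior weights, early exaggeration (input affinities multiplied by 4
#' for the first 100 iterations), and adaptive per-parameter gains.
#' Exaggeration and gains can be switched off
#' (`exaggeration = 1, gains = FALSE`) to run the bare momentum descent.
#'
#' @param iterations number of gradient steps `M`.
#' @param eta learning rate.
#' @param momentum_early,momentum_late,momentum_switch momentum schedule:
#'   `momentum_early` while the iteration count is below `momentum_switch`,
#'   `momentum_late` afterwards.
#' @param seed integer seed controlling the initialisation.
#' @param init_sd standard deviation of the Gaussian initialisation (the
#'   literal standard Gaussian is `init_sd = 1`).
#' @param exaggeration,exaggeration_iters early-exaggeration factor applied
#'   to the input affinities for the first `exaggeration_iters` iterations
#'   (factor 1 disables it).
#' @param gradient_variant `"cost_consistent"` (leading factors `4*alpha`,
#'   `4*(1 - alpha)`, the analytic gradient of the combined cost) or
#'   `"as_printed"` (`4*alpha^2`, `4*(1 - alpha)^2`).
#' @param center mean-centre the embedding after every iteration (the cost
#'   is translation invariant; centering removes drift).
#' @param gains use the classical adaptive per-parameter gain heuristic.
#' @param record_trajectory keep the coordinates of every iteration in the
#'   run trace.
#' @param verbose log the cost every 50 iterations.
#' @return A list of class `tsne_config`.
#' @export
tsne_config <- function(iterations = 1000L, eta = 100,
                        momentum_early = 0.5, momentum_late = 0.8,
                        momentum_switch = 250L, seed = 1L, init_sd = 1e-4,
                        exaggeration = 4, exaggeration_iters = 100L,
                        gradient_variant = c("cost_consistent", "as_printed"),
                        center = TRUE, gains = TRUE,
                        record_trajectory = FALSE, verbose = FALSE) {
  stopifnot(iterations >= 1L, eta > 0, init_sd > 0)
  structure(list(iterations = as.integer(iterations), eta = eta,
                 momentum_early = momentum_early,
                 momentum_late = momentum_late,
                 momentum_switch = as.integer(momentum_switch),
                 seed = as.integer(seed), init_sd = init_sd,
                 exaggeration = exaggeration,
                 exaggeration_iters = as.integer(exaggeration_iters),
                 gradient_variant = match.arg(gradient_variant),
                 center = center, gains = gains,
                 record_trajectory = record_trajectory, verbose = verbose),
            class = "tsne_config")
}

## low-dimensional Student-t weights and joint probabilities for one margin.
## Y1, Y2: I x K coordinate matrices; margin = "row" aggregates over columns.
lowdim_parts <- function(Y1, Y2, margin) {
  if (margin == "column") { Y1 <- t(Y1); Y2 <- t(Y2) }
  S <- sqdist_rows(Y1) + sqdist_rows(Y2)
  W <- 1 / (1 + S)
  diag(W) <- 0
  list(W = W, Q = W / sum(W))
}

kl_term <- function(P, Q) {
  pos <- P > 0
  sum(P[pos] * log(P[pos] / Q[pos]))
}

#' Combined Kullback-Leibler cost of an embedding
#'
#' `C = alpha * KL(P_row || Q_row) + (1 - alpha) * KL(P_col || Q_col)`,
#' where the low-dimensional joint probabilities aggregate coordinates over
#' the opposite margin (see [lowdim_affinity()]).  Diagonal terms are
#' excluded and `0 * log(0 / q) = 0`.
#'
#' @param Pr,Pc row- and column-margin `affinity` objects (or plain
#'   matrices summing to 1).
#' @param Y a `matrix_embedding` or `I x K x 2` array.
#' @param alpha weight in `[0, 1]` on the row term.
#' @return Nonnegative cost.
#' @export
kl_cost <- function(Pr, Pc, Y, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (inherits(Y, "matrix_embedding")) Y <- Y$Y
  Pr <- if (inherits(Pr, "affinity")) Pr$P else Pr
  Pc <- if (inherits(Pc, "affinity")) Pc$P else Pc
  Y1 <- Y[, , 1L]; Y2 <- Y[, , 2L]
  r <- lowdim_parts(Y1, Y2, "row")
  cc <- lowdim_parts(Y1, Y2, "column")
  alpha * kl_term(Pr, r$Q) + (1 - alpha) * kl_term(Pc, cc$Q)
}

#' Gradient of the combined cost
#'
#' For the `"cost_consistent"` variant (the analytic gradient of the
#' combined cost), the gradient at cell `(i, k)` is
#' `4 alpha sum_j (pr_ij - qr_ij) wr_ij (Y_ik - Y_jk) +
#'  4 (1 - alpha) sum_l (pc_kl - qc_kl) wc_kl (Y_ik - Y_il)`,
#' with `w = (1 + aggregated squared distance)^-1`.  The `"as_printed"`
#' variant replaces the leading factors by `4 alpha^2` and
#' `4 (1 - alpha)^2`, preserving the same attraction-repulsion structure.
#'
#' @inheritParams kl_cost
#' @param variant `"cost_consistent"` or `"as_printed"`.
#' @return `I x K x 2` array of gradient components; the components sum to
#'   the zero vector (pairwise interactions are antisymmetric).
#' @export
tsne_gradient <- function(Pr, Pc, Y, alpha,
                          variant = c("cost_consistent", "as_printed")) {
  variant <- match.arg(variant)
  if (inherits(Y, "matrix_embedding")) Y <- Y$Y
  Pr <- if (inherits(Pr, "affinity")) Pr$P else Pr
  Pc <- if (inherits(Pc, "affinity")) Pc$P else Pc
  Y1 <- Y[, , 1L]; Y2 <- Y[, , 2L]
  r <- lowdim_parts(Y1, Y2, "row")
  cc <- lowdim_parts(Y1, Y2, "column")
  g <- gradient_core(Pr, Pc, Y1, Y2, r, cc, alpha, variant)
  out <- array(0, dim(Y))
  out[, , 1L] <- g$G1
  out[, , 2L] <- g$G2
  out
}

## shared by tsne_gradient and the optimiser loop; r/cc from lowdim_parts
gradient_core <- function(Pr, Pc, Y1, Y2, r, cc, alpha, variant) {
  fr <- if (variant == "as_printed") 4 * alpha^2 else 4 * alpha
  fc <- if (variant == "as_printed") 4 * (1 - alpha)^2 else 4 * (1 - alpha)
  Mr <- (Pr - r$Q) * r$W            # I x I
  Mc <- (Pc - cc$Q) * cc$W          # K x K
  mr <- rowSums(Mr)
  mc <- rowSums(Mc)
  G1 <- fr * (mr * Y1 - Mr %*% Y1) +
        fc * (Y1 * rep(mc, each = nrow(Y1)) - Y1 %*% Mc)
  G2 <- fr * (mr * Y2 - Mr %*% Y2) +
        fc * (Y2 * rep(mc, each = nrow(Y2)) - Y2 %*% Mc)
  list(G1 = G1, G2 = G2)
}

#' Structure-preserving t-SNE of matrix-framed data
#'
#' Minimises the convex combination of row- and column-margin KL costs by
#' momentum gradient descent.  Initialisation depends on the weight:
#' at `alpha = 1` the initial coordinates are drawn per row and repeated
#' across columns (at this boundary the method is exactly t-SNE of the row
#' margin, and every column stays identical throughout); at `alpha = 0`
#' they are drawn per column and repeated across rows; at interior weights
#' all `I * K` coordinates are i.i.d. Gaussian with scale
#' `config$init_sd`.  The run is deterministic given `config$seed`.
#'
#' @param x a `matrix_framed` dataset, or a list with `affinity` components
#'   `row` and `col` (as from [build_affinities()]).
#' @param alpha weight in `[0, 1]` on the row-margin cost.
#' @param config a [tsne_config()].
#' @param perp_r,perp_c margin perplexities used when `x` is a dataset;
#'   `NULL` applies the `min(n/3, 30)` rule.
#' @param step DTW step pattern (series data only).
#' @param Y0 optional `I x K x 2` initialisation overriding the seeded draw.
#' @return A list of class `matrix_tsne` with `embedding`
#'   (a [matrix_embedding()]), `trace` (cost at iterations `0..M`), `alpha`,
#'   `config`, and `trajectory` when recorded.
#' @export
matrix_tsne <- function(x, alpha = 0.5, config = tsne_config(),
                        perp_r = NULL, perp_c = NULL, step = "symmetric2",
                        Y0 = NULL) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (inherits(x, "matrix_framed")) {
    aff <- build_affinities(x, perp_r, perp_c, step)
    row_ids <- x$row_ids; col_ids <- x$col_ids
  } else {
    aff <- x
    row_ids <- NULL; col_ids <- NULL
  }
  Pr <- aff$row$P; Pc <- aff$col$P
  I <- nrow(Pr); K <- nrow(Pc)

  if (is.null(Y0)) {
    set.seed(config$seed)
    if (alpha == 1) {
      Z <- matrix(stats::rnorm(I * 2L), I, 2L) * config$init_sd
      Y1 <- matrix(Z[, 1L], I, K); Y2 <- matrix(Z[, 2L], I, K)
    } else if (alpha == 0) {
      Z <- matrix(stats::rnorm(K * 2L), K, 2L) * config$init_sd
      Y1 <- matrix(Z[, 1L], I, K, byrow = TRUE)
      Y2 <- matrix(Z[, 2L], I, K, byrow = TRUE)
    } else {
      Y1 <- matrix(stats::rnorm(I * K), I, K) * config$init_sd
      Y2 <- matrix(stats::rnorm(I * K), I, K) * config$init_sd
    }
  } else {
    stopifnot(identical(dim(Y0), c(I, K, 2L)))
    Y1 <- Y0[, , 1L]; Y2 <- Y0[, , 2L]
  }

  exa <- config$exaggeration
  PrX <- if (exa != 1 && config$exaggeration_iters > 0L) Pr * exa else Pr
  PcX <- if (exa != 1 && config$exaggeration_iters > 0L) Pc * exa else Pc

  U1 <- matrix(0, I, K); U2 <- matrix(0, I, K)     # momentum increments
  Ga1 <- matrix(1, I, K); Ga2 <- matrix(1, I, K)   # optional gains
  trace <- numeric(config$iterations + 1L)
  trajectory <- if (config$record_trajectory) vector("list", config$iterations)
  r <- lowdim_parts(Y1, Y2, "row"); cc <- lowdim_parts(Y1, Y2, "column")
  trace[1L] <- alpha * kl_term(Pr, r$Q) + (1 - alpha) * kl_term(Pc, cc$Q)

  for (m in seq_len(config$iterations)) {
    useP_r <- if (m <= config$exaggeration_iters) PrX else Pr
    useP_c <- if (m <= config$exaggeration_iters) PcX else Pc
    g <- gradient_core(useP_r, useP_c, Y1, Y2, r, cc, alpha,
                       config$gradient_variant)
    gamma <- if (m < config$momentum_switch) config$momentum_early
             else config$momentum_late
    if (config$gains) {
      Ga1 <- update_gains(Ga1, g$G1, U1)
      Ga2 <- update_gains(Ga2, g$G2, U2)
    }
    U1 <- gamma * U1 - config$eta * Ga1 * g$G1
    U2 <- gamma * U2 - config$eta * Ga2 * g$G2
    Y1 <- Y1 + U1
    Y2 <- Y2 + U2
    if (config$center) {
      Y1 <- Y1 - mean(Y1)
      Y2 <- Y2 - mean(Y2)
    }
    if (!all(is.finite(Y1)) || !all(is.finite(Y2)))
      stop("embedding diverged (non-finite coordinates) at iteration ", m)
    r <- lowdim_parts(Y1, Y2, "row"); cc <- lowdim_parts(Y1, Y2, "column")
    trace[m + 1L] <- alpha * kl_term(Pr, r$Q) + (1 - alpha) * kl_term(Pc, cc$Q)
    if (config$record_trajectory) {
      Ym <- array(0, c(I, K, 2L)); Ym[, , 1L] <- Y1; Ym[, , 2L] <- Y2
      trajectory[[m]] <- Ym
    }
    if (config$verbose && m %% 50L == 0L)
      message(sprintf("iteration %d: cost %.6f", m, trace[m + 1L]))
  }

  Y <- array(0, c(I, K, 2L)); Y[, , 1L] <- Y1; Y[, , 2L] <- Y2
  structure(list(embedding = matrix_embedding(Y, row_ids, col_ids),
                 trace = trace, alpha = alpha, config = config,
                 affinities = aff, trajectory = trajectory),
            class = "matrix_tsne")
}

update_gains <- function(gain, grad, incr) {
  same <- sign(grad) == sign(incr)
  gain <- ifelse(same, gain * 0.8, gain + 0.2)
  pmax(gain, 0.01)
}

#' Classical t-SNE on a precomputed distance matrix
#'
#' Standard t-SNE: Gaussian conditional affinities with per-point
#' perplexity calibration on the squared distances, symmetrisation over the
#' `n` points, Student-t low-dimensional kernel, and the same momentum
#' optimiser as [matrix_tsne()].  This is the engine behind the
#' unstructured-distance baseline, and — through `multiplicity` — the exact
#' margin-wise reduction of the structure-preserving method: at
#' `alpha = 1` the row-margin problem aggregates `K` identical coordinate
#' copies into each pairwise distance, which is reproduced here by using
#' the kernel `(1 + multiplicity * d^2)^-1` while keeping the per-element
#' gradient step.
#'
#' @param D an `element_dist`/`margin_dist` object or an `n x n` distance
#'   matrix (unsquared unless `squared = TRUE`).
#' @param perplexity target perplexity, at most `n - 1`; defaults to 30
#'   clamped to `n - 1`.
#' @param config a [tsne_config()].
#' @param squared set when `D` already holds squared distances
#'   (`margin_dist` objects are always squared).
#' @param multiplicity aggregation count in the low-dimensional kernel
#'   (1 for plain t-SNE).
#' @param Y0 optional `n x 2` initial coordinates.
#' @return A list of class `classical_tsne` with `Y` (`n x 2`), `trace`,
#'   `config`, and `trajectory` when recorded.
#' @export
classical_tsne <- function(D, perplexity = NULL, config = tsne_config(),
                           squared = FALSE, multiplicity = 1, Y0 = NULL) {
  if (inherits(D, "element_dist")) { D2 <- D$D^2 }
  else if (inherits(D, "margin_dist")) { D2 <- D$D2 }
  else { D2 <- if (squared) D else D^2 }
  n <- nrow(D2)
  if (is.null(perplexity)) perplexity <- min(30, n - 1)
  aff <- margin_affinity(D2, perplexity)
  P <- aff$P
  PX <- if (config$exaggeration != 1 && config$exaggeration_iters > 0L)
    P * config$exaggeration else P

  if (is.null(Y0)) {
    set.seed(config$seed)
    Y <- matrix(stats::rnorm(n * 2L), n, 2L) * config$init_sd
  } else Y <- Y0
  U <- matrix(0, n, 2L)
  Ga <- matrix(1, n, 2L)
  trace <- numeric(config$iterations + 1L)
  trajectory <- if (config$record_trajectory) vector("list", config$iterations)

  ## The aggregated kernel (1 + multiplicity * d^2)^-1 is realised by
  ## replicating each coordinate `multiplicity` times, the literal form of
  ## the collapsed-margin aggregation; for multiplicity 1 this is plain
  ## t-SNE.
  rep_cols <- function(v) matrix(v, length(v), multiplicity)
  lowdim <- function(Y) {
    S <- if (multiplicity > 1L)
      sqdist_rows(rep_cols(Y[, 1L])) + sqdist_rows(rep_cols(Y[, 2L]))
    else sqdist_rows(Y)
    W <- 1 / (1 + S); diag(W) <- 0
    list(W = W, Q = W / sum(W))
  }
  ld <- lowdim(Y)
  trace[1L] <- kl_term(P, ld$Q)
  for (m in seq_len(config$iterations)) {
    useP <- if (m <= config$exaggeration_iters) PX else P
    M <- (useP - ld$Q) * ld$W
    G <- if (multiplicity > 1L)
      4 * cbind(rowSums(M) * Y[, 1L] - (M %*% rep_cols(Y[, 1L]))[, 1L],
                rowSums(M) * Y[, 2L] - (M %*% rep_cols(Y[, 2L]))[, 1L])
    else 4 * (rowSums(M) * Y - M %*% Y)
    gamma <- if (m < config$momentum_switch) config$momentum_early
             else config$momentum_late
    if (config$gains) Ga <- update_gains(Ga, G, U)
    U <- gamma * U - config$eta * Ga * G
    Y <- Y + U
    if (config$center) {
      ctr <- if (multiplicity > 1L)
        c(mean(rep_cols(Y[, 1L])), mean(rep_cols(Y[, 2L])))
      else colMeans(Y)
      Y <- sweep(Y, 2L, ctr)
    }
    if (!all(is.finite(Y)))
      stop("embedding diverged (non-finite coordinates) at iteration ", m)
    ld <- lowdim(Y)
    trace[m + 1L] <- kl_term(P, ld$Q)
    if (config$record_trajectory) trajectory[[m]] <- Y
    if (config$verbose && m %% 50L == 0L)
      message(sprintf("iteration %d: cost %.6f", m, trace[m + 1L]))
  }
  structure(list(Y = Y, trace = trace, config = config,
                 perplexity = perplexity, trajectory = trajectory),
            class = "classical_tsne")
}

#' Classical t-SNE on a convex combination of margin distances
#'
#' Optional baseline: the element-pair squared distance is
#' `alpha * d_row(i, j)^2 + (1 - alpha) * d_col(k, l)^2` and a single
#' classical t-SNE embeds the `I * K` elements.  Unlike [matrix_tsne()]
#' this uses one perplexity and one cost, so it is sensitive to scale
#' differences between the margins.
#'
#' @inheritParams matrix_tsne
#' @param perplexity single perplexity for the flattened problem.
#' @return A `classical_tsne` result; rows follow the row-major element
#'   order.
#' @export
convex_distance_tsne <- function(x, alpha = 0.5, perplexity = NULL,
                                 config = tsne_config(), step = "symmetric2") {
  stopifnot(inherits(x, "matrix_framed"), alpha >= 0, alpha <= 1)
  I <- length(x$row_ids); K <- length(x$col_ids)
  dr <- row_distance_matrix(x, step)$D2
  dc <- col_distance_matrix(x, step)$D2
  idx_i <- rep(seq_len(I), each = K)
  idx_k <- rep(seq_len(K), times = I)
  D2 <- alpha * dr[idx_i, idx_i] + (1 - alpha) * dc[idx_k, idx_k]
  classical_tsne(D2, perplexity, config, squared = TRUE)
}

#' Arithmetic operation count of one optimiser iteration
#'
#' Sums, step by step, the scalar multiply/add/divide counts of the dense
#' linear-algebra operations one [matrix_tsne()] iteration performs
#' (margin squared-distance matrices, Student-t weights and normalisation,
#' and the two-margin gradient).  The dominant terms are proportional to
#' `I^2 K` (row margin) and `K^2 I` (column margin), i.e. the per-iteration
#' work grows as `I K (I + K)`.
#'
#' @param I,K grid dimensions.
#' @return Total scalar operation count (a pure function of `I` and `K`).
#' @export
count_iteration_ops <- function(I, K) {
  margin <- function(n, k) {
    ## sqdist_rows on two n x k coordinate matrices:
    ##   rowSums(A*A) twice + combine: 2*(n*k + n*(k-1)) + n
    ##   outer(sq, sq, "+"): n^2
    ##   tcrossprod twice: 2*(n^2*k + n^2*(k-1)), combine S: 2*n^2
    ##   W = 1/(1+S): 2*n^2;  Q = W/sum(W): 2*n^2;  M = (P-Q)*W: 2*n^2
    2 * (n * k + n * (k - 1)) + n +
      n^2 + 2 * (n^2 * k + n^2 * (k - 1)) + 2 * n^2 +
      6 * n^2
  }
  gradient <- function(n, k) {
    ## per coordinate: rowSums(M): n^2; scale by margin sums: n*k;
    ## M %*% Y: n^2*k + n*(n-1)*k; combine and weight: 3*n*k
    2 * (n^2 + n * k + n^2 * k + n * (n - 1) * k + 3 * n * k)
  }
  update <- 2 * 6 * I * K   # momentum update, step, centering per coordinate
  margin(I, K) + margin(K, I) + gradient(I, K) + gradient(K, I) + update
}
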