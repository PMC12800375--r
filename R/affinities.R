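#' Gaussian conditional neighbour probabilities for one point
#'
#' For point `i` with bandwidth `sigma`, the probability that `j` is picked
#' as a neighbour is proportional to `exp(-D2[i, j] / (2 sigma^2))` over
#' `j != i`, normalised to sum to 1 (`p[i] = 0`).  The row minimum of the
#' scaled distances is subtracted before exponentiation — exact in exact
#' arithmetic — so the computation never underflows to an all-zero row.
#'
#' @param d2row numeric vector: squared distances from point `i` to all `n`
#'   points, with `d2row[i] = 0`.
#' @param i index of the conditioning point.
#' @param sigma positive bandwidth.
#' @return Probability vector of length `n` summing to 1 with `p[i] = 0`.
#' @export
conditional_row <- function(d2row, i, sigma) {
  stopifnot(sigma > 0, i >= 1L, i <= length(d2row))
  z <- d2row[-i] / (2 * sigma^2)
  if (all(!is.finite(z))) stop("all off-diagonal distances are infinite")
  w <- exp(-(z - min(z)))
  p <- numeric(length(d2row))
  p[-i] <- w / sum(w)
  p
}

shannon_perplexity <- function(p) {
  p <- p[p > 0]
  2^(-sum(p * log2(p)))
}

#' Calibrate a Gaussian bandwidth to a target perplexity
#'
#' Finds `sigma` such that the conditional distribution of
#' [conditional_row()] has perplexity `2^H` within `tol` of the target.
#' The entropy is monotone nondecreasing in `sigma`, so the root is found
#' by bisection on `log(sigma)` over the bracket `[1e-10, 1e10]`.  If the
#' target is unreachable (e.g. equidistant neighbours pin the perplexity at
#' `n - 1`), the boundary `sigma` is returned with attribute
#' `converged = FALSE`.
#'
#' @inheritParams conditional_row
#' @param perplexity target in `(1, n - 1]`.
#' @param tol absolute tolerance on the achieved perplexity.
#' @param max_iter bisection iteration cap.
#' @return Positive `sigma`, with attributes `perplexity` (achieved) and
#'   `converged`.
#' @export
calibrate_bandwidth <- function(d2row, i, perplexity, tol = 1e-5,
                                max_iter = 200L) {
  n <- length(d2row)
  if (perplexity > n - 1)
    stop("infeasible perplexity ", perplexity, " > n - 1 = ", n - 1)
  if (perplexity <= 1) stop("perplexity must exceed 1")
  perp_at <- function(s) shannon_perplexity(conditional_row(d2row, i, s))
  lo <- log(1e-10); hi <- log(1e10)
  p_lo <- perp_at(exp(lo)); p_hi <- perp_at(exp(hi))
  if (p_lo >= perplexity + tol)
    return(structure(exp(lo), perplexity = p_lo, converged = FALSE))
  if (p_hi <= perplexity - tol)
    return(structure(exp(hi), perplexity = p_hi, converged = FALSE))
  sigma <- exp((lo + hi) / 2); achieved <- perp_at(sigma)
  iter <- 0L
  while (abs(achieved - perplexity) > tol && iter < max_iter) {
    if (achieved < perplexity) lo <- log(sigma) else hi <- log(sigma)
    sigma <- exp((lo + hi) / 2)
    achieved <- perp_at(sigma)
    iter <- iter + 1L
  }
  structure(sigma, perplexity = achieved,
            converged = abs(achieved - perplexity) <= tol)
}

#' Symmetrised joint affinities from a conditional matrix
#'
#' `P[i, j] = (Pcond[j | i] + Pcond[i | j]) / (2 n)`; since every row of the
#' conditional matrix sums to 1, the joint matrix sums to exactly 1.
#'
#' @param Pcond `n x n` matrix whose row `i` is the conditional distribution
#'   given point `i` (zero diagonal).
#' @return Symmetric matrix with zero diagonal, total mass 1.
#' @export
symmetrize_affinity <- function(Pcond) {
  n <- nrow(Pcond)
  (Pcond + t(Pcond)) / (2 * n)
}

#' High-dimensional affinity matrix for one margin
#'
#' Runs per-point bandwidth calibration and symmetrisation on a margin
#' squared-distance matrix.  `normalization = "conditional"` (default) is
#' the classical per-row conditional; `"pairs"` normalises each row's
#' Gaussian kernel by the sum over all ordered point pairs (each evaluated
#' with that row's bandwidth), in which case rows no longer sum to 1 and the
#' symmetrised mass is renormalised to 1.  Bandwidths are calibrated under
#' the conditional reading in both cases.
#'
#' @param D2 a `margin_dist` object or plain symmetric matrix of squared
#'   distances.
#' @param perplexity target perplexity in `(1, n - 1]`.
#' @param tol,max_iter calibration controls, see [calibrate_bandwidth()].
#' @param normalization `"conditional"` or `"pairs"`.
#' @return An `affinity` object: list with `P` (symmetric, zero diagonal,
#'   sums to 1), `sigmas`, `perplexity`, `axis`, `uncalibrated` (indices
#'   where the target was unreachable).
#' @export
margin_affinity <- function(D2, perplexity, tol = 1e-5, max_iter = 200L,
                            normalization = c("conditional", "pairs")) {
  normalization <- match.arg(normalization)
  axis <- if (inherits(D2, "margin_dist")) D2$axis else "row"
  M <- if (inherits(D2, "margin_dist")) D2$D2 else D2
  n <- nrow(M)
  sigmas <- numeric(n)
  flags <- logical(n)
  Pcond <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- calibrate_bandwidth(M[i, ], i, perplexity, tol, max_iter)
    sigmas[i] <- s
    flags[i] <- !attr(s, "converged")
    Pcond[i, ] <- conditional_row(M[i, ], i, as.numeric(s))
  }
  if (normalization == "pairs") {
    ## literal all-pairs denominator: kernel with sigma_i over row i,
    ## denominator = sum over all ordered pairs of the same kernel
    Kmat <- exp(-M / (2 * sigmas^2))
    diag(Kmat) <- 0
    Pcond <- Kmat / sum(Kmat)
    P <- (Pcond + t(Pcond))
    P <- P / sum(P)
  } else {
    P <- symmetrize_affinity(Pcond)
  }
  structure(list(P = P, sigmas = sigmas, perplexity = perplexity,
                 axis = axis, uncalibrated = which(flags)),
            class = "affinity")
}

#' Row- and column-margin affinities for a matrix-framed dataset
#'
#' Convenience composition: margin squared distances, per-point bandwidth
#' calibration, symmetrisation — once over rows with `perp_r` and once over
#' columns with `perp_c`.  Defaults follow the rule
#' `min(n / 3, 30)` for each margin of size `n`.
#'
#' @param data a `matrix_framed` object.
#' @param perp_r,perp_c margin perplexities; `NULL` applies the default rule.
#' @param step DTW step pattern (series data only).
#' @param ... passed to [margin_affinity()].
#' @return List with components `row` and `col`, each an `affinity` object.
#' @export
build_affinities <- function(data, perp_r = NULL, perp_c = NULL,
                             step = "symmetric2", ...) {
  I <- length(data$row_ids); K <- length(data$col_ids)
  if (is.null(perp_r)) perp_r <- default_perplexity(I)
  if (is.null(perp_c)) perp_c <- default_perplexity(K)
  list(row = margin_affinity(row_distance_matrix(data, step), perp_r, ...),
       col = margin_affinity(col_distance_matrix(data, step), perp_c, ...))
}

#' Default perplexity rule
#'
#' The smaller of one third of the number of points and 30, floored below
#' at just above 1 for very small margins.
#'
#' @param n number of points on the margin.
#' @export
default_perplexity <- function(n) {
  max(min(n / 3, 30), min(1.5, n - 1))
}

#' Low-dimensional Student-t joint affinities over a margin
#'
#' For the row axis the squared separation of rows `i` and `j` aggregates
#' all columns: `S[i, j] = sum_k ||Y_ik - Y_jk||^2`, and
#' `q_ij = (1 + S[i, j])^-1 / sum_{i' != j'} (1 + S[i', j'])^-1`.
#' The column axis exchanges the roles of `i` and `k`.
#'
#' @param Y a `matrix_embedding` or an `I x K x 2` array.
#' @param axis `"row"` or `"column"`.
#' @return List with `Q` (symmetric, zero diagonal, sums to 1) and `axis`.
#' @export
lowdim_affinity <- function(Y, axis = c("row", "column")) {
  axis <- match.arg(axis)
  if (inherits(Y, "matrix_embedding")) Y <- Y$Y
  if (!all(is.finite(Y))) stop("non-finite embedding coordinates")
  Y1 <- Y[, , 1L]; Y2 <- Y[, , 2L]
  if (axis == "column") { Y1 <- t(Y1); Y2 <- t(Y2) }
  S <- sqdist_rows(Y1) + sqdist_rows(Y2)
  W <- 1 / (1 + S)
  diag(W) <- 0
  list(Q = W / sum(W), axis = axis)
}

## n x n matrix of squared Euclidean distances between the rows of A
sqdist_rows <- function(A) {
  A <- as.matrix(A)
  sq <- rowSums(A * A)
  S <- outer(sq, sq, "+") - 2 * tcrossprod(A)
  S[S < 0] <- 0
  S
}
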