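#' Dynamic time warping distance between two 1-D sequences
#'
#' Unnormalised cumulative alignment cost over the full warping lattice
#' (no window constraint), with absolute-difference local cost.  The
#' `"symmetric2"` step pattern weights the diagonal transition by 2 (the
#' common default in DTW software); `"symmetric1"` weights all three
#' transitions by 1.  For any input pair the `symmetric1` cost is no larger
#' than the `symmetric2` cost.
#'
#' @param a,b nonempty numeric vectors.
#' @param step step pattern, `"symmetric2"` (default) or `"symmetric1"`.
#' @return Nonnegative warping cost; 0 iff an alignment with zero local
#'   cost everywhere exists (in particular whenever `a` equals `b`).
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 2, 2, 3))  # 0: the repeat is absorbed
#' @export
dtw_distance <- function(a, b, step = c("symmetric2", "symmetric1")) {
  step <- match.arg(step)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("empty sequence in dtw_distance")
  dtw_cost_cpp(a, b, if (step == "symmetric2") 2 else 1)
}

#' Squared distance between two series elements
#'
#' Each of the `P` coordinates is warped independently and the per-coordinate
#' DTW costs are squared and summed:
#' `sum_p DTW(x[, p], y[, p])^2`.
#'
#' @param x,y `T x P` numeric matrices with the same `P` (`T` may differ).
#' @param step DTW step pattern, see [dtw_distance()].
#' @return Nonnegative squared distance.
#' @export
series_sq_distance <- function(x, y, step = "symmetric2") {
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != ncol(y))
    stop("series dimension mismatch: P = ", ncol(x), " vs ", ncol(y))
  sum(vapply(seq_len(ncol(x)),
             function(p) dtw_distance(x[, p], y[, p], step)^2, numeric(1)))
}

#' L2-Wasserstein distance between two histograms
#'
#' Treats each histogram as a piecewise-uniform density, so its quantile
#' function is piecewise linear in the cumulative mass.  The distance is
#' `sqrt(integral over t in [0,1] of (Q1(t) - Q2(t))^2 dt)`, evaluated in
#' closed form on the merged grid of cumulative-mass knots of the two
#' quantile functions.
#'
#' @param h1,h2 histograms as `list(breaks, masses)`; masses must sum to 1.
#' @return Nonnegative distance, in the units of the bin edges.
#' @export
wasserstein <- function(h1, h2) {
  h1 <- validate_histogram(h1); h2 <- validate_histogram(h2)
  q1 <- quantile_pieces(h1); q2 <- quantile_pieces(h2)
  knots <- sort(unique(c(0, q1$cum, q2$cum, 1)))
  knots <- knots[knots >= 0 & knots <= 1]
  total <- 0
  for (s in seq_len(length(knots) - 1L)) {
    t0 <- knots[s]; t1 <- knots[s + 1L]
    if (t1 <= t0) next
    p1 <- piece_at(q1, t0); p2 <- piece_at(q2, t0)
    da <- p1$a - p2$a; db <- p1$b - p2$b
    total <- total + da * da * (t1 - t0) +
      da * db * (t1^2 - t0^2) + db * db * (t1^3 - t0^3) / 3
  }
  sqrt(max(total, 0))
}

## Linear pieces of a histogram quantile function: on the cumulative-mass
## interval [cum[b-1], cum[b]] (mass > 0), Q(t) = a + b t.
quantile_pieces <- function(h) {
  keep <- h$masses > 0
  widths <- diff(h$breaks)[keep]
  left <- h$breaks[-length(h$breaks)][keep]
  cum <- cumsum(h$masses[keep])
  lo <- c(0, cum[-length(cum)])
  slope <- widths / (cum - lo)
  list(cum = cum, lo = lo, a = left - lo * slope, b = slope)
}

piece_at <- function(q, t) {
  b <- findInterval(t, q$lo, rightmost.closed = FALSE)
  b <- min(max(b, 1L), length(q$cum))
  list(a = q$a[b], b = q$b[b])
}

## squared distance between two same-position elements, by kind
element_sq_distance <- function(x, y, kind, step = "symmetric2") {
  switch(kind,
         scalar = (x - y)^2,
         series = series_sq_distance(x, y, step),
         histogram = wasserstein(x, y)^2,
         stop("unknown element kind '", kind, "'"))
}

#' Row- and column-margin squared distance matrices
#'
#' The squared distance between rows `i` and `j` aggregates same-column
#' element discrepancies: `d(X_i., X_j.)^2 = sum_k d(X_ik, X_jk)^2`, where
#' the element distance is `|x - y|` for scalars, the per-coordinate DTW
#' combination of [series_sq_distance()] for series, and [wasserstein()]
#' for histograms.  The column margin mirrors this with rows and columns
#' exchanged, so `col_distance_matrix(x)` equals
#' `row_distance_matrix(t(x))`.
#'
#' @param data a `matrix_framed` object.
#' @param step DTW step pattern (series data only).
#' @return A `margin_dist` object: list with `axis` (`"row"`/`"column"`),
#'   `D2` (symmetric nonnegative matrix of squared distances, zero
#'   diagonal), and `ids`.
#' @export
row_distance_matrix <- function(data, step = "symmetric2") {
  stopifnot(inherits(data, "matrix_framed"))
  I <- length(data$row_ids); K <- length(data$col_ids)
  if (data$kind == "scalar") {
    D2 <- unname(as.matrix(stats::dist(data$values))^2)
  } else {
    D2 <- matrix(0, I, I)
    for (i in seq_len(I - 1L)) for (j in seq(i + 1L, I)) {
      s <- 0
      for (k in seq_len(K))
        s <- s + element_sq_distance(data$elements[[i, k]],
                                     data$elements[[j, k]], data$kind, step)
      D2[i, j] <- D2[j, i] <- s
    }
  }
  structure(list(axis = "row", D2 = D2, ids = data$row_ids),
            class = "margin_dist")
}

#' @rdname row_distance_matrix
#' @export
col_distance_matrix <- function(data, step = "symmetric2") {
  out <- row_distance_matrix(t(data), step)
  out$axis <- "column"
  out
}

#' Unstructured element-pair distance matrix
#'
#' All-pairs distances between the `I * K` flattened elements (row-major
#' order: element `(i, k)` is point `(i - 1) * K + k`), ignoring the grid
#' structure.  Distances are unsquared: `|x - y|` for scalars,
#' `sqrt(series_sq_distance)` for series, [wasserstein()] for histograms.
#' This feeds the classical t-SNE baseline.
#'
#' @inheritParams row_distance_matrix
#' @return An `element_dist` object: list with `D` (`n x n` symmetric,
#'   zero-diagonal), `row_id`, `col_id` per flattened point.
#' @export
element_distance_matrix <- function(data, step = "symmetric2") {
  stopifnot(inherits(data, "matrix_framed"))
  I <- length(data$row_ids); K <- length(data$col_ids)
  n <- I * K
  idx_i <- rep(seq_len(I), each = K)
  idx_k <- rep(seq_len(K), times = I)
  if (data$kind == "scalar") {
    v <- as.vector(t(data$values))
    D <- abs(outer(v, v, "-"))
  } else {
    D <- matrix(0, n, n)
    for (a in seq_len(n - 1L)) for (b in seq(a + 1L, n)) {
      d2 <- element_sq_distance(data$elements[[idx_i[a], idx_k[a]]],
                                data$elements[[idx_i[b], idx_k[b]]],
                                data$kind, step)
      D[a, b] <- D[b, a] <- sqrt(d2)
    }
  }
  structure(list(D = D, row_id = data$row_ids[idx_i],
                 col_id = data$col_ids[idx_k]),
            class = "element_dist")
}
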