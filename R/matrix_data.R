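#' Matrix-framed data
#'
#' A matrix-framed dataset is an `I x K` grid of typed elements indexed by
#' `I` distinct row labels and `K` distinct column labels.  All elements of
#' one dataset share a single kind:
#'
#' * `"scalar"` — each element is one finite real number;
#' * `"series"` — each element is a `T x P` real matrix (time points by
#'   coordinates); `P` is fixed across the dataset, `T` may vary per element;
#' * `"histogram"` — each element is a list with `breaks` (strictly
#'   increasing numeric vector of length `B + 1`) and `masses`
#'   (nonnegative, summing to 1).
#'
#' Internally scalar data are stored as a numeric matrix in `$values`;
#' series and histogram data as an `I x K` list-matrix in `$elements`.
#'
#' @param x for `scalar_data()`, a numeric matrix with unique `dimnames`
#'   (generated when absent); for `series_data()`/`histogram_data()`, an
#'   `I x K` list-matrix of elements.
#' @param row_ids,col_ids optional character labels overriding `dimnames`.
#' @return An object of class `matrix_framed` with fields `kind`,
#'   `row_ids`, `col_ids`, and `values` (scalar) or `elements` (otherwise).
#' @examples
#' d <- scalar_data(matrix(1:6, 2, 3))
#' dim(d)
#' @export
scalar_data <- function(x, row_ids = NULL, col_ids = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  ids <- resolve_ids(x, row_ids, col_ids, "r", "c")
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop("non-finite scalar element at row '", ids$row[bad[1L]],
         "', column '", ids$col[bad[2L]], "'")
  }
  new_matrix_framed("scalar", ids$row, ids$col, values = unname(x))
}

#' @rdname scalar_data
#' @export
series_data <- function(x, row_ids = NULL, col_ids = NULL) {
  stopifnot(is.matrix(x), is.list(x))
  ids <- resolve_ids(x, row_ids, col_ids, "r", "c")
  x[] <- lapply(x, function(e) {
    e <- as.matrix(e)
    storage.mode(e) <- "double"
    e
  })
  p <- unique(vapply(x, ncol, integer(1)))
  if (length(p) != 1L)
    stop("inconsistent series dimension P across elements: ",
         paste(sort(p), collapse = ", "))
  if (any(vapply(x, nrow, integer(1)) < 1L)) stop("series element with T < 1")
  if (!all(vapply(x, function(e) all(is.finite(e)), logical(1))))
    stop("non-finite value in a series element")
  new_matrix_framed("series", ids$row, ids$col, elements = unname(x))
}

#' @rdname scalar_data
#' @export
histogram_data <- function(x, row_ids = NULL, col_ids = NULL) {
  stopifnot(is.matrix(x), is.list(x))
  ids <- resolve_ids(x, row_ids, col_ids, "r", "c")
  x[] <- lapply(x, validate_histogram)
  new_matrix_framed("histogram", ids$row, ids$col, elements = unname(x))
}

new_matrix_framed <- function(kind, row_ids, col_ids, values = NULL,
                              elements = NULL) {
  I <- length(row_ids); K <- length(col_ids)
  if (I < 2L || K < 2L) stop("matrix-framed data needs I >= 2 and K >= 2")
  if (anyDuplicated(row_ids))
    stop("duplicate row label '", row_ids[duplicated(row_ids)][1L], "'")
  if (anyDuplicated(col_ids))
    stop("duplicate column label '", col_ids[duplicated(col_ids)][1L], "'")
  structure(list(kind = kind, row_ids = as.character(row_ids),
                 col_ids = as.character(col_ids),
                 values = values, elements = elements),
            class = "matrix_framed")
}

resolve_ids <- function(x, row_ids, col_ids, rp, cp) {
  if (is.null(row_ids)) row_ids <- rownames(x)
  if (is.null(col_ids)) col_ids <- colnames(x)
  if (is.null(row_ids)) row_ids <- paste0(rp, seq_len(nrow(x)))
  if (is.null(col_ids)) col_ids <- paste0(cp, seq_len(ncol(x)))
  stopifnot(length(row_ids) == nrow(x), length(col_ids) == ncol(x))
  list(row = as.character(row_ids), col = as.character(col_ids))
}

validate_histogram <- function(h, renorm_tol = 0) {
  if (!is.list(h) || is.null(h$breaks) || is.null(h$masses))
    stop("histogram element must be list(breaks, masses)")
  breaks <- as.numeric(h$breaks); masses <- as.numeric(h$masses)
  if (length(breaks) != length(masses) + 1L)
    stop("histogram needs length(breaks) == length(masses) + 1")
  if (length(masses) < 1L) stop("histogram needs at least one bin")
  if (any(!is.finite(breaks)) || any(!is.finite(masses)))
    stop("non-finite histogram entry")
  if (any(diff(breaks) <= 0)) stop("histogram breaks must be strictly increasing")
  if (any(masses < 0)) stop("negative histogram mass")
  s <- sum(masses)
  if (s == 0) stop("zero-mass histogram")
  if (abs(s - 1) > max(renorm_tol, 1e-9))
    stop("histogram masses sum to ", format(s), ", not 1")
  list(breaks = breaks, masses = masses / s)
}

#' @export
dim.matrix_framed <- function(x) c(length(x$row_ids), length(x$col_ids))

#' @export
print.matrix_framed <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("matrix-framed data: %d x %d, kind '%s'\n", d[1L], d[2L], x$kind))
  invisible(x)
}

#' Extract one element of a matrix-framed dataset
#'
#' @param data a `matrix_framed` object.
#' @param i,k row and column position (integer index).
#' @return The element: a scalar, a `T x P` matrix, or a
#'   `list(breaks, masses)` histogram.
#' @export
get_element <- function(data, i, k) {
  if (data$kind == "scalar") data$values[i, k] else data$elements[[i, k]]
}

#' Transpose a matrix-framed dataset
#'
#' Rows become columns and vice versa; element kind is preserved.
#'
#' @param x a `matrix_framed` object.
#' @export
t.matrix_framed <- function(x) {
  if (x$kind == "scalar")
    new_matrix_framed("scalar", x$col_ids, x$row_ids, values = t(x$values))
  else
    new_matrix_framed(x$kind, x$col_ids, x$row_ids, elements = t(x$elements))
}

## ---- readers / writers ----------------------------------------------------
## One fixed dialect: comma separator, '.' decimal mark, UTF-8, header rows.

#' Read and write a scalar matrix as delimited text
#'
#' The file has one header row of column labels and one leading column of row
#' labels; the body is numeric.  Labels are kept in file order.
#'
#' @param path file path.
#' @param data a scalar-kind `matrix_framed` object (for the writer).
#' @return `read_scalar_matrix()` returns a `matrix_framed` of kind
#'   `"scalar"`; `write_scalar_matrix()` returns `path` invisibly.
#' @export
read_scalar_matrix <- function(path) {
  lines <- read_csv_lines(path)
  if (length(lines) < 3L) stop("scalar matrix file needs a header and >= 2 rows")
  header <- split_csv(lines[[1L]])
  col_ids <- header[-1L]
  nfield <- length(header)
  body <- lines[-1L]
  row_ids <- character(length(body))
  values <- matrix(NA_real_, length(body), length(col_ids))
  for (r in seq_along(body)) {
    f <- split_csv(body[[r]])
    if (length(f) != nfield)
      stop("ragged row '", f[1L], "': expected ", nfield, " fields, got ",
           length(f))
    row_ids[r] <- f[1L]
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(v)) {
      k <- which(is.na(v))[1L]
      stop("non-numeric cell at row '", f[1L], "', column '", col_ids[k], "'")
    }
    values[r, ] <- v
  }
  scalar_data(values, row_ids, col_ids)
}

#' @rdname read_scalar_matrix
#' @export
write_scalar_matrix <- function(data, path) {
  stopifnot(inherits(data, "matrix_framed"), data$kind == "scalar")
  header <- paste(c("", data$col_ids), collapse = ",")
  body <- vapply(seq_along(data$row_ids), function(i) {
    paste(c(data$row_ids[i], num_chr(data$values[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read and write long-format tables of series or histogram elements
#'
#' Series tables have columns `row_id, col_id, dim, time, value` with
#' 0-based contiguous integer times per `(row_id, col_id, dim)`; histogram
#' tables have columns `row_id, col_id, bin_left, bin_right, mass` with
#' contiguous, ordered bins per cell.  Every `(row_id, col_id)` combination
#' must be present.  Histogram masses are renormalised to sum to 1 when
#' within `1e-6` of 1, otherwise the load fails.
#'
#' @param path file path.
#' @param kind `"series"` or `"histogram"`.
#' @param data a series- or histogram-kind `matrix_framed` (for the writer).
#' @return `read_long_table()` returns a `matrix_framed`;
#'   `write_long_table()` returns `path` invisibly.
#' @export
read_long_table <- function(path, kind = c("series", "histogram")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(row_id = "character",
                                       col_id = "character"))
  need <- if (kind == "series") c("row_id", "col_id", "dim", "time", "value")
          else c("row_id", "col_id", "bin_left", "bin_right", "mass")
  if (!all(need %in% names(df)))
    stop("long table must have columns: ", paste(need, collapse = ", "))
  row_ids <- unique(df$row_id); col_ids <- unique(df$col_id)
  I <- length(row_ids); K <- length(col_ids)
  key <- paste(df$row_id, df$col_id, sep = "\r")
  cells <- split(df, factor(key, levels = unique(key)))
  want <- as.vector(outer(row_ids, col_ids, paste, sep = "\r"))
  missing <- setdiff(want, names(cells))
  if (length(missing)) {
    m <- strsplit(missing[1L], "\r", fixed = TRUE)[[1L]]
    stop("missing cell (", m[1L], ", ", m[2L], ")")
  }
  elements <- matrix(vector("list", I * K), I, K)
  for (i in seq_len(I)) for (k in seq_len(K)) {
    cell <- cells[[paste(row_ids[i], col_ids[k], sep = "\r")]]
    elements[[i, k]] <- if (kind == "series") parse_series_cell(cell)
                        else parse_histogram_cell(cell)
  }
  if (kind == "series") series_data(elements, row_ids, col_ids)
  else histogram_data(elements, row_ids, col_ids)
}

parse_series_cell <- function(cell) {
  dims <- sort(unique(as.numeric(cell$dim)))
  ok <- isTRUE(all.equal(dims, seq_along(dims) - 1)) ||
        isTRUE(all.equal(dims, as.numeric(seq_along(dims))))
  if (!ok)
    stop("series dims must be contiguous integers in cell (",
         cell$row_id[1L], ", ", cell$col_id[1L], ")")
  cols <- lapply(dims, function(d) {
    sub <- cell[cell$dim == d, ]
    sub <- sub[order(sub$time), ]
    if (!identical(as.numeric(sub$time), as.numeric(seq_len(nrow(sub)) - 1)))
      stop("series times must be 0-based contiguous integers in cell (",
           cell$row_id[1L], ", ", cell$col_id[1L], ")")
    sub$value
  })
  tlen <- unique(lengths(cols))
  if (length(tlen) != 1L)
    stop("unequal T across dims in cell (", cell$row_id[1L], ", ",
         cell$col_id[1L], ")")
  matrix(unlist(cols), ncol = length(cols))
}

parse_histogram_cell <- function(cell) {
  cell <- cell[order(cell$bin_left), ]
  breaks <- c(cell$bin_left, cell$bin_right[nrow(cell)])
  if (any(abs(cell$bin_right[-nrow(cell)] - cell$bin_left[-1L]) > 1e-12) ||
      any(diff(breaks) <= 0))
    stop("overlapping or unordered bins in cell (", cell$row_id[1L], ", ",
         cell$col_id[1L], ")")
  s <- sum(cell$mass)
  if (abs(s - 1) > 1e-6)
    stop("histogram masses in cell (", cell$row_id[1L], ", ",
         cell$col_id[1L], ") sum to ", format(s), ", not within 1e-6 of 1")
  validate_histogram(list(breaks = breaks, masses = cell$mass), renorm_tol = 1e-6)
}

#' @rdname read_long_table
#' @export
write_long_table <- function(data, path) {
  stopifnot(inherits(data, "matrix_framed"), data$kind != "scalar")
  I <- length(data$row_ids); K <- length(data$col_ids)
  recs <- character(0)
  if (data$kind == "series") {
    header <- "row_id,col_id,dim,time,value"
    for (i in seq_len(I)) for (k in seq_len(K)) {
      e <- data$elements[[i, k]]
      for (p in seq_len(ncol(e)))
        recs <- c(recs, paste(data$row_ids[i], data$col_ids[k], p - 1L,
                              seq_len(nrow(e)) - 1L, num_chr(e[, p]), sep = ","))
    }
  } else {
    header <- "row_id,col_id,bin_left,bin_right,mass"
    for (i in seq_len(I)) for (k in seq_len(K)) {
      e <- data$elements[[i, k]]
      b <- length(e$masses)
      recs <- c(recs, paste(data$row_ids[i], data$col_ids[k],
                            num_chr(e$breaks[-(b + 1L)]), num_chr(e$breaks[-1L]),
                            num_chr(e$masses), sep = ","))
    }
  }
  writeLines(c(header, recs), path, useBytes = TRUE)
  invisible(path)
}

#' Write or read a 2-D embedding as delimited text
#'
#' One record per matrix element, columns `row_id, col_id, y1, y2`, in
#' row-major element order.  Coordinates are written with 17 significant
#' digits so that a read-back reproduces them to better than `1e-12`.
#'
#' @param embedding a `matrix_embedding` object.
#' @param path file path.
#' @return `write_embedding()` returns `path` invisibly; `read_embedding()`
#'   a `matrix_embedding`.
#' @export
write_embedding <- function(embedding, path) {
  stopifnot(inherits(embedding, "matrix_embedding"))
  if (!all(is.finite(embedding$Y)))
    stop("embedding contains non-finite coordinates; refusing to write")
  df <- as.data.frame(embedding)
  recs <- paste(df$row_id, df$col_id, num_chr(df$y1), num_chr(df$y2), sep = ",")
  writeLines(c("row_id,col_id,y1,y2", recs), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(row_id = "character",
                                       col_id = "character",
                                       y1 = "numeric", y2 = "numeric"))
  row_ids <- unique(df$row_id); col_ids <- unique(df$col_id)
  I <- length(row_ids); K <- length(col_ids)
  if (nrow(df) != I * K) stop("embedding file is not a complete I x K grid")
  Y <- array(NA_real_, c(I, K, 2L))
  i <- match(df$row_id, row_ids); k <- match(df$col_id, col_ids)
  Y[cbind(i, k, 1L)] <- df$y1
  Y[cbind(i, k, 2L)] <- df$y2
  matrix_embedding(Y, row_ids, col_ids)
}

## shared CSV helpers: one dialect — comma, '.', UTF-8
read_csv_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines[nzchar(lines)]
}
split_csv <- function(line) strsplit(line, ",", fixed = TRUE)[[1L]]
num_chr <- function(x) sprintf("%.17g", x)
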