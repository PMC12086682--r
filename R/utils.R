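#' @importFrom methods as is
#' @importFrom stats median quantile rgamma rnorm runif setNames dist
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce dense or sparse input to dgCMatrix
as_dgc <- function(x) {
  if (!is(x, "sparseMatrix")) x <- Matrix::Matrix(as.matrix(x), sparse = TRUE)
  as(as(x, "CsparseMatrix"), "generalMatrix")
}

#' Exact k-nearest neighbors with the self excluded
#'
#' Thin wrapper around a kd-tree search that removes each point's own index
#' from its neighbor list and re-sorts returned neighbors by
#' (distance, index) so tie handling is deterministic.
#'
#' @param x Numeric matrix (points in rows).
#' @param k Number of neighbors to return per point (`k < nrow(x)`).
#' @param tie_buffer Extra neighbors fetched before tie-stable re-sorting.
#' @return List with integer matrix `idx` and numeric matrix `dist`, both
#'   `nrow(x) x k`, distances nondecreasing along rows.
#' @export
exact_knn <- function(x, k, tie_buffer = 5L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of points (", n, ")")
  kq <- min(n, k + 1L + tie_buffer)
  nn <- RANN::nn2(x, k = kq, treetype = "kd", searchtype = "standard")
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ii <- nn$nn.idx[i, ]
    dd <- nn$nn.dists[i, ]
    keep <- ii != i
    # with exact duplicates RANN may list i itself later than column 1;
    # drop exactly one occurrence of the self index
    if (sum(!keep) == 0L) keep[kq] <- FALSE
    ii <- ii[keep][seq_len(min(sum(keep), kq - 1L))]
    dd <- dd[keep][seq_len(length(ii))]
    o <- order(dd, ii)[seq_len(k)]
    idx[i, ] <- ii[o]
    dst[i, ] <- dd[o]
  }
  list(idx = idx, dist = dst)
}

# row-wise Euclidean distances from x[i, ] to x[idx[i, j], ] for each column j
cross_distances <- function(x, idx) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- ncol(idx)
  out <- matrix(0, n, k)
  for (j in seq_len(k)) {
    d <- x - x[idx[, j], , drop = FALSE]
    out[, j] <- sqrt(rowSums(d * d))
  }
  out
}

row_medians <- function(m) apply(m, 1L, median)

check_finite <- function(x, what) {
  xs <- if (is(x, "sparseMatrix")) x@x else x
  if (length(xs) && any(!is.finite(xs)))
    stop(what, " contains non-finite entries")
  invisible(TRUE)
}
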