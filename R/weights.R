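#' Empirical CDF of cell-cell distances in one modality
#'
#' Samples `P` unordered pairs of distinct cells uniformly (with replacement
#' across pairs) and records their Euclidean distances. Evaluating the ECDF at
#' `x` returns the fraction of sampled distances that are `<= x`, a
#' rank-based normalization of distances to `[0, 1]` relative to the
#' modality's global geometry.
#'
#' @param embedding Cell-by-dimension matrix for the modality.
#' @param P Number of sampled pairs (1000 is usually enough).
#' @param seed Optional RNG seed; with the same seed every modality samples
#'   the same cell pairs, which makes downstream weights exactly equivariant
#'   under modality permutation.
#' @return Object of class `distance_ecdf` (sorted distance sample).
#' @export
estimate_ecdf <- function(embedding, P = 1000L, seed = NULL) {
  embedding <- as.matrix(embedding)
  C <- nrow(embedding)
  if (C < 2L) stop("insufficient data: need at least 2 cells to sample pairs")
  if (P < 1L) stop("P must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  a <- sample.int(C, P, replace = TRUE)
  b <- sample.int(C - 1L, P, replace = TRUE)
  b <- ifelse(b >= a, b + 1L, b)  # uniform over distinct partners
  d <- sqrt(rowSums((embedding[a, , drop = FALSE] -
                     embedding[b, , drop = FALSE])^2))
  structure(list(sample = sort(d), P = as.integer(P)),
            class = "distance_ecdf")
}

#' Evaluate a distance ECDF
#' @param e A `distance_ecdf`.
#' @param x Numeric vector or matrix of distances.
#' @return Values in `[0, 1]`, same shape as `x`.
#' @export
ecdf_evaluate <- function(e, x) {
  stopifnot(inherits(e, "distance_ecdf"))
  v <- findInterval(x, e$sample) / e$P
  if (is.matrix(x)) v <- matrix(v, nrow(x), ncol(x))
  v
}

#' Per-modality nearest neighborhoods
#'
#' Computes, for each modality, the `k` nearest neighbors of every cell in
#' that modality's own space (self excluded).
#'
#' @param embeddings List of cell-by-dimension matrices, one per modality.
#' @param k Neighbor count.
#' @return List of `exact_knn()` results, one per modality.
#' @export
modality_neighborhoods <- function(embeddings, k) {
  lapply(embeddings, exact_knn, k = k)
}

#' Raw modality scores from ECDF-scaled cross-modality distances
#'
#' For each cell `c` and modality `m`, sums over the remaining modalities `l`
#' the median ECDF^m-scaled distance from `c` to its modality-`l` nearest
#' neighbors, the distances being measured in modality-`m` space. A large
#' score means the cell's cross-modality neighborhood is expanded in `m`,
#' i.e. modality `m` is where developmental movement is happening.
#'
#' @param embeddings List of per-modality matrices.
#' @param neighborhoods Result of [modality_neighborhoods()].
#' @param ecdfs List of per-modality `distance_ecdf` objects.
#' @return Cell-by-modality matrix of raw scores.
#' @export
score_modalities <- function(embeddings, neighborhoods, ecdfs) {
  M <- length(embeddings)
  if (M < 2L)
    stop("configuration error: modality scoring needs at least 2 modalities")
  C <- nrow(embeddings[[1L]])
  s <- matrix(0, C, M)
  for (m in seq_len(M)) {
    for (l in seq_len(M)[-m]) {
      d_ml <- cross_distances(embeddings[[m]], neighborhoods[[l]]$idx)
      s[, m] <- s[, m] + row_medians(ecdf_evaluate(ecdfs[[m]], d_ml))
    }
  }
  colnames(s) <- names(embeddings)
  s
}

#' Smooth modality scores over the highest-scoring modality's neighborhood
#'
#' Each cell's score row is replaced by the mean of the score rows over the
#' cell itself and its `smoothing_k` nearest neighbors in the space of its
#' highest-scoring modality (argmax ties break toward the lower modality
#' index). Self-inclusion keeps isolated cells stable.
#'
#' @param scores Cell-by-modality score matrix.
#' @param neighborhoods Result of [modality_neighborhoods()].
#' @param smoothing_k Neighbors averaged over; defaults to the full
#'   neighborhood width.
#' @return Smoothed score matrix, same shape.
#' @export
smooth_scores <- function(scores, neighborhoods, smoothing_k = NULL) {
  check_finite(scores, "scores")
  smoothing_k <- smoothing_k %||% ncol(neighborhoods[[1L]]$idx)
  smoothing_k <- min(smoothing_k, ncol(neighborhoods[[1L]]$idx))
  mstar <- max.col(scores, ties.method = "first")
  out <- scores
  for (m in unique(mstar)) {
    rows <- which(mstar == m)
    acc <- scores[rows, , drop = FALSE]
    idx <- neighborhoods[[m]]$idx
    for (j in seq_len(smoothing_k))
      acc <- acc + scores[idx[rows, j], , drop = FALSE]
    out[rows, ] <- acc / (smoothing_k + 1)
  }
  out
}

#' Softmax normalization of modality scores into weights
#'
#' `w_c^m = exp(alpha * s_c^m) / sum_l exp(alpha * s_c^l)`, computed with
#' max-subtraction for numerical stability. Rows sum to 1 exactly up to
#' floating point.
#'
#' @param scores Cell-by-modality score matrix.
#' @param alpha Softmax temperature, must be `>= 1`; 10 by default (sharper
#'   than 1, so the dominant modality is emphasized without saturating).
#' @return Cell-by-modality weight matrix of class `weight_matrix` with
#'   attributes `alpha`.
#' @export
softmax_weights <- function(scores, alpha = 10) {
  if (alpha < 1) stop("configuration error: alpha must be >= 1")
  z <- alpha * scores
  z <- z - apply(z, 1L, max)
  w <- exp(z)
  w <- w / rowSums(w)
  attr(w, "alpha") <- alpha
  class(w) <- c("weight_matrix", class(w))
  w
}

#' Cell-specific multimodal weights
#'
#' End-to-end weight pipeline: per-modality nearest neighborhoods, shared-pair
#' distance ECDFs, cross-modality scoring, neighborhood smoothing, and softmax
#' normalization. The result is a per-cell probability distribution over
#' modalities quantifying which modality's geometry carries the cell's
#' developmental signal.
#'
#' @param embeddings List of per-modality cell-by-dimension matrices (shared
#'   cell order), or a [multimodal_dataset()].
#' @param k Nearest-neighbor count used for cross-modality distances and
#'   smoothing; 20 by default, 60 for the simulated-data weight benchmarks.
#' @param P ECDF pair-sample size.
#' @param alpha Softmax temperature (`>= 1`).
#' @param smoothing_k Neighbor count for score smoothing; defaults to `k`.
#' @param seed RNG seed for the ECDF pair sample.
#' @return `weight_matrix` (cells x modalities, rows sum to 1).
#' @export
compute_weights <- function(embeddings, k = 20L, P = 1000L, alpha = 10,
                            smoothing_k = NULL, seed = NULL) {
  if (inherits(embeddings, "multimodal_dataset"))
    embeddings <- embeddings$modalities
  embeddings <- lapply(embeddings, as.matrix)
  M <- length(embeddings)
  if (M < 2L)
    stop("configuration error: weights need at least 2 modalities")
  seed <- seed %||% sample.int(.Machine$integer.max, 1L)
  nbh <- modality_neighborhoods(embeddings, k)
  # identical seed per modality => identical sampled pairs across modalities
  ecdfs <- lapply(embeddings, estimate_ecdf, P = P, seed = seed)
  s <- score_modalities(embeddings, nbh, ecdfs)
  s <- smooth_scores(s, nbh, smoothing_k = smoothing_k %||% k)
  w <- softmax_weights(s, alpha = alpha)
  rownames(w) <- rownames(embeddings[[1L]])
  colnames(w) <- names(embeddings)
  attr(w, "smoothing_k") <- smoothing_k %||% k
  w
}

#' Validate a weight matrix
#' @param w Cell-by-modality matrix.
#' @param tol Row-sum tolerance.
#' @return `w`, invisibly; errors if rows do not sum to 1 or entries leave
#'   `[0, 1]`.
#' @export
validate_weights <- function(w, tol = 1e-9) {
  if (any(w < 0) || any(w > 1)) stop("weights must lie in [0, 1]")
  if (max(abs(rowSums(w) - 1)) > tol)
    stop("weight rows must sum to 1 within ", tol)
  invisible(w)
}
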