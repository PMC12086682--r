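#' Density-adjusted Gaussian affinity kernel
#'
#' Builds the sparse symmetric affinity graph of one modality. The affinity
#' between cells `c1, c2` is `exp(-d(c1,c2)^2 / (eps_c1 * eps_c2))` where
#' `eps_c` is the distance from `c` to its `n_kernel_neighbor`-th nearest
#' neighbor, adapting the bandwidth to local density. Affinities are computed
#' to each cell's `n_graph_neighbors` nearest neighbors and the graph is
#' symmetrized by union: if an edge exists in either direction both entries
#' carry the same kernel value. Self-affinities are excluded.
#'
#' @param embedding Cell-by-dimension matrix.
#' @param n_kernel_neighbor Index of the neighbor whose distance sets the
#'   local bandwidth `eps_c` (20 by default).
#' @param n_graph_neighbors Neighbors kept per cell in the sparse graph;
#'   defaults to `n_kernel_neighbor`.
#' @return Sparse symmetric `dgCMatrix` of affinities in `[0, 1]`.
#' @export
gaussian_kernel <- function(embedding, n_kernel_neighbor = 20L,
                            n_graph_neighbors = NULL) {
  embedding <- as.matrix(embedding)
  C <- nrow(embedding)
  n_graph_neighbors <- max(n_graph_neighbors %||% n_kernel_neighbor,
                           n_kernel_neighbor)
  if (C <= n_kernel_neighbor)
    stop("need more cells than n_kernel_neighbor")
  nn <- exact_knn(embedding, min(n_graph_neighbors, C - 1L))
  eps <- nn$dist[, n_kernel_neighbor]
  if (any(eps == 0)) {
    warning("duplicate cells give a zero kernel bandwidth; ",
            "flooring eps at a machine-epsilon-scaled value")
    floor_val <- max(max(eps), 1) * sqrt(.Machine$double.eps)
    eps[eps == 0] <- floor_val
  }
  i <- rep(seq_len(C), ncol(nn$idx))
  j <- as.vector(nn$idx)
  kap <- exp(-as.vector(nn$dist)^2 / (eps[i] * eps[j]))
  a <- Matrix::drop0(Matrix::sparseMatrix(i = i, j = j, x = kap,
                                          dims = c(C, C)))
  # union symmetrization: kappa is symmetric in its arguments, so averaging
  # the (equal) values present in either direction reproduces kappa exactly
  b <- a + Matrix::t(a)
  cnt <- (a != 0) + (Matrix::t(a) != 0)
  b@x <- b@x / cnt@x
  b
}

#' Weighted multimodal Markov chain
#'
#' Combines per-modality affinity kernels and cell-specific modality weights
#' into a single diffusion operator. Per modality, affinities are scaled by
#' the average weight of the two endpoint cells (keeping each kernel
#' symmetric), row-normalized, and summed across modalities; the sum is
#' row-normalized again and symmetrized along the diagonal.
#'
#' @param affinities List of sparse symmetric C x C affinity matrices, one per
#'   modality (from [gaussian_kernel()]).
#' @param weights Cell-by-modality weight matrix with rows summing to 1.
#' @return Object of class `multimodal_chain` with elements
#'   `per_modality_K` (weighted affinities, Eq.-level symmetric), `combined_K`
#'   (sum of row-normalized weighted affinities), and `symmetric_K` (the
#'   symmetrized operator actually eigendecomposed).
#' @export
build_chain <- function(affinities, weights) {
  M <- length(affinities)
  C <- nrow(affinities[[1L]])
  weights <- as.matrix(weights)
  if (nrow(weights) != C || ncol(weights) != M)
    stop("weights must be ", C, " x ", M)
  validate_weights(weights, tol = 1e-6)
  per_modality <- vector("list", M)
  normalized <- vector("list", M)
  for (m in seq_len(M)) {
    km <- as_dgc(affinities[[m]])
    t3 <- as(km, "TsparseMatrix")
    wavg <- (weights[t3@i + 1L, m] + weights[t3@j + 1L, m]) / 2
    km@x <- t3@x * wavg
    per_modality[[m]] <- km
    rs <- Matrix::rowSums(km)
    zero <- rs == 0
    if (any(zero))
      warning(sum(zero), " cell(s) isolated in modality ", m,
              "; their chain rows stay zero")
    dinv <- ifelse(zero, 0, 1 / rs)
    normalized[[m]] <- Matrix::Diagonal(x = dinv) %*% km
  }
  K <- Reduce(`+`, normalized)
  rsk <- Matrix::rowSums(K)
  dinv <- ifelse(rsk == 0, 0, 1 / rsk)
  DK <- Matrix::Diagonal(x = dinv) %*% K
  K_hat <- DK + Matrix::t(DK)
  structure(list(per_modality_K = per_modality, combined_K = K,
                 symmetric_K = as_dgc(K_hat)),
            class = "multimodal_chain")
}

#' Eigendecompose the symmetrized multimodal chain
#'
#' Computes the top `n_components + n_extra + 1` eigenpairs of the symmetric
#' operator, sorted by decreasing algebraic eigenvalue. The extra pairs guard
#' against accuracy degradation of trailing eigenvectors and are discarded at
#' embedding time. Eigenvector signs are fixed by making the
#' largest-magnitude entry positive so output is reproducible.
#'
#' @param chain A `multimodal_chain` or a symmetric matrix.
#' @param n_components Number of embedding dimensions wanted (N).
#' @param n_extra Guard eigenpairs (E), 10 by default.
#' @param method `"auto"` (dense for up to 500 cells, else sparse Lanczos),
#'   `"dense"`, or `"sparse"`.
#' @return Object of class `eigen_system`: `values` (decreasing),
#'   `vectors` (unit-norm columns), `n_components`, `n_extra`.
#' @export
eigendecompose <- function(chain, n_components, n_extra = 10L,
                           method = c("auto", "dense", "sparse")) {
  method <- match.arg(method)
  K_hat <- if (inherits(chain, "multimodal_chain")) chain$symmetric_K else chain
  if (is(K_hat, "sparseMatrix")) K_hat <- as_dgc(K_hat)
  C <- nrow(K_hat)
  k <- n_components + n_extra + 1L
  if (k > C - 1L)
    stop("n_components + n_extra + 1 must be at most C - 1")
  if (method == "auto") method <- if (C <= 500L) "dense" else "sparse"
  if (method == "dense") {
    e <- eigen(as.matrix(K_hat), symmetric = TRUE)
    values <- e$values[seq_len(k)]
    vectors <- e$vectors[, seq_len(k), drop = FALSE]
  } else {
    e <- tryCatch(
      RSpectra::eigs_sym(K_hat, k = k, which = "LA",
                         opts = list(initvec = rep(1 / sqrt(C), C))),
      error = function(err)
        stop("sparse eigensolver failed (", conditionMessage(err),
             "); retry with method = \"dense\""))
    if (e$nconv < k)
      stop("sparse eigensolver converged for only ", e$nconv, " of ", k,
           " eigenpairs; retry with method = \"dense\"")
    o <- order(e$values, decreasing = TRUE)
    values <- e$values[o]
    vectors <- e$vectors[, o, drop = FALSE]
  }
  for (i in seq_len(ncol(vectors))) {
    v <- vectors[, i]
    v <- v / sqrt(sum(v * v))
    if (v[which.max(abs(v))] < 0) v <- -v
    vectors[, i] <- v
  }
  structure(list(values = values, vectors = vectors,
                 n_components = as.integer(n_components),
                 n_extra = as.integer(n_extra)),
            class = "eigen_system")
}

#' MDM embedding from retained eigenpairs
#'
#' Column `i` of the embedding is `lambda_{i+1} * q_{i+1}`: eigenvalue-scaled
#' eigenvectors, skipping the first (largest) eigenpair, which is
#' non-informative for recovering developmental structure.
#'
#' @param eig An `eigen_system`.
#' @param n_components Number of embedding dimensions; defaults to the value
#'   stored in `eig`.
#' @return Cell-by-`n_components` coordinate matrix.
#' @export
mdm_embedding <- function(eig, n_components = NULL) {
  n <- n_components %||% eig$n_components
  if (length(eig$values) < n + 1L)
    stop("dimension error: eigen system holds ", length(eig$values),
         " pairs; need ", n + 1L)
  cols <- seq_len(n) + 1L
  coords <- sweep(eig$vectors[, cols, drop = FALSE], 2L, eig$values[cols], `*`)
  colnames(coords) <- paste0("MDM", seq_len(n))
  coords
}

#' Run the full multimodal diffusion map
#'
#' Pipeline: per-modality density-adjusted Gaussian kernels, multimodal
#' weights (computed if not supplied; unit weights for a single modality),
#' weighted multimodal Markov chain, symmetric eigendecomposition, and the
#' eigenvalue-scaled embedding.
#'
#' @param dataset A [multimodal_dataset()] or list of per-modality
#'   cell-by-dimension matrices (shared cell order).
#' @param n_components Embedding dimensions (N), 10 by default.
#' @param n_kernel_neighbor Kernel bandwidth neighbor (20 by default).
#' @param n_graph_neighbors Sparse-graph neighbors per cell; defaults to
#'   `max(weight_k, n_kernel_neighbor)`.
#' @param n_extra Guard eigenpairs (E), 10 by default.
#' @param weights Optional precomputed weight matrix; computed via
#'   [compute_weights()] when `NULL` and more than one modality is present.
#' @param weight_k Neighbor count handed to [compute_weights()].
#' @param ecdf_pairs ECDF pair-sample size for the weights.
#' @param alpha Softmax temperature for the weights.
#' @param seed RNG seed (ECDF pair sampling).
#' @param eigen_method Passed to [eigendecompose()].
#' @return List of class `mdm_result`: `embedding`, `eigen` (`eigen_system`),
#'   `chain` (`multimodal_chain`), `weights`.
#' @export
run_mdm <- function(dataset, n_components = 10L, n_kernel_neighbor = 20L,
                    n_graph_neighbors = NULL, n_extra = 10L, weights = NULL,
                    weight_k = 20L, ecdf_pairs = 1000L, alpha = 10,
                    seed = NULL, eigen_method = "auto") {
  embeddings <- if (inherits(dataset, "multimodal_dataset"))
    dataset$modalities else dataset
  embeddings <- lapply(embeddings, as.matrix)
  M <- length(embeddings)
  C <- nrow(embeddings[[1L]])
  n_graph_neighbors <- n_graph_neighbors %||%
    max(weight_k, n_kernel_neighbor)
  if (is.null(weights)) {
    weights <- if (M == 1L) {
      matrix(1, C, 1L)
    } else {
      compute_weights(embeddings, k = weight_k, P = ecdf_pairs,
                      alpha = alpha, seed = seed)
    }
  }
  affinities <- lapply(embeddings, gaussian_kernel,
                       n_kernel_neighbor = n_kernel_neighbor,
                       n_graph_neighbors = n_graph_neighbors)
  chain <- build_chain(affinities, weights)
  eig <- eigendecompose(chain, n_components = n_components,
                        n_extra = n_extra, method = eigen_method)
  coords <- mdm_embedding(eig, n_components)
  rownames(coords) <- rownames(embeddings[[1L]])
  structure(list(embedding = coords, eigen = eig, chain = chain,
                 weights = weights),
            class = "mdm_result")
}
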