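# Independent brute-force oracles used to pin expected values. These
# deliberately avoid the package's sparse/kNN code paths: everything is dense
# arithmetic straight from the model definitions.

# all-pairs kNN by full distance sort (ties by index)
brute_knn <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(dist(x))
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    o <- order(d[i, ], seq_len(n))
    o <- o[o != i][seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- d[i, o]
  }
  list(idx = idx, dist = dst)
}

# dense density-adjusted Gaussian kernel over the FULL graph (every pair kept)
dense_kernel_oracle <- function(x, n_kernel_neighbor) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(dist(x))
  eps <- vapply(seq_len(n),
                function(i) sort(d[i, -i])[n_kernel_neighbor], numeric(1L))
  kap <- exp(-d^2 / outer(eps, eps))
  diag(kap) <- 0
  kap
}

# dense weighted multimodal chain: weighted affinities, row-normalized sum,
# row-normalized again, symmetrized along the diagonal
dense_chain_oracle <- function(kernels, w) {
  n <- nrow(kernels[[1L]])
  M <- length(kernels)
  K <- matrix(0, n, n)
  for (m in seq_len(M)) {
    km <- kernels[[m]] * (outer(w[, m], w[, m], `+`) / 2)
    rs <- rowSums(km)
    rs[rs == 0] <- Inf
    K <- K + km / rs
  }
  rs <- rowSums(K)
  rs[rs == 0] <- Inf
  DK <- K / rs
  DK + t(DK)
}

# full dense pipeline: kernels -> chain -> eigen -> eigenvalue-scaled
# embedding skipping the first pair
dense_mdm_oracle <- function(modalities, w, n_kernel_neighbor, n_components) {
  kernels <- lapply(modalities, dense_kernel_oracle, n_kernel_neighbor)
  k_hat <- dense_chain_oracle(kernels, w)
  e <- eigen(k_hat, symmetric = TRUE)
  cols <- seq_len(n_components) + 1L
  list(values = e$values, vectors = e$vectors,
       coords = sweep(e$vectors[, cols, drop = FALSE], 2L,
                      e$values[cols], `*`),
       k_hat = k_hat)
}

# exhaustive ECDF over every distinct cell pair
full_pair_ecdf <- function(x) {
  d <- sort(as.vector(dist(x)))
  function(q) findInterval(q, d) / length(d)
}

# align eigenvector columns up to sign and compare
expect_vectors_match <- function(got, want, tol = 1e-6) {
  expect_equal(dim(got), dim(want))
  for (i in seq_len(ncol(got))) {
    s <- sign(sum(got[, i] * want[, i]))
    expect_lt(max(abs(got[, i] - s * want[, i])), tol)
  }
}

# kNN label purity by exhaustive vote
knn_purity <- function(coords, labels, k = 20L) {
  nn <- exact_knn(as.matrix(coords), k)
  mean(vapply(seq_len(nrow(coords)),
              function(i) mean(labels[nn$idx[i, ]] == labels[i]),
              numeric(1L)))
}

# small reproducible multimodal instance
random_modalities <- function(C, dims = c(3L, 3L), seed = 1L) {
  set.seed(seed)
  lapply(dims, function(d) matrix(rnorm(C * d), C, d))
}
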