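test_that("gaussian kernel reproduces closed-form affinities and symmetry", {
  # collinear points spaced 1 apart with bandwidth from the 1st neighbor:
  # every eps is 1, so kappa at distance 1 is exp(-1)
  x <- matrix(c(0, 1, 2, 3), ncol = 1)
  k <- gaussian_kernel(x, n_kernel_neighbor = 1, n_graph_neighbors = 2)
  expect_equal(k[1, 2], exp(-1), tolerance = 1e-12)
  expect_equal(k[2, 3], exp(-1), tolerance = 1e-12)
  expect_equal(k[1, 3], exp(-4), tolerance = 1e-12)
  expect_equal(k[1, 1], 0)

  set.seed(31)
  y <- matrix(rnorm(90), 30, 3)
  ky <- gaussian_kernel(y, n_kernel_neighbor = 3, n_graph_neighbors = 5)
  expect_equal(max(abs(ky - Matrix::t(ky))), 0)
  expect_true(all(ky@x >= 0))

  dup <- y[c(1, 1, 1:28), ]
  expect_warning(gaussian_kernel(dup, n_kernel_neighbor = 1,
                                 n_graph_neighbors = 3), "bandwidth")
})

test_that("chain construction matches hand evaluation on a 4-cell toy", {
  kern <- list(
    matrix(c(0, .9, .1, 0, .9, 0, .2, 0, .1, .2, 0, .5, 0, 0, .5, 0), 4, 4),
    matrix(c(0, .3, 0, .4, .3, 0, .6, 0, 0, .6, 0, .2, .4, 0, .2, 0), 4, 4))
  w <- matrix(c(.7, .2, .5, .9, .3, .8, .5, .1), 4, 2)
  chain <- build_chain(lapply(kern, Matrix::Matrix, sparse = TRUE), w)

  k_hat <- dense_chain_oracle(kern, w)
  expect_equal(as.matrix(chain$symmetric_K), k_hat, tolerance = 1e-12,
               ignore_attr = TRUE)
  for (m in 1:2) {
    km <- kern[[m]] * (outer(w[, m], w[, m], `+`) / 2)
    expect_equal(as.matrix(chain$per_modality_K[[m]]), km,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unname(Matrix::rowSums(chain$per_modality_K[[m]] /
                                          rowSums(km))), rep(1, 4),
                 tolerance = 1e-12)
  }
  expect_equal(max(abs(chain$symmetric_K - Matrix::t(chain$symmetric_K))), 0)
})

test_that("row-stochasticity holds for the combined chain", {
  emb <- random_modalities(25, dims = c(3, 3), seed = 32)
  w <- compute_weights(emb, k = 4, P = 200, seed = 32)
  kernels <- lapply(emb, gaussian_kernel, n_kernel_neighbor = 4)
  chain <- build_chain(kernels, as.matrix(w))
  # K itself sums to M per row (each row-normalized summand contributes 1);
  # DK is row-stochastic
  rs <- Matrix::rowSums(chain$combined_K)
  expect_equal(unname(rs), rep(2, 25), tolerance = 1e-9)
})

test_that("eigendecomposition is exact on a diagonal operator and matches a
           dense factorization on random instances", {
  d <- Matrix::Diagonal(x = c(3, 2, 1, 0.5, 0.1, 0.05))
  eig <- eigendecompose(d, n_components = 1, n_extra = 1, method = "dense")
  expect_equal(eig$values, c(3, 2, 1))
  expect_equal(abs(eig$vectors), diag(6)[, 1:3], tolerance = 1e-12)

  set.seed(33)
  a <- matrix(rnorm(2500), 50, 50)
  k_hat <- Matrix::Matrix(crossprod(a) / 50, sparse = TRUE)
  sp <- eigendecompose(k_hat, n_components = 4, n_extra = 5, method = "sparse")
  dn <- eigendecompose(k_hat, n_components = 4, n_extra = 5, method = "dense")
  expect_equal(sp$values, dn$values, tolerance = 1e-8)
  expect_vectors_match(sp$vectors, dn$vectors, tol = 1e-6)
  # orthonormality of retained eigenvectors
  g <- crossprod(sp$vectors)
  expect_lt(max(abs(g - diag(ncol(g)))), 1e-6)
  expect_error(eigendecompose(d, n_components = 4, n_extra = 2), "at most")
})

test_that("the embedding scales eigenvectors and skips the first pair", {
  eig <- structure(list(values = c(2, 1, 0.5), vectors = diag(5)[, 1:3],
                        n_components = 2L, n_extra = 0L),
                   class = "eigen_system")
  co <- mdm_embedding(eig)
  expect_equal(unname(co), cbind(diag(5)[, 2], 0.5 * diag(5)[, 3]))
  eig$values <- c(2, 0, 0)
  expect_equal(unname(mdm_embedding(eig)), matrix(0, 5, 2))
  expect_error(mdm_embedding(eig, n_components = 3), "dimension error")
})

test_that("a single modality with unit weights reproduces the classical
           diffusion map", {
  set.seed(34)
  x <- matrix(rnorm(80 * 3), 80, 3)
  res <- run_mdm(list(x), n_components = 3, n_kernel_neighbor = 5,
                 n_graph_neighbors = 79, n_extra = 3)
  oracle <- dense_mdm_oracle(list(x), matrix(1, 80, 1), 5, 3)
  expect_vectors_match(res$embedding, oracle$coords, tol = 1e-6)
})

test_that("duplicated modalities embed like the single modality and modality
           order does not change the embedding", {
  set.seed(35)
  x <- matrix(rnorm(60 * 3), 60, 3)
  res1 <- run_mdm(list(x), n_components = 2, n_kernel_neighbor = 4,
                  n_graph_neighbors = 10, n_extra = 2)
  res2 <- run_mdm(list(x, x), n_components = 2, n_kernel_neighbor = 4,
                  n_graph_neighbors = 10, n_extra = 2, seed = 5)
  expect_vectors_match(res2$embedding, res1$embedding, tol = 1e-6)

  emb <- random_modalities(50, dims = c(3, 2), seed = 36)
  ra <- run_mdm(emb, n_components = 2, n_kernel_neighbor = 4,
                n_graph_neighbors = 8, n_extra = 2, seed = 7)
  rb <- run_mdm(emb[c(2, 1)], n_components = 2, n_kernel_neighbor = 4,
                n_graph_neighbors = 8, n_extra = 2, seed = 7)
  expect_equal(rb$eigen$values, ra$eigen$values, tolerance = 1e-9)
  expect_vectors_match(rb$embedding, ra$embedding, tol = 1e-6)
})
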