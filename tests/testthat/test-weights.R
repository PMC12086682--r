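test_that("distance ECDF matches the exhaustive pairwise ECDF", {
  set.seed(21)
  x <- matrix(rnorm(200 * 2), 200, 2)
  e <- estimate_ecdf(x, P = 1000, seed = 21)
  expect_true(all(diff(e$sample) >= 0))
  oracle <- full_pair_ecdf(x)
  qs <- quantile(e$sample, c(0.1, 0.25, 0.5, 0.75, 0.9))
  expect_lt(max(abs(ecdf_evaluate(e, qs) - oracle(qs))), 0.06)
  # the sample median of an independent large draw sits near ECDF 0.5
  med <- median(as.vector(dist(matrix(rnorm(400), 200, 2))))
  expect_gt(ecdf_evaluate(e, med), 0.45)
  expect_lt(ecdf_evaluate(e, med), 0.55)

  same <- matrix(1, 5, 2)
  e0 <- estimate_ecdf(same, P = 50, seed = 1)
  expect_equal(ecdf_evaluate(e0, 0), 1)
  expect_equal(ecdf_evaluate(e, min(e$sample) - 1e-9), 0)
  expect_error(estimate_ecdf(matrix(1, 1, 2), P = 10), "insufficient")
})

test_that("modality scores match a brute-force evaluation on a toy instance", {
  set.seed(5)
  emb <- list(matrix(rnorm(10), 5, 2), matrix(rnorm(10), 5, 2))
  k <- 2L
  nbh <- modality_neighborhoods(emb, k)
  ecdfs <- lapply(emb, estimate_ecdf, P = 400, seed = 9)
  s <- score_modalities(emb, nbh, ecdfs)

  for (c in 1:5) {
    for (m in 1:2) {
      l <- 3 - m
      nb <- brute_knn(emb[[l]], k)$idx[c, ]
      d <- sqrt(colSums((t(emb[[m]][nb, , drop = FALSE]) - emb[[m]][c, ])^2))
      expect_equal(s[c, m], median(ecdf_evaluate(ecdfs[[m]], d)),
                   tolerance = 1e-12)
    }
  }
  expect_error(score_modalities(emb[1], nbh[1], ecdfs[1]), "at least 2")
})

test_that("two identical modalities score and weigh symmetrically", {
  set.seed(6)
  x <- matrix(rnorm(60), 20, 3)
  w <- compute_weights(list(a = x, b = x), k = 4, P = 200, seed = 3)
  expect_equal(unname(w[, 1]), rep(0.5, 20), tolerance = 1e-12)
  expect_equal(unname(rowSums(w)), rep(1, 20), tolerance = 1e-12)
})

test_that("score smoothing averages over the dominant modality neighborhood", {
  set.seed(7)
  emb <- list(matrix(rnorm(12), 6, 2), matrix(rnorm(12), 6, 2))
  nbh <- modality_neighborhoods(emb, 2)
  s <- matrix(runif(12), 6, 2)
  sm <- smooth_scores(s, nbh)
  for (c in 1:6) {
    mstar <- which.max(s[c, ])
    rows <- c(c, nbh[[mstar]]$idx[c, ])
    expect_equal(sm[c, ], colMeans(s[rows, , drop = FALSE]), tolerance = 1e-12)
  }
  # equal rows are a fixed point
  su <- matrix(rep(c(0.3, 0.7), each = 6), 6, 2)
  expect_equal(smooth_scores(su, nbh), su, tolerance = 1e-15)
})

test_that("softmax normalization reproduces closed-form weights", {
  w <- softmax_weights(matrix(c(0.2, 0.1), 1, 2), alpha = 10)
  expect_equal(as.vector(w), c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  w3 <- softmax_weights(matrix(1, 4, 3), alpha = 10)
  expect_equal(unname(as.matrix(w3)), matrix(1 / 3, 4, 3), tolerance = 1e-15,
               ignore_attr = TRUE)
  wsat <- softmax_weights(matrix(c(1, 0.5), 1, 2), alpha = 1000)
  expect_gt(wsat[1, 1], 1 - 1e-12)
  expect_error(softmax_weights(matrix(1, 2, 2), alpha = 0.5), "alpha")
})

test_that("weights are equivariant under modality permutation and scale", {
  emb <- random_modalities(40, dims = c(3, 2, 4), seed = 8)
  w <- compute_weights(emb, k = 5, P = 300, seed = 12)
  wp <- compute_weights(emb[c(2, 3, 1)], k = 5, P = 300, seed = 12)
  expect_equal(unname(as.matrix(wp)), unname(as.matrix(w))[, c(2, 3, 1)],
               tolerance = 1e-12, ignore_attr = TRUE)
  # positive rescaling of one modality leaves the rank-based scores unchanged
  emb2 <- emb
  emb2[[2]] <- emb2[[2]] * 37.5
  ws <- compute_weights(emb2, k = 5, P = 300, seed = 12)
  expect_equal(unname(as.matrix(ws)), unname(as.matrix(w)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("weights favor the structured modality over replicated noise", {
  sim <- make_binary_tree(seed = 13, n_per_type = 150, oversample = 3)
  set.seed(14)
  noise <- matrix(rnorm(nrow(sim$modalities[[1]]) * 3), ncol = 3)
  w <- compute_weights(list(signal = sim$modalities[[1]], noise = noise),
                       k = 20, P = 1000, seed = 14)
  ab <- sim$type %in% c("A", "B")
  expect_gt(mean(w[ab, "signal"]), 0.5)
})
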