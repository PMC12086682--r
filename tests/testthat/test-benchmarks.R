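test_that("cohesiveness score reproduces its closed forms", {
  # one connected component with all psi = 0: Psi = 1, Phi = 0
  set.seed(71)
  emb <- matrix(rnorm(80, sd = 0.1), 40, 2)
  res <- cohesiveness_score(emb, rep(0, 40), top_fraction = 0.2, eps = 100)
  expect_equal(length(res$component_scores), 1L)
  expect_equal(res$phi, 0)

  # two far-apart zero-activity clusters among low-activity filler:
  # Phi = -log(2)
  cl <- rbind(matrix(rnorm(8, sd = 0.01), 4, 2),
              matrix(rnorm(8, sd = 0.01), 4, 2) + 100)
  filler <- matrix(rnorm(64, sd = 0.01), 32, 2) - 100
  emb2 <- rbind(cl, filler)
  act <- c(rep(0, 8), rep(-1, 32))
  res2 <- cohesiveness_score(emb2, act, top_fraction = 0.2, eps = 1)
  expect_equal(length(res2$component_scores), 2L)
  expect_equal(res2$phi, -log(2), tolerance = 1e-12)

  # hand-computed two-cluster instance with nonzero activities
  emb3 <- matrix(c(0, 0.1, 0.2, 5, 5.1, 5.2, rep(0, 6)), 6, 2)
  act3 <- c(3, 2, 1, 3, 2, 1)
  res3 <- cohesiveness_score(emb3, act3, top_fraction = 0.99, n_psi = 2,
                             eps = 0.5)
  psi_by_cell <- c(mean(act3[c(2, 3)]), mean(act3[c(1, 3)]),
                   mean(act3[c(2, 1)]), mean(act3[c(5, 6)]),
                   mean(act3[c(4, 6)]), mean(act3[c(5, 4)]))
  phi_hand <- -log(exp(-sum(psi_by_cell[1:3])) + exp(-sum(psi_by_cell[4:6])))
  expect_equal(res3$phi, phi_hand, tolerance = 1e-12)
  expect_error(cohesiveness_score(emb3, act3, top_fraction = 0.01),
               "insufficient")
})

test_that("phi decreases as equal-activity cells fragment into more
           components", {
  mk <- function(k) {
    centers <- 100 * seq_len(k)
    emb <- do.call(rbind, lapply(centers, function(cc)
      matrix(rnorm(8, sd = 0.01), 4, 2) + cc))
    cohesiveness_score(emb, rep(0, 4 * k), top_fraction = 0.99, eps = 1)$phi
  }
  phis <- vapply(1:4, mk, numeric(1))
  expect_equal(phis, -log(1:4), tolerance = 1e-12)
  expect_true(all(diff(phis) < 0))
})

test_that("vector-field alignment matches hand trigonometry", {
  emb <- matrix(c(0, 1, 0, 0, 0, 1), 3, 2)  # cells at (0,0), (1,0), (0,1)
  tr <- Matrix::sparseMatrix(i = c(1, 1), j = c(2, 3), x = c(0.9, 0.1),
                             dims = c(3, 3))
  # direction straight at the top-probability target
  dirs <- matrix(c(1, 0, 0, 0, 0, 0), 3, 2)
  expect_equal(vector_field_score(emb, dirs, tr, n_top = 1)$score, 1)
  # direction exactly away from it
  expect_equal(vector_field_score(emb, -dirs, tr, n_top = 1)$score, -1)
  # with both targets, the cell score is the median of cos(0) and cos(90)
  res <- vector_field_score(emb, dirs, tr, n_top = 3)
  expect_equal(res$per_cell[1], median(c(1, 0)))

  # 10-cell toy against direct evaluation
  set.seed(72)
  emb10 <- matrix(rnorm(20), 10, 2)
  dirs10 <- matrix(rnorm(20), 10, 2)
  tr10 <- Matrix::rsparsematrix(10, 10, 0.3, rand.x = runif)
  tr10@x <- abs(tr10@x)
  Matrix::diag(tr10) <- 0
  res10 <- vector_field_score(emb10, dirs10, tr10, n_top = 3)
  trd <- as.matrix(tr10)
  for (c in 1:10) {
    pos <- which(trd[c, ] > 0)
    if (!length(pos)) { expect_true(is.na(res10$per_cell[c])); next }
    top <- pos[order(-trd[c, pos], pos)][seq_len(min(3, length(pos)))]
    sims <- vapply(top, function(tg) {
      v <- emb10[tg, ] - emb10[c, ]
      sum(v * dirs10[c, ]) / sqrt(sum(v^2) * sum(dirs10[c, ]^2))
    }, numeric(1))
    expect_equal(res10$per_cell[c], median(sims), tolerance = 1e-12)
  }
  expect_equal(res10$score, median(res10$per_cell, na.rm = TRUE))

  dirs0 <- dirs10
  dirs0[which(rowSums(trd) > 0)[1], ] <- 0
  expect_warning(vector_field_score(emb10, dirs0, tr10), "zero direction")
})

test_that("terminal-state separation reproduces its extreme and symmetric
           cases", {
  # perfectly separated absorption: score 1 everywhere
  emb <- matrix(c(seq(0, 1, length.out = 50),
                  seq(9, 10, length.out = 50), rep(0, 100)), 100, 2)
  ab <- cbind(t1 = rep(c(1, 0), each = 50), t2 = rep(c(0, 1), each = 50))
  sc <- terminal_separation_score(emb, ab, n = c(10, 40))
  expect_equal(unname(sc), matrix(1, 2, 2))

  # indistinguishable absorption: score 0
  ab05 <- matrix(0.5, 100, 2)
  expect_warning(
    sc0 <- terminal_separation_score(emb, ab05, n = 20),
    "coincide")
  expect_equal(unname(sc0), matrix(0, 1, 2))

  # 4-state toy against direct evaluation
  set.seed(73)
  emb4 <- matrix(rnorm(80), 40, 2)
  ab4 <- matrix(runif(160), 40, 4)
  ab4 <- ab4 / rowSums(ab4)
  n <- 7L
  sc4 <- terminal_separation_score(emb4, ab4, n = n, location_fraction = 0.1)
  for (t in 1:4) {
    loc <- colMeans(emb4[order(ab4[, t], decreasing = TRUE)[1:4], ])
    nb <- order(sqrt(colSums((t(emb4) - loc)^2)))[1:n]
    ap_tt <- mean(ab4[nb, t])
    # own-neighborhood terms toward the other states
    others <- vapply(setdiff(1:4, t), function(t0) {
      loc0 <- colMeans(emb4[order(ab4[, t0], decreasing = TRUE)[1:4], ])
      nb0 <- order(sqrt(colSums((t(emb4) - loc0)^2)))[1:n]
      mean(ab4[nb0, t])
    }, numeric(1))
    expect_equal(unname(sc4[1, t]), ap_tt - sum(others), tolerance = 1e-12)
  }
  # boundedness
  expect_true(all(sc4 >= -3 & sc4 <= 1))
})

test_that("correlation structure score separates block from flat matrices", {
  labels <- rep(c("x", "y"), each = 3)
  block <- outer(labels, labels, `==`) * 1
  expect_equal(celltype_correlation_score(block, labels), 1)
  expect_equal(celltype_correlation_score(matrix(0.7, 6, 6), labels), 0)
  # direct evaluation on a random symmetric toy
  set.seed(74)
  m <- matrix(runif(36), 6, 6)
  m <- (m + t(m)) / 2
  same <- outer(labels, labels, `==`); diag(same) <- NA
  hand <- mean(m[which(same)]) - mean(m[which(!same)])
  expect_equal(celltype_correlation_score(m, labels), hand)
  expect_warning(celltype_correlation_score(m, c(labels[1:5], "solo")),
                 "size 1")
})

test_that("count downsampling removes the exact fraction and thins uniformly", {
  set.seed(75)
  counts <- matrix(rpois(200, 4), 20, 10)
  expect_identical(downsample_counts(counts, 0), counts)
  for (p in c(0.1, 0.5, 0.8)) {
    thinned <- downsample_counts(counts, p, seed = 75)
    expect_equal(sum(thinned), sum(counts) - round(p * sum(counts)))
    expect_true(all(thinned >= 0) && all(thinned <= counts))
  }
  # per-entry expectation ~ (1 - p) * original
  tot <- matrix(0, 20, 10)
  for (s in 1:300) tot <- tot + downsample_counts(counts, 0.4, seed = s)
  expect_equal(mean(abs(tot / 300 - 0.6 * counts)), 0, tolerance = 0.15)

  sp <- Matrix::Matrix(counts, sparse = TRUE)
  thsp <- downsample_counts(sp, 0.3, seed = 2)
  expect_s4_class(thsp, "sparseMatrix")
  expect_equal(sum(thsp), sum(counts) - round(0.3 * sum(counts)))
})

test_that("mse matches its definition", {
  expect_equal(mse(c(1, 2), c(1, 2)), 0)
  expect_equal(mse(c(0, 0), c(1, 1)), 1)
  set.seed(76)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(mse(x, y), sum((x - y)^2) / 10)
  expect_error(mse(x, y[1:5]), "dimension error")
})
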