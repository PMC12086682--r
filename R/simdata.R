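# Simulated developmental multimodal datasets.
#
# Geometry conventions (fixed, overridable via arguments where exposed):
# Gaussian branches are mixtures of unit-spaced isotropic Gaussian centers
# (sd 0.5, i.e. covariance 0.25 I) laid along a direction for 4 length units;
# blobs are single isotropic Gaussians (sd 0.5). Types not separated by a
# modality sit at a common blob placed at their lineage's junction point so
# trajectories stay connected across modalities.

sample_branch <- function(n, from, dir, len = 4, sd = 0.5) {
  dir <- dir / sqrt(sum(dir^2))
  centers <- outer(0:len, dir) + matrix(from, len + 1L, 3L, byrow = TRUE)
  pick <- sample.int(len + 1L, n, replace = TRUE)
  pts <- centers[pick, , drop = FALSE] +
    matrix(rnorm(3L * n, sd = sd), n, 3L)
  list(points = pts,
       progress = as.vector((pts - matrix(from, n, 3L, byrow = TRUE)) %*% dir))
}

sample_blob <- function(n, center, sd = 0.5) {
  matrix(center, n, 3L, byrow = TRUE) + matrix(rnorm(3L * n, sd = sd), n, 3L)
}

sample_segment <- function(n, from, to) {
  tt <- runif(n)
  pts <- matrix(from, n, 3L, byrow = TRUE) + outer(tt, to - from)
  list(points = pts, progress = tt * sqrt(sum((to - from)^2)))
}

#' Density-based downsampling
#'
#' Retains `target_n` points, sampled without replacement with probability
#' proportional to the cubed distance from each point to its `nn_index`-th
#' nearest neighbor. Points in sparse regions are preferentially retained,
#' flattening density so downstream kNN structure is stable along
#' trajectories.
#'
#' @param points Coordinate matrix.
#' @param target_n Number of points to keep.
#' @param nn_index Which neighbor's distance measures local density (25 by
#'   default).
#' @param seed Optional RNG seed.
#' @return Sorted integer indices of the retained points.
#' @export
density_downsample <- function(points, target_n, nn_index = 25L, seed = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (target_n > n) stop("target_n exceeds the number of points")
  if (nn_index >= n) stop("nn_index must be smaller than the number of points")
  if (!is.null(seed)) set.seed(seed)
  d <- exact_knn(points, nn_index)$dist[, nn_index]
  w <- d^3
  if (all(w == 0)) {
    warning("all neighbor distances are zero; falling back to uniform sampling")
    w <- rep(1, n)
  }
  sort(sample.int(n, target_n, replace = FALSE, prob = w))
}

finish_simulated <- function(modality_parts, types, pt_raw, modality_of_type,
                             seed, noise_block = 100L) {
  C <- length(types)
  pre <- rank(pt_raw, ties.method = "first") - 1L
  ord <- order(pre)
  noisy <- pre
  starts <- seq(1L, C, by = noise_block)
  for (a in starts) {
    b <- min(a + noise_block - 1L, C)
    cells <- ord[a:b]
    if (length(cells) > 1L) noisy[cells] <- pre[sample(cells)]
  }
  ids <- sprintf("cell%05d", seq_len(C))
  modalities <- lapply(modality_parts, function(m) {
    rownames(m) <- ids
    colnames(m) <- paste0("dim", 1:3)
    m
  })
  structure(list(modalities = modalities,
                 modality_names = names(modalities),
                 type = types, pseudotime = noisy, pseudotime_prenoise = pre,
                 cell_ids = ids, modality_of_type = modality_of_type,
                 seed = seed),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset:", length(x$cell_ids), "observations,",
      length(x$modalities), "modalities,",
      length(unique(x$type)), "types\n")
  invisible(x)
}

#' Convert a simulated dataset to a multimodal dataset
#' @param sim A `simulated_dataset`.
#' @return A [multimodal_dataset()] carrying type and pseudotime annotations.
#' @export
as_multimodal_dataset <- function(sim) {
  stopifnot(inherits(sim, "simulated_dataset"))
  multimodal_dataset(sim$modalities, cell_ids = sim$cell_ids,
                     obs = data.frame(type = sim$type,
                                      pseudotime = sim$pseudotime))
}

#' Simulated binary-tree developmental dataset
#'
#' Three modalities, 6000 observations in six types A-F (1000 per type after
#' density-based downsampling). Modality 1 introduces lineages A-B (two
#' Gaussian branches diverging from the root), modality 2 introduces C-D
#' (branching from the tip of A), and modality 3 introduces E-F (branching
#' from the tip of C). In modalities that do not introduce a type, its
#' observations sit at a common Gaussian blob at the lineage junction, so
#' only the introducing modality separates the pair. Pseudotime ranks
#' observations by distance from the developmental root along their lineage;
#' noise shuffles every consecutive block of 100 ranks.
#'
#' @param seed RNG seed.
#' @param n_per_type Observations per type after downsampling (1000).
#' @param oversample Oversampling factor before downsampling.
#' @param nn_index Density neighbor for the downsampling law (25).
#' @return A `simulated_dataset`.
#' @export
make_binary_tree <- function(seed = 1L, n_per_type = 1000L, oversample = 3L,
                             nn_index = 25L) {
  set.seed(seed)
  types <- LETTERS[1:6]
  intro <- c(A = 1L, B = 1L, C = 2L, D = 2L, E = 3L, F = 3L)
  len <- 4
  up <- c(1, 1, 0) / sqrt(2)
  dn <- c(1, -1, 0) / sqrt(2)
  origin <- c(0, 0, 0)
  tipA <- len * up   # junction where C,D branch (in modality 2 coordinates)
  tipC <- len * up   # junction where E,F branch (in modality 3 coordinates)
  branch_dirs <- list(A = up, B = dn, C = up, D = dn, E = up, F = dn)
  offsets <- c(A = 0, B = 0, C = len, D = len, E = 2 * len, F = 2 * len)
  n_raw <- oversample * n_per_type
  mod_parts <- list(matrix(0, 0, 3), matrix(0, 0, 3), matrix(0, 0, 3))
  all_types <- character(); pt <- numeric()
  for (ty in types) {
    m_intro <- intro[[ty]]
    br <- sample_branch(n_raw, origin, branch_dirs[[ty]], len = len)
    other <- vector("list", 3L)
    for (m in 1:3) {
      if (m == m_intro) { other[[m]] <- br$points; next }
      center <- if (m < m_intro) {
        # a modality that already branched earlier: this type sits past its
        # junction, at the tip of the earlier lineage
        if (m == 1L) tipA else tipC
      } else origin  # not yet branched here: still at the root blob
      other[[m]] <- sample_blob(n_raw, center)
    }
    keep <- density_downsample(other[[m_intro]], n_per_type,
                               nn_index = nn_index)
    for (m in 1:3)
      mod_parts[[m]] <- rbind(mod_parts[[m]], other[[m]][keep, , drop = FALSE])
    all_types <- c(all_types, rep(ty, n_per_type))
    pt <- c(pt, offsets[[ty]] + br$progress[keep])
  }
  names(mod_parts) <- paste0("modality", 1:3)
  finish_simulated(mod_parts, all_types, pt, intro, seed)
}

#' Simulated rare-transitions developmental dataset
#'
#' Two modalities, 4500 observations in nine types A-I (500 per type).
#' Modality 1 introduces the transient lineage A-B-C as three unit-length 3D
#' segments laid head-to-tail and sampled uniformly; modality 2 introduces
#' lineages D-I as six Gaussian branches radiating from the A-C terminus,
#' downsampled by local density as in the binary tree. In modality 2 the A-C
#' observations sit at a common blob at the branch root; in modality 1 the
#' D-I observations sit at a blob at the segment terminus.
#'
#' @inheritParams make_binary_tree
#' @param n_per_type Observations per type after downsampling (500).
#' @return A `simulated_dataset`.
#' @export
make_rare_transitions <- function(seed = 1L, n_per_type = 500L,
                                  oversample = 3L, nn_index = 25L) {
  set.seed(seed)
  types <- LETTERS[1:9]
  intro <- setNames(c(rep(1L, 3L), rep(2L, 6L)), types)
  segs <- list(A = list(c(0, 0, 0), c(1, 0, 0)),
               B = list(c(1, 0, 0), c(1, 1, 0)),
               C = list(c(1, 1, 0), c(1, 1, 1)))
  terminus <- c(1, 1, 1)
  dirs <- list(D = c(1, 0, 0), E = c(-1, 0, 0), F = c(0, 1, 0),
               G = c(0, -1, 0), H = c(0, 0, 1), I = c(0, 0, -1))
  len <- 4
  mod_parts <- list(matrix(0, 0, 3), matrix(0, 0, 3))
  all_types <- character(); pt <- numeric()
  for (ty in types[1:3]) {
    sg <- sample_segment(n_per_type, segs[[ty]][[1L]], segs[[ty]][[2L]])
    mod_parts[[1L]] <- rbind(mod_parts[[1L]], sg$points)
    mod_parts[[2L]] <- rbind(mod_parts[[2L]],
                             sample_blob(n_per_type, c(0, 0, 0)))
    all_types <- c(all_types, rep(ty, n_per_type))
    pt <- c(pt, match(ty, types) - 1 + sg$progress)
  }
  n_raw <- oversample * n_per_type
  for (ty in types[4:9]) {
    br <- sample_branch(n_raw, c(0, 0, 0), dirs[[ty]], len = len)
    keep <- density_downsample(br$points, n_per_type, nn_index = nn_index)
    mod_parts[[1L]] <- rbind(mod_parts[[1L]],
                             sample_blob(n_per_type, terminus))
    mod_parts[[2L]] <- rbind(mod_parts[[2L]], br$points[keep, , drop = FALSE])
    all_types <- c(all_types, rep(ty, n_per_type))
    pt <- c(pt, 3 + br$progress[keep])
  }
  names(mod_parts) <- paste0("modality", 1:2)
  finish_simulated(mod_parts, all_types, pt, intro, seed)
}

#' Ground-truth modality weights of a simulated dataset
#'
#' One-hot rows: weight 1 on the modality that introduces the observation's
#' lineage, 0 elsewhere.
#'
#' @param sim A `simulated_dataset`.
#' @return Cell-by-modality 0/1 matrix.
#' @export
target_weights <- function(sim) {
  stopifnot(inherits(sim, "simulated_dataset"))
  m <- sim$modality_of_type[sim$type]
  if (any(is.na(m))) stop("unknown type label in the dataset")
  M <- length(sim$modalities)
  w <- matrix(0, length(sim$type), M,
              dimnames = list(sim$cell_ids, names(sim$modalities)))
  w[cbind(seq_along(m), m)] <- 1
  w
}

#' Mean squared error between computed and target weights
#' @param weights Cell-by-modality weight matrix.
#' @param targets Matrix of the same shape.
#' @return Mean of squared elementwise differences.
#' @export
weight_mse <- function(weights, targets) {
  if (!all(dim(weights) == dim(targets)))
    stop("dimension error: weights and targets differ in shape")
  mean((as.matrix(weights) - as.matrix(targets))^2)
}
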