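# Embedding-quality and imputation benchmarks. All scorers are pure
# functions of their inputs; externally computed quantities (absorption
# probabilities, velocity directions, signature activities) are inputs,
# never recomputed here.

#' Signature cohesiveness score of an embedding
#'
#' Evaluates whether the cells most active for a signature (a gene set's mean
#' z-score or a motif variability score) occupy one cohesive region. The top
#' `top_fraction` of cells by activity are selected; each selected cell gets
#' `psi = mean activity over its n_psi nearest embedding neighbors` (searched
#' among all cells, self excluded); the selected cells are linked whenever
#' within `eps` of each other and split into connected components; a
#' component scores `Psi_G = exp(-sum psi)` and the embedding scores
#' `Phi = -log(sum_G Psi_G)`. Fragmentation into several components lowers
#' `Phi`; higher is better.
#'
#' @param embedding Cell-by-dimension coordinate matrix.
#' @param activity Per-cell signature activity vector.
#' @param top_fraction Fraction of cells selected (0.05).
#' @param n_psi Neighbors averaged for `psi` (3).
#' @param eps Connectivity radius; `NULL` estimates it as the median distance
#'   over `n_pairs` random cell pairs.
#' @param n_pairs Pair-sample size for the `eps` estimate (1000).
#' @param seed RNG seed for the pair sample.
#' @return List of class `cohesiveness_result`: `phi`, `component_scores`
#'   (Psi_G per component), `components` (membership), `psi`, `selected`,
#'   `eps`.
#' @export
cohesiveness_score <- function(embedding, activity, top_fraction = 0.05,
                               n_psi = 3L, eps = NULL, n_pairs = 1000L,
                               seed = NULL) {
  embedding <- as.matrix(embedding)
  C <- nrow(embedding)
  if (length(activity) != C) stop("activity must have one value per cell")
  if (top_fraction <= 0 || top_fraction >= 1)
    stop("top_fraction must lie in (0, 1)")
  n_sel <- ceiling(top_fraction * C)
  if (n_sel < 2L)
    stop("insufficient data: fewer than 2 cells selected")
  sel <- order(activity, decreasing = TRUE)[seq_len(n_sel)]
  nn <- exact_knn(embedding, n_psi)
  psi <- rowMeans(matrix(activity[nn$idx[sel, , drop = FALSE]],
                         n_sel, n_psi))
  if (is.null(eps)) {
    e <- estimate_ecdf(embedding, P = n_pairs, seed = seed)
    eps <- median(e$sample)
  }
  d <- as.matrix(dist(embedding[sel, , drop = FALSE]))
  adj <- d <= eps
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  psi_g <- vapply(split(psi, comp), function(p) exp(-sum(p)), numeric(1L))
  phi <- -log(sum(psi_g))
  structure(list(phi = phi, component_scores = psi_g, components = comp,
                 psi = psi, selected = sel, eps = eps),
            class = "cohesiveness_result")
}

#' Velocity vector-field alignment score of an embedding
#'
#' Scores each cell as the median cosine similarity between its projected
#' developmental direction and the vectors pointing from the cell to its
#' `n_top` highest-transition-probability targets; the embedding score is the
#' median over cells that have at least one positive transition. Cells with a
#' zero direction vector are skipped with a warning.
#'
#' @param embedding 2D or 3D coordinate matrix.
#' @param directions Per-cell projected direction vectors (same dimensions).
#' @param transitions A [transition_matrix()] or sparse matrix.
#' @param n_top Transition targets per cell (3).
#' @return List with `score` (embedding median) and `per_cell` (NA for cells
#'   without transitions or direction).
#' @export
vector_field_score <- function(embedding, directions, transitions,
                               n_top = 3L) {
  embedding <- as.matrix(embedding)
  directions <- as.matrix(directions)
  C <- nrow(embedding)
  if (!all(dim(directions) == dim(embedding)))
    stop("directions are not aligned with the embedding")
  probs <- if (inherits(transitions, "transition_matrix"))
    transitions$probs else as_dgc(transitions)
  if (nrow(probs) != C) stop("transitions are not aligned to the cell order")
  tp <- as(probs, "TsparseMatrix")
  pos <- tp@x > 0
  prow <- split(data.frame(j = tp@j[pos] + 1L, x = tp@x[pos]), tp@i[pos] + 1L)
  per_cell <- rep(NA_real_, C)
  skipped <- 0L
  for (cs in names(prow)) {
    c <- as.integer(cs)
    dir <- directions[c, ]
    nrm <- sqrt(sum(dir^2))
    if (nrm == 0) { skipped <- skipped + 1L; next }
    pr <- prow[[cs]]
    o <- order(-pr$x, pr$j)
    targets <- pr$j[o][seq_len(min(n_top, length(pr$j)))]
    sims <- vapply(targets, function(tg) {
      v <- embedding[tg, ] - embedding[c, ]
      vn <- sqrt(sum(v^2))
      if (vn == 0) return(NA_real_)
      sum(v * dir) / (vn * nrm)
    }, numeric(1L))
    per_cell[c] <- median(sims, na.rm = TRUE)
  }
  if (skipped > 0L)
    warning(skipped, " cell(s) with a zero direction vector were skipped")
  list(score = median(per_cell, na.rm = TRUE), per_cell = per_cell)
}

#' Terminal-state separation score of an embedding
#'
#' Each terminal state's location is the mean coordinate of the
#' `location_fraction` of cells with its highest absorption probabilities.
#' `ap(n, t1, t2)` is the mean absorption probability toward `t1` over the
#' `n` embedding-nearest neighbors of `t2`'s location, and the state's score
#' is `ap(n, t, t) - sum_{t0 != t} ap(n, t, t0)`: high when a terminal
#' state's own absorption dominates its neighborhood and competing states'
#' absorption there is low.
#'
#' @param embedding Coordinate matrix.
#' @param absorption Cell-by-terminal-state matrix of absorption
#'   probabilities in `[0, 1]` with terminal-state column names.
#' @param n Vector of neighborhood sizes (each `< C`).
#' @param location_fraction Fraction of top cells that define a terminal
#'   state's location (0.01).
#' @return Matrix of scores, `length(n)` rows x one column per terminal state.
#' @export
terminal_separation_score <- function(embedding, absorption, n,
                                      location_fraction = 0.01) {
  embedding <- as.matrix(embedding)
  absorption <- as.matrix(absorption)
  C <- nrow(embedding)
  Tn <- ncol(absorption)
  if (Tn < 2L) stop("need at least 2 terminal states")
  if (nrow(absorption) != C)
    stop("absorption table is not aligned to the cell order")
  if (any(n >= C)) stop("every n must be smaller than the cell count")
  n_loc <- max(1L, ceiling(location_fraction * C))
  locs <- t(vapply(seq_len(Tn), function(t) {
    top <- order(absorption[, t], decreasing = TRUE)[seq_len(n_loc)]
    colMeans(embedding[top, , drop = FALSE])
  }, numeric(ncol(embedding))))
  if (anyDuplicated(round(locs, 12)))
    warning("some terminal-state locations coincide")
  # rank all cells by distance to each terminal location once
  ord <- lapply(seq_len(Tn), function(t) {
    d <- sqrt(colSums((t(embedding) - locs[t, ])^2))
    order(d)
  })
  scores <- matrix(0, length(n), Tn,
                   dimnames = list(as.character(n),
                                   colnames(absorption) %||%
                                     paste0("terminal", seq_len(Tn))))
  for (ni in seq_along(n)) {
    ap <- matrix(0, Tn, Tn)  # ap[t1, t2]: absorption of t1 near t2
    for (t2 in seq_len(Tn)) {
      nbrs <- ord[[t2]][seq_len(n[ni])]
      ap[, t2] <- colMeans(absorption[nbrs, , drop = FALSE])
    }
    scores[ni, ] <- vapply(seq_len(Tn),
                           function(t) ap[t, t] - sum(ap[t, -t]), numeric(1L))
  }
  scores
}

#' Mean squared error between two vectors
#' @param x,y Numeric vectors of equal length.
#' @return `mean((x - y)^2)`.
#' @export
mse <- function(x, y) {
  if (length(x) != length(y)) stop("dimension error: lengths differ")
  mean((x - y)^2)
}

#' Cell-type structure score of a cell-cell correlation matrix
#'
#' Mean correlation over same-type cell pairs (off-diagonal) minus the mean
#' correlation over different-type pairs. A correlation matrix with clear
#' cell-type block structure scores high.
#'
#' @param correlations Square cell-by-cell correlation matrix.
#' @param labels Per-cell type labels.
#' @return A single numeric score.
#' @export
celltype_correlation_score <- function(correlations, labels) {
  correlations <- as.matrix(correlations)
  C <- nrow(correlations)
  if (ncol(correlations) != C) stop("correlation matrix must be square")
  if (length(labels) != C) stop("labels are not aligned to the matrix")
  singles <- names(which(table(labels) == 1L))
  if (length(singles))
    warning("label class(es) of size 1 contribute no same-type pairs: ",
            paste(singles, collapse = ", "))
  same <- outer(labels, labels, `==`)
  diag(same) <- NA
  off <- !is.na(same)
  same_mean <- mean(correlations[off & same])
  diff_mean <- mean(correlations[off & !same])
  same_mean - diff_mean
}

#' Randomly remove a fraction of counts (multinomial thinning)
#'
#' Removes exactly `round(p * total)` individual count units uniformly at
#' random from the matrix, emulating reduced sequencing depth; entries stay
#' nonnegative and the grand total is conserved at `round((1 - p) * total)`.
#'
#' @param counts Integer count matrix (dense or sparse).
#' @param p Fraction of counts to remove, in `[0, 1)`.
#' @param seed Optional RNG seed.
#' @return Thinned matrix, same class layout (sparse stays sparse).
#' @export
downsample_counts <- function(counts, p, seed = NULL) {
  if (p < 0 || p >= 1) stop("p must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  sparse <- is(counts, "sparseMatrix")
  x <- if (sparse) counts@x else as.vector(counts)
  if (any(x != round(x)) || any(x < 0)) stop("counts must be nonnegative integers")
  total <- sum(x)
  n_remove <- round(p * total)
  if (n_remove == 0L) return(counts)
  cs <- cumsum(x)
  units <- sample(total, n_remove)
  hit <- findInterval(units - 1L, cs) + 1L  # unit u lies in entry j: cs[j-1] < u <= cs[j]
  removed <- tabulate(hit, nbins = length(x))
  out <- counts
  if (sparse) {
    out@x <- x - removed
    out <- Matrix::drop0(out)
  } else {
    out[] <- x - removed
  }
  out
}
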