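# Latent Dirichlet allocation by batch variational Bayes.
#
# Each cell is modeled as a multinomial mixture of topics; each topic is a
# distribution over features. The fit follows the standard mean-field scheme:
# the E-step optimizes per-cell topic posteriors (gamma) with the fixed-point
# update vectorized across all cells through sparse matrix products, and the
# M-step updates the topic-feature variational parameters (lambda). Priors
# default to 1/n_topics, the common single-cell choice.

#' Fit a topic model to a count matrix
#'
#' @param counts Cell-by-feature nonnegative count matrix (dense or sparse).
#' @param n_topics Number of topics T (>= 2).
#' @param n_iterations Variational EM iterations (default 30).
#' @param seed RNG seed for the topic-feature initialization; fits are
#'   deterministic for a fixed seed.
#' @param doc_topic_prior,topic_feature_prior Dirichlet priors; default
#'   `1/n_topics`.
#' @param inner_iterations Maximum fixed-point iterations per E-step.
#' @param inner_tol Mean absolute gamma change that stops the E-step early.
#' @return Object of class `topic_model` with `cell_topic` (C x T, rows sum
#'   to 1), `topic_feature` (T x F, rows sum to 1), `n_topics`,
#'   `n_iterations`, `seed`.
#' @export
fit_topics <- function(counts, n_topics, n_iterations = 30L, seed = NULL,
                       doc_topic_prior = 1 / n_topics,
                       topic_feature_prior = 1 / n_topics,
                       inner_iterations = 60L, inner_tol = 1e-4) {
  if (n_topics < 2L) stop("n_topics must be at least 2")
  x <- as_dgc(counts)
  if (length(x@x) && min(x@x) < 0) stop("counts must be nonnegative")
  zero <- Matrix::rowSums(x) == 0
  if (any(zero)) {
    ids <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
    stop("all-zero cells have no valid multinomial: ",
         paste(ids[zero], collapse = ", "))
  }
  C <- nrow(x); F_ <- ncol(x); T_ <- n_topics
  xt <- as(x, "TsparseMatrix")
  i_idx <- xt@i + 1L
  j_idx <- xt@j + 1L
  v <- xt@x
  seed <- seed %||% sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  lambda <- matrix(rgamma(T_ * F_, 100, 100), T_, F_)
  exp_dirichlet <- function(a) exp(digamma(a) - digamma(rowSums(a)))
  for (it in seq_len(n_iterations)) {
    eb <- exp_dirichlet(lambda)           # T x F
    gamma <- matrix(1, C, T_)
    et <- exp_dirichlet(gamma)            # C x T
    ebt <- t(eb)                          # F x T
    for (inner in seq_len(inner_iterations)) {
      phinorm <- rowSums(et[i_idx, , drop = FALSE] *
                         ebt[j_idx, , drop = FALSE]) + 1e-100
      r <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = v / phinorm,
                                dims = c(C, F_))
      gamma_new <- doc_topic_prior + et * as.matrix(r %*% ebt)
      change <- mean(abs(gamma_new - gamma))
      gamma <- gamma_new
      et <- exp_dirichlet(gamma)
      if (change < inner_tol) break
    }
    phinorm <- rowSums(et[i_idx, , drop = FALSE] *
                       ebt[j_idx, , drop = FALSE]) + 1e-100
    r <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = v / phinorm,
                              dims = c(C, F_))
    sstats <- as.matrix(Matrix::crossprod(r, et))  # F x T
    lambda <- topic_feature_prior + t(sstats) * eb
  }
  cell_topic <- gamma / rowSums(gamma)
  topic_feature <- lambda / rowSums(lambda)
  rownames(cell_topic) <- rownames(counts)
  colnames(topic_feature) <- colnames(counts)
  structure(list(cell_topic = cell_topic, topic_feature = topic_feature,
                 n_topics = as.integer(n_topics),
                 n_iterations = as.integer(n_iterations), seed = seed),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat("topic_model:", nrow(x$cell_topic), "cells,", x$n_topics, "topics,",
      ncol(x$topic_feature), "features\n")
  invisible(x)
}

#' Build topic-based latent modalities from a unimodal count matrix
#'
#' Assigns every feature to its most probable topic (argmax over the
#' topic-feature distribution; ties break toward the lower topic index),
#' optionally truncates each group to its top features, and emits one latent
#' modality (a cell-by-feature count submatrix) per nonempty group. The
#' cell-topic proportions, restricted to the retained topics and renormalized
#' per cell, are returned as a ready-made weight source for the multimodal
#' workflow.
#'
#' @param model A fitted `topic_model`.
#' @param counts The count matrix the model was fitted on.
#' @param top_rule `"above_uniform"` keeps features whose within-topic
#'   probability exceeds the uniform level `1/F` (default); `"top_k"` keeps
#'   the `top_k` highest-probability features per topic; `"all"` keeps every
#'   feature.
#' @param top_k Per-topic feature count for `top_rule = "top_k"`.
#' @return Object of class `latent_modality_set`: `feature_groups` (disjoint
#'   feature-index lists per retained topic), `matrices` (per-topic
#'   submatrices), `weights_source` (renormalized cell-topic columns),
#'   `retained_topics`.
#' @export
build_latent_modalities <- function(model, counts,
                                    top_rule = c("above_uniform", "top_k",
                                                 "all"),
                                    top_k = NULL) {
  top_rule <- match.arg(top_rule)
  stopifnot(inherits(model, "topic_model"))
  tf <- model$topic_feature
  F_ <- ncol(tf)
  if (ncol(counts) != F_)
    stop("counts and topic model disagree on the feature set")
  assign <- max.col(t(tf), ties.method = "first")
  keep <- rep(TRUE, F_)
  if (top_rule == "above_uniform") {
    keep <- tf[cbind(assign, seq_len(F_))] > 1 / F_
  } else if (top_rule == "top_k") {
    if (is.null(top_k)) stop("top_k must be given for top_rule = \"top_k\"")
    keep <- rep(FALSE, F_)
    for (t in unique(assign)) {
      feats <- which(assign == t)
      o <- order(tf[t, feats], decreasing = TRUE)
      keep[feats[o][seq_len(min(top_k, length(feats)))]] <- TRUE
    }
  }
  if (!any(keep))
    stop("configuration error: the top-feature rule retains zero features")
  groups <- split(which(keep), assign[keep])
  retained <- as.integer(names(groups))
  matrices <- lapply(groups, function(f) counts[, f, drop = FALSE])
  names(matrices) <- paste0("topic", retained)
  ws <- model$cell_topic[, retained, drop = FALSE]
  ws <- ws / rowSums(ws)
  colnames(ws) <- names(matrices)
  structure(list(feature_groups = groups, matrices = matrices,
                 weights_source = ws, retained_topics = retained),
            class = "latent_modality_set")
}

#' Log-normalize a count matrix
#'
#' Scales each cell to a fixed total of `scale` counts and applies
#' `log(1 + x)` - the standard transformation applied to topic-based latent
#' modalities before computing diffusion kernels.
#'
#' @param counts Cell-by-feature count matrix.
#' @param scale Per-cell target total (10,000 by default).
#' @return Dense log-normalized matrix.
#' @export
log_normalize <- function(counts, scale = 1e4) {
  m <- as.matrix(counts)
  totals <- rowSums(m)
  totals[totals == 0] <- 1
  log1p(m / totals * scale)
}
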