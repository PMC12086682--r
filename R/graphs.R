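new_layout_graph <- function(source, target, rank, out_degree, variant,
                             cell_ids) {
  edges <- data.frame(source = source, target = target, rank = rank)
  structure(list(edges = edges, out_degree = as.integer(out_degree),
                 variant = variant, cell_ids = cell_ids),
            class = "layout_graph")
}

#' @export
print.layout_graph <- function(x, ...) {
  cat("layout_graph (", x$variant, "): ", nrow(x$edges), " edges, ",
      x$out_degree, " per node\n", sep = "")
  invisible(x)
}

#' Nearest-neighbor layout graph
#'
#' Connects every cell to its `out_degree` nearest neighbors in the MDM
#' latent space. Every node gets exactly `out_degree` outgoing edges; ties
#' break by distance then cell index.
#'
#' @param embedding Cell-by-dimension MDM coordinate matrix.
#' @param out_degree Edges per node (must be `< C`).
#' @return A `layout_graph` (directed edge list with per-source ranks).
#' @export
nn_graph <- function(embedding, out_degree) {
  embedding <- as.matrix(embedding)
  C <- nrow(embedding)
  if (out_degree >= C)
    stop("configuration error: out_degree must be smaller than the cell count")
  nn <- exact_knn(embedding, out_degree)
  new_layout_graph(source = rep(seq_len(C), each = out_degree),
                   target = as.vector(t(nn$idx)),
                   rank = rep(seq_len(out_degree), C),
                   out_degree = out_degree, variant = "nn",
                   cell_ids = rownames(embedding))
}

rank_candidates <- function(cand, dist, probs, out_degree) {
  o <- order(-probs, dist, cand)
  cand[o][seq_len(out_degree)]
}

#' Transitions-based layout graph
#'
#' For each cell, edges go to the `out_degree` cells with the highest
#' developmental transition probability among its `candidate_pool` MDM
#' nearest neighbors; any shortfall (zero-probability slots) is filled with
#' the closest not-yet-linked MDM neighbors. Cells whose transition row is
#' all zero get pure nearest-neighbor edges. Ties break by probability
#' descending, then distance ascending, then cell index.
#'
#' @param embedding MDM coordinate matrix.
#' @param transitions A [transition_matrix()] (or sparse matrix) aligned to
#'   the cell order.
#' @param out_degree Edges per node.
#' @param candidate_pool Size of the MDM neighborhood searched;
#'   `10 * out_degree` by default.
#' @return A `layout_graph`.
#' @export
transitions_graph <- function(embedding, transitions, out_degree,
                              candidate_pool = NULL) {
  embedding <- as.matrix(embedding)
  C <- nrow(embedding)
  if (out_degree >= C)
    stop("configuration error: out_degree must be smaller than the cell count")
  probs <- if (inherits(transitions, "transition_matrix"))
    transitions$probs else as_dgc(transitions)
  if (nrow(probs) != C) stop("transitions are not aligned to the cell order")
  pool <- min(candidate_pool %||% (10L * out_degree), C - 1L)
  pool <- max(pool, out_degree)
  nn <- exact_knn(embedding, pool)
  tp <- as(probs, "TsparseMatrix")
  prow <- split(data.frame(j = tp@j + 1L, x = tp@x), tp@i + 1L)
  src <- rep(seq_len(C), each = out_degree)
  tgt <- integer(C * out_degree)
  for (c in seq_len(C)) {
    cand <- nn$idx[c, ]
    dist <- nn$dist[c, ]
    pr <- prow[[as.character(c)]]
    pv <- numeric(pool)
    if (!is.null(pr) && any(pr$x > 0)) {
      mt <- match(cand, pr$j)
      pv[!is.na(mt)] <- pr$x[mt[!is.na(mt)]]
    }
    tgt[((c - 1L) * out_degree + 1L):(c * out_degree)] <-
      rank_candidates(cand, dist, pv, out_degree)
  }
  new_layout_graph(source = src, target = tgt,
                   rank = rep(seq_len(out_degree), C),
                   out_degree = out_degree, variant = "transitions",
                   cell_ids = rownames(embedding))
}

#' Timestamped transitions-based layout graph
#'
#' Like [transitions_graph()], but each cell's candidate neighbors are
#' restricted to cells from the subsequent timestamp; cells of the terminal
#' timestamp search within their own timestamp.
#'
#' @param embedding MDM coordinate matrix.
#' @param transitions A [transition_matrix()], sparse matrix, or `NULL` for
#'   pure nearest-neighbor ranking within the allowed timestamp.
#' @param timestamps Per-cell ordinal labels (numeric, ordered factor, or
#'   anything `sort(unique(.))` orders correctly).
#' @param out_degree Edges per node.
#' @param candidate_pool MDM neighborhood size searched per cell;
#'   `10 * out_degree` by default.
#' @return A `layout_graph`.
#' @export
timestamped_graph <- function(embedding, transitions, timestamps, out_degree,
                              candidate_pool = NULL) {
  embedding <- as.matrix(embedding)
  C <- nrow(embedding)
  if (length(timestamps) != C)
    stop("timestamps are not aligned to the cell order")
  levels <- sort(unique(timestamps))
  probs <- if (is.null(transitions)) {
    Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                         dims = c(C, C))
  } else if (inherits(transitions, "transition_matrix")) {
    transitions$probs
  } else as_dgc(transitions)
  pool_req <- candidate_pool %||% (10L * out_degree)
  tp <- as(probs, "TsparseMatrix")
  prow <- split(data.frame(j = tp@j + 1L, x = tp@x), tp@i + 1L)
  src <- rep(seq_len(C), each = out_degree)
  tgt <- integer(C * out_degree)
  for (ti in seq_along(levels)) {
    terminal <- ti == length(levels)
    sources <- which(timestamps == levels[ti])
    candidates <- if (terminal) sources
                  else which(timestamps == levels[ti + 1L])
    avail <- if (terminal) length(candidates) - 1L else length(candidates)
    if (avail < out_degree)
      stop("degree error: timestamp '", levels[ti],
           "' has only ", avail, " candidate cells for out_degree ",
           out_degree)
    kq <- min(max(pool_req, out_degree + 1L), length(candidates))
    nn <- RANN::nn2(embedding[candidates, , drop = FALSE],
                    query = embedding[sources, , drop = FALSE], k = kq)
    for (s in seq_along(sources)) {
      c <- sources[s]
      cand <- candidates[nn$nn.idx[s, ]]
      dist <- nn$nn.dists[s, ]
      keep <- cand != c
      cand <- cand[keep]
      dist <- dist[keep]
      o <- order(dist, cand)
      cand <- cand[o]
      dist <- dist[o]
      pr <- prow[[as.character(c)]]
      pv <- numeric(length(cand))
      if (!is.null(pr) && any(pr$x > 0)) {
        mt <- match(cand, pr$j)
        pv[!is.na(mt)] <- pr$x[mt[!is.na(mt)]]
      }
      tgt[((c - 1L) * out_degree + 1L):(c * out_degree)] <-
        rank_candidates(cand, dist, pv, out_degree)
    }
  }
  new_layout_graph(source = src, target = tgt,
                   rank = rep(seq_len(out_degree), C),
                   out_degree = out_degree, variant = "transitions_timestamped",
                   cell_ids = rownames(embedding))
}

#' Export a layout graph as a tab-delimited edge list
#'
#' Rows are ordered by source then rank, so re-export is byte-identical; the
#' file is directly consumable by external ForceAtlas2/UMAP-graph layout
#' engines.
#'
#' @param graph A `layout_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path) {
  ids <- graph$cell_ids %||% as.character(seq_len(max(graph$edges$source)))
  e <- graph$edges[order(graph$edges$source, graph$edges$rank), ]
  tab <- data.frame(source = ids[e$source], target = ids[e$target])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge list written by [export_graph()]
#' @param path File path.
#' @return data.frame with character `source` and `target` columns.
#' @export
read_graph <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}
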