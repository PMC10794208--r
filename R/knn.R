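#' Exact k-nearest-neighbour graph on embeddings
#'
#' Computes each contig's k nearest neighbours by squared L2 distance
#' (blocked exact search) and symmetrizes the directed neighbour lists by
#' union. Self-edges are excluded.
#'
#' @param embeddings Numeric matrix `N x d`, rownames = contig ids.
#' @param k Neighbours per node; default `min(100, N - 1)`.
#' @param block Rows per distance block (memory control).
#' @return A `knn_graph`: list with `edges` (data frame `i`, `j`, `d2`;
#'   `i < j`, `d2` = squared L2), `ids`, `n`, `k`.
#' @export
knn_graph <- function(embeddings, k = NULL, block = 1024L) {
  N <- nrow(embeddings)
  if (is.null(k)) k <- min(100L, N - 1L)
  if (k >= N) stop("k (", k, ") must be smaller than the number of points (", N, ")")
  if (k < 1) stop("k must be >= 1")
  sq <- rowSums(embeddings^2)
  nb_i <- vector("list", ceiling(N / block))
  nb_j <- vector("list", ceiling(N / block))
  nb_d <- vector("list", ceiling(N / block))
  bi <- 0L
  for (s in seq(1L, N, by = block)) {
    e <- min(s + block - 1L, N)
    D <- outer(sq[s:e], sq, "+") -
      2 * tcrossprod(embeddings[s:e, , drop = FALSE], embeddings)
    D <- pmax(D, 0)
    idx <- matrix(0L, e - s + 1L, k)
    dd <- matrix(0, e - s + 1L, k)
    for (r in seq_len(e - s + 1L)) {
      drow <- D[r, ]
      drow[s + r - 1L] <- Inf   # exclude self
      o <- order(drow)[seq_len(k)]
      idx[r, ] <- o
      dd[r, ] <- drow[o]
    }
    bi <- bi + 1L
    nb_i[[bi]] <- rep(s:e, each = k)
    nb_j[[bi]] <- as.vector(t(idx))
    nb_d[[bi]] <- as.vector(t(dd))
  }
  ii <- unlist(nb_i); jj <- unlist(nb_j); dd <- unlist(nb_d)
  a <- pmin(ii, jj); b <- pmax(ii, jj)
  key <- paste(a, b)
  keep <- !duplicated(key)
  edges <- data.frame(i = a[keep], j = b[keep], d2 = dd[keep])
  edges <- edges[order(edges$d2, edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, ids = rownames(embeddings), n = N, k = k),
            class = "knn_graph")
}

#' @export
print.knn_graph <- function(x, ...) {
  cat(sprintf("knn_graph: %d nodes, %d undirected edges (k = %d)\n",
              x$n, nrow(x$edges), x$k))
  invisible(x)
}

#' Keep the closest fraction of edges
#'
#' Retains `floor(ratio * E)` edges with the smallest distances (ties broken
#' by node indices for determinism); `ratio = 1` is the identity.
#'
#' @param graph A `knn_graph`.
#' @param ratio Fraction of edges to keep, in `(0, 1]`.
#' @return A `knn_graph` with the filtered edge set.
#' @export
filter_edges <- function(graph, ratio) {
  stopifnot(inherits(graph, "knn_graph"), ratio > 0, ratio <= 1)
  if (ratio == 1) return(graph)
  E <- nrow(graph$edges)
  keep <- floor(ratio * E)
  ord <- order(graph$edges$d2, graph$edges$i, graph$edges$j)
  graph$edges <- graph$edges[ord[seq_len(keep)], , drop = FALSE]
  rownames(graph$edges) <- NULL
  graph
}

#' Convert distances to similarities
#'
#' Gaussian kernel on the squared L2 distance: `S_ij = exp(-d2 / sigma)`,
#' giving similarities in `(0, 1]` that decrease in distance.
#'
#' @param graph A `knn_graph`.
#' @param sigma Kernel bandwidth (> 0).
#' @return A `similarity_graph`: the graph with an added `s` edge column and
#'   the `sigma` used.
#' @export
to_similarity <- function(graph, sigma) {
  stopifnot(inherits(graph, "knn_graph"), sigma > 0)
  edges <- graph$edges
  edges$s <- exp(-edges$d2 / sigma)
  structure(list(edges = edges, ids = graph$ids, n = graph$n, sigma = sigma),
            class = "similarity_graph")
}
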