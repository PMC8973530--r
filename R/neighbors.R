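#' Build a symmetrized k-nearest-neighbour graph
#'
#' Edges connect i and j whenever j is among i's `k_graph` Euclidean nearest
#' neighbours or vice versa; the edge weight is the Euclidean distance.
#' Duplicate points yield zero-weight edges, which Dijkstra handles.
#'
#' @param X numeric n x D matrix.
#' @param k_graph neighbours per point used to build the graph (`1 <=
#'   k_graph < n`).
#' @return An object of class `knn_graph`: list with `n`, `k_graph`,
#'   `nn_index` (n x k_graph, ties broken by smaller index, self excluded),
#'   `nn_dist`, `euclid` (dense n x n distance matrix) and `edges`
#'   (data.frame `from`, `to`, `weight` of the symmetrized edge set).
#' @export
build_knn_graph <- function(X, k_graph) {
  X <- as.matrix(X)
  n <- nrow(X)
  k_graph <- as.integer(k_graph)
  if (k_graph < 1L || k_graph >= n)
    stop("need 1 <= k_graph < n (n = ", n, ", k_graph = ", k_graph, ")")
  D <- as.matrix(stats::dist(X))
  nn_index <- matrix(0L, n, k_graph)
  nn_dist <- matrix(0, n, k_graph)
  for (i in seq_len(n)) {
    ord <- order(D[i, ])          # ties -> smaller index first
    ord <- ord[ord != i][seq_len(k_graph)]
    nn_index[i, ] <- ord
    nn_dist[i, ] <- D[i, ord]
  }
  from <- rep(seq_len(n), k_graph)
  to <- as.vector(nn_index)
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(cbind(a, b))
  edges <- data.frame(from = a[keep], to = b[keep],
                      weight = D[cbind(a[keep], b[keep])])
  structure(list(n = n, k_graph = k_graph, nn_index = nn_index,
                 nn_dist = nn_dist, euclid = D, edges = edges),
            class = "knn_graph")
}

#' All-pairs geodesic distances on a kNN graph
#'
#' Shortest-path (Dijkstra) distances over the symmetrized Euclidean kNN
#' graph, the standard Isomap-style approximation of distance along the
#' data manifold. Pairs split across disconnected components fall back to
#' their ambient Euclidean distance (dropping points would silently change
#' the sample; infinite distances would poison the normalization), and the
#' number of such pairs is reported via `attr(, "n_disconnected")` and a
#' message.
#'
#' @param graph a `knn_graph` from [build_knn_graph()].
#' @return Dense symmetric n x n matrix of geodesic distances, zero on the
#'   diagonal.
#' @export
geodesic_distances <- function(graph) {
  stopifnot(inherits(graph, "knn_graph"))
  g <- igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = data.frame(name = seq_len(graph$n)))
  geo <- igraph::distances(g, weights = igraph::E(g)$weight,
                           algorithm = "dijkstra")
  geo <- geo[order(as.integer(rownames(geo))),
             order(as.integer(colnames(geo)))]
  dimnames(geo) <- NULL
  disc <- !is.finite(geo)
  n_disc <- sum(disc) / 2
  if (n_disc > 0) {
    geo[disc] <- graph$euclid[disc]
    message("kNN graph has disconnected components: ", n_disc,
            " pair(s) fall back to ambient Euclidean distance")
  }
  attr(geo, "n_disconnected") <- n_disc
  geo
}

#' Normalized geodesic distance
#'
#' Scale-free neighbor metric: each geodesic distance f(x_i, x_j) is divided
#' by the geometric mean of the two points' mean geodesic distances d(x_i),
#' d(x_j) to all other points, so that uniformly rescaling the coordinates
#' leaves the metric unchanged and dense/sparse regions of the manifold are
#' ranked comparably.
#'
#' @param geodesic symmetric n x n geodesic distance matrix.
#' @param mean_geo optional length-n vector of mean geodesic distances
#'   (self excluded); computed from `geodesic` when omitted.
#' @return Symmetric n x n matrix `d_ij = f_ij / sqrt(d_i * d_j)` with zero
#'   diagonal and `attr(, "mean_geo")`.
#' @export
normalized_distance <- function(geodesic, mean_geo = NULL) {
  n <- nrow(geodesic)
  if (n < 2L) stop("need at least two points")
  if (is.null(mean_geo)) mean_geo <- rowSums(geodesic) / (n - 1)
  if (any(mean_geo <= 0))
    stop("degenerate input: some point has zero mean geodesic distance ",
         "(all points coincide?)")
  d <- geodesic / sqrt(outer(mean_geo, mean_geo))
  diag(d) <- 0
  attr(d, "mean_geo") <- mean_geo
  d
}

#' Final neighborhoods under a distance matrix
#'
#' Picks, for each point, the k other points with smallest distance (ties
#' broken by smaller index).
#'
#' @param dmat symmetric n x n distance matrix.
#' @param k neighborhood size, `k < n`.
#' @return Integer n x k matrix; row i holds J_i sorted by distance.
#' @export
final_neighborhoods <- function(dmat, k) {
  n <- nrow(dmat)
  k <- as.integer(k)
  if (k >= n) stop("need k < n (n = ", n, ", k = ", k, ")")
  J <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(dmat[i, ])
    J[i, ] <- ord[ord != i][seq_len(k)]
  }
  J
}

#' Build the full neighbor structure for MLLE training
#'
#' Two-stage neighbor selection: a Euclidean kNN graph supports geodesic
#' distances, and the normalized geodesic metric then picks the final
#' neighborhoods used for the local reconstruction weights. With
#' `metric = "euclidean"` the geodesic stage is skipped and the plain
#' Euclidean kNN sets are used (the classical MLLE setting, and the mode
#' compared against reference implementations).
#'
#' @param X numeric n x D matrix.
#' @param k final neighborhood size.
#' @param k_graph neighbours used to build the graph (default `k`).
#' @param metric `"geodesic"` (normalized geodesic, the default) or
#'   `"euclidean"`.
#' @return An object of class `neighbor_graph`: list with `n`, `k`,
#'   `k_graph`, `metric`, `neighborhoods` (n x k index matrix), and for the
#'   geodesic metric also `geodesic`, `mean_geo`, `normalized` and
#'   `n_disconnected`.
#' @export
neighbor_graph <- function(X, k, k_graph = k,
                           metric = c("geodesic", "euclidean")) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  n <- nrow(X)
  if (k >= n) stop("need k < n (n = ", n, ", k = ", k, ")")
  g <- build_knn_graph(X, min(k_graph, n - 1L))
  if (metric == "euclidean") {
    J <- g$nn_index[, seq_len(k), drop = FALSE]
    if (k > g$k_graph) J <- final_neighborhoods(g$euclid, k)
    return(structure(list(n = n, k = k, k_graph = g$k_graph,
                          metric = metric, neighborhoods = J,
                          euclid = g$euclid),
                     class = "neighbor_graph"))
  }
  geo <- geodesic_distances(g)
  nd <- normalized_distance(geo)
  J <- final_neighborhoods(nd, k)
  structure(list(n = n, k = k, k_graph = g$k_graph, metric = metric,
                 neighborhoods = J, euclid = g$euclid, geodesic = geo,
                 mean_geo = attr(nd, "mean_geo"), normalized = nd,
                 n_disconnected = attr(geo, "n_disconnected")),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("Neighbor graph: n = ", x$n, ", k = ", x$k, ", metric = ", x$metric,
      "\n", sep = "")
  invisible(x)
}
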