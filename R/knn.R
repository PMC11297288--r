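#' Exact k-nearest-neighbour graph
#'
#' Builds the exact kNN graph (no self-neighbours) used by the graph-based
#' metrics. Cosine distance is realized by L2-normalizing rows, which
#' preserves cosine neighbour ordering.
#'
#' @param x A [profile_table] or numeric matrix (wells x dims).
#' @param k Neighbour count, `k < n_wells`.
#' @param metric `"euclidean"` or `"cosine"`.
#' @return Object of class `knn_graph`: list with `index` (n x k neighbour
#'   indices), `dist` (n x k distances), `k`, `metric`.
#' @export
build_knn_graph <- function(x, k = 15, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  M <- rep_matrix(x)
  n <- nrow(M)
  if (k >= n) stop("k = ", k, " must be smaller than the number of wells (",
                   n, ")")
  if (metric == "cosine") M <- l2_normalize(M)
  nn <- FNN::get.knn(M, k = k)
  structure(list(index = nn$nn.index, dist = nn$nn.dist, k = k,
                 metric = metric, n = n),
            class = "knn_graph")
}

#' @export
print.knn_graph <- function(x, ...) {
  cat("knn_graph: ", x$n, " wells, k = ", x$k, ", metric = ", x$metric,
      "\n", sep = "")
  invisible(x)
}

knn_igraph <- function(graph) {
  stopifnot(inherits(graph, "knn_graph"))
  edges <- cbind(rep(seq_len(graph$n), graph$k), as.vector(graph$index))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, graph$n - igraph::vcount(g)))
  igraph::simplify(g)
}

rep_matrix <- function(x) {
  if (inherits(x, "profile_table")) return(x$features)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected a profile_table or numeric matrix")
}
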