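#' Directed graph density
#'
#' Density of a lag under the directed convention: E / (N (N - 1)), edge
#' weights ignored. This is the denominator consistent with the directed
#' clustering coefficient used throughout the package.
#'
#' @param lag a `lag` with at least 2 nodes.
#' @return Density in `[0, 1]`.
#' @export
lag_density <- function(lag) {
  stopifnot(inherits(lag, "lag"))
  n <- lag_node_count(lag)
  if (n < 2L) stop("density is undefined for graphs with fewer than 2 nodes",
                   call. = FALSE)
  lag_edge_count(lag) / (n * (n - 1))
}

# Binary adjacency (dense logical matrix) of a lag; weights dropped.
# Dense is fine at the scale of fluency graphs (hundreds of nodes).
lag_adjacency <- function(lag) {
  as.matrix(igraph::as_adjacency_matrix(lag$graph, sparse = FALSE)) > 0
}

#' Clustering coefficient of one node
#'
#' The clustering coefficient of a vertex v is the density of the directed
#' subgraph spanned by its adjacent vertices (in- and out-neighbours
#' pooled, v itself excluded): with k neighbours and r directed edges among
#' them, the coefficient is r / (k (k - 1)). Nodes with fewer than two
#' neighbours get 0 by convention.
#'
#' @param lag a `lag`.
#' @param word a node name.
#' @return List with `word`, `k` (neighbour count), `r` (directed edges
#'   among the neighbours) and `value` = r / (k (k - 1)).
#' @export
node_clustering <- function(lag, word) {
  stopifnot(inherits(lag, "lag"))
  nodes <- lag_nodes(lag)
  if (!word %in% nodes) stop("unknown node: ", word, call. = FALSE)
  A <- lag_adjacency(lag)
  i <- match(word, rownames(A))
  nb <- which(A[i, ] | A[, i])
  nb <- setdiff(nb, i)
  k <- length(nb)
  r <- if (k >= 2L) sum(A[nb, nb]) else 0L
  value <- if (k < 2L) 0 else r / (k * (k - 1))
  list(word = word, k = k, r = as.integer(r), value = value)
}

#' Clustering coefficients of every node
#'
#' @param lag a `lag`.
#' @return data.frame `word, k, r, value`, one row per node, in node order.
#' @export
clustering_profile <- function(lag) {
  stopifnot(inherits(lag, "lag"))
  A <- lag_adjacency(lag)
  n <- nrow(A)
  k <- integer(n); r <- integer(n)
  if (n > 0L) {
    U <- (A | t(A))
    for (i in seq_len(n)) {
      nb <- which(U[i, ])
      k[i] <- length(nb)
      if (k[i] >= 2L) r[i] <- sum(A[nb, nb])
    }
  }
  value <- ifelse(k < 2L, 0, r / (k * (k - 1)))
  data.frame(word = rownames(A), k = k, r = r, value = value,
             stringsAsFactors = FALSE)
}

#' Mean clustering coefficient of a lag
#'
#' Arithmetic mean of the per-node clustering coefficients over the whole
#' vertex set. By default nodes with fewer than two neighbours contribute 0;
#' set `include_low_degree = FALSE` to average only over nodes with k >= 2.
#'
#' @param lag a `lag` with at least 1 node.
#' @param include_low_degree include k < 2 nodes as zeros (default `TRUE`).
#' @return Mean clustering in `[0, 1]` (`NaN` if no node qualifies).
#' @export
mean_clustering <- function(lag, include_low_degree = TRUE) {
  prof <- clustering_profile(lag)
  if (!include_low_degree) prof <- prof[prof$k >= 2L, , drop = FALSE]
  if (nrow(prof) == 0L) return(NaN)
  mean(prof$value)
}

# Hop-distance matrix (weights ignored). mode "directed" follows edge
# direction; "undirected" symmetrizes.
lag_distances <- function(lag, mode = c("directed", "undirected")) {
  mode <- match.arg(mode)
  igraph::distances(lag$graph, mode = if (mode == "directed") "out" else "all",
                    weights = NA)
}

#' Shortest-path statistics of a lag
#'
#' All-pairs hop distances (edge weights ignored). Averages and the diameter
#' are taken over ordered reachable pairs only; disconnection is reported
#' through `reachable_pair_fraction` rather than treated as an error.
#'
#' @param lag a `lag` with at least 2 nodes.
#' @param mode `"directed"` (follow edge direction) or `"undirected"`
#'   (symmetrized).
#' @return List with `avg_shortest_path`, `diameter` (max finite distance),
#'   `reachable_pair_fraction` (finite ordered pairs / N(N-1)) and
#'   `eccentricity`, a named vector of per-node maxima of finite distances
#'   (0 for a node that reaches nothing).
#' @export
path_stats <- function(lag, mode = c("directed", "undirected")) {
  stopifnot(inherits(lag, "lag"))
  mode <- match.arg(mode)
  n <- lag_node_count(lag)
  if (n < 2L) stop("path statistics need at least 2 nodes", call. = FALSE)
  d <- lag_distances(lag, mode)
  diag(d) <- NA
  finite <- is.finite(d)
  n_pairs <- n * (n - 1)
  n_reach <- sum(finite, na.rm = TRUE)
  ecc <- apply(d, 1L, function(row) {
    f <- row[is.finite(row)]
    if (length(f) == 0L) 0 else max(f)
  })
  list(
    avg_shortest_path = if (n_reach > 0L) mean(d[which(finite)]) else NaN,
    diameter = if (n_reach > 0L) max(d[which(finite)]) else 0,
    reachable_pair_fraction = n_reach / n_pairs,
    eccentricity = ecc)
}

#' Structural summary of a lag
#'
#' Bundles node/edge counts, density, mean clustering and path statistics —
#' the metric rows of a small-world comparison table.
#'
#' @param lag a `lag` with at least 2 nodes.
#' @param mode path-statistics mode, `"directed"` or `"undirected"`.
#' @return An object of class `metrics_summary`: list with `node_count`,
#'   `edge_count`, `density`, `mean_clustering`, `avg_shortest_path`,
#'   `diameter`, `reachable_pair_fraction`, `mode`.
#' @export
metrics_summary <- function(lag, mode = c("directed", "undirected")) {
  mode <- match.arg(mode)
  ps <- path_stats(lag, mode)
  structure(list(
    node_count = lag_node_count(lag),
    edge_count = lag_edge_count(lag),
    density = lag_density(lag),
    mean_clustering = mean_clustering(lag),
    avg_shortest_path = ps$avg_shortest_path,
    diameter = ps$diameter,
    reachable_pair_fraction = ps$reachable_pair_fraction,
    mode = mode), class = "metrics_summary")
}

#' @export
print.metrics_summary <- function(x, ...) {
  cat("<metrics_summary> (", x$mode, " paths)\n", sep = "")
  cat(sprintf("  nodes %d  edges %d  density %.3f\n",
              x$node_count, x$edge_count, x$density))
  cat(sprintf("  mean clustering %.3f  avg path %.3f  diameter %g  reachable %.3f\n",
              x$mean_clustering, x$avg_shortest_path, x$diameter,
              x$reachable_pair_fraction))
  invisible(x)
}

#' Centrality table of a lag
#'
#' Computes, per word: total degree (in + out edge count), weighted degree
#' (in + out weight sum), eccentricity (max finite directed hop distance
#' from the node; 0 when it reaches nothing), closeness (reciprocal of the
#' mean hop distance to the nodes it reaches; 0 when it reaches nothing),
#' harmonic closeness (mean of 1/d over all other nodes, 1/Inf = 0) and
#' betweenness (directed, unweighted shortest-path pair dependencies,
#' unnormalized).
#'
#' @param lag a `lag` with at least 2 nodes.
#' @return data.frame `word, degree, weighted_degree, eccentricity,
#'   closeness, harmonic_closeness, betweenness`.
#' @export
centralities <- function(lag) {
  stopifnot(inherits(lag, "lag"))
  n <- lag_node_count(lag)
  if (n < 2L) stop("centralities need at least 2 nodes", call. = FALSE)
  g <- lag$graph
  d <- lag_distances(lag, "directed")
  diag(d) <- NA
  closeness <- apply(d, 1L, function(row) {
    f <- row[is.finite(row)]
    if (length(f) == 0L) 0 else length(f) / sum(f)
  })
  harmonic <- apply(d, 1L, function(row) {
    inv <- 1 / row
    inv[!is.finite(row)] <- 0
    sum(inv, na.rm = TRUE) / (n - 1)
  })
  ecc <- apply(d, 1L, function(row) {
    f <- row[is.finite(row)]
    if (length(f) == 0L) 0 else max(f)
  })
  data.frame(
    word = igraph::V(g)$name,
    degree = igraph::degree(g, mode = "all"),
    weighted_degree = igraph::strength(g, mode = "all",
                                       weights = igraph::E(g)$weight),
    eccentricity = ecc,
    closeness = closeness,
    harmonic_closeness = harmonic,
    betweenness = igraph::betweenness(g, directed = TRUE, weights = NA),
    row.names = NULL, stringsAsFactors = FALSE)
}

centrality_measures <- c("degree", "weighted_degree", "eccentricity",
                         "closeness", "harmonic_closeness", "betweenness")

#' Top-ranked words on one centrality measure
#'
#' Ranks descending for every measure except eccentricity, which ranks
#' ascending (lower eccentricity means higher centrality). Ties are broken
#' lexicographically so the ranking is fully deterministic.
#'
#' @param table a centrality table from [centralities()].
#' @param measure one of `degree`, `weighted_degree`, `eccentricity`,
#'   `closeness`, `harmonic_closeness`, `betweenness`.
#' @param count number of words to return.
#' @param min_value optional filter: drop rows whose value on `measure` is
#'   below it before ranking (eccentricity: rows with value below it are
#'   dropped too, mirroring an outlier cut).
#' @return Character vector of at most `count` words.
#' @export
top_central <- function(table, measure, count, min_value = NULL) {
  stopifnot(is.data.frame(table))
  if (!measure %in% centrality_measures) {
    stop("unknown measure '", measure, "'; expected one of: ",
         paste(centrality_measures, collapse = ", "), call. = FALSE)
  }
  vals <- table[[measure]]
  keep <- rep(TRUE, nrow(table))
  if (!is.null(min_value)) keep <- vals >= min_value
  tab <- table[keep, , drop = FALSE]
  vals <- vals[keep]
  ord <- if (measure == "eccentricity") {
    order(vals, tab$word)
  } else {
    order(-vals, tab$word)
  }
  utils::head(tab$word[ord], count)
}

#' Overlap between two ranked word lists
#'
#' @param list_a,list_b non-empty character vectors.
#' @return List with `count` (size of the intersection) and `jaccard`
#'   (intersection over union).
#' @export
ranking_overlap <- function(list_a, list_b) {
  if (length(list_a) == 0L || length(list_b) == 0L) {
    stop("ranking lists must be non-empty", call. = FALSE)
  }
  a <- unique(list_a); b <- unique(list_b)
  inter <- length(intersect(a, b))
  list(count = inter, jaccard = inter / length(union(a, b)))
}
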