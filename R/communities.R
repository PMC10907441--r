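#' Modularity communities of a lag
#'
#' Runs Louvain-style greedy modularity maximisation on the undirected
#' weighted projection of the graph (reciprocal edges' weights summed);
#' everywhere else in the package the graph stays directed, but modularity
#' is conventionally defined on the symmetrized graph. Community ids are
#' relabelled contiguously from 0, ordered by decreasing size (ties: the
#' lexicographically smallest member).
#'
#' @param lag a `lag` with at least 1 node.
#' @param resolution resolution parameter of the modularity quality
#'   function (default 1, the classical Newman definition).
#' @param seed integer RNG seed; the run is deterministic given the seed.
#' @return An object of class `community_partition`: list with
#'   `assignment` (named integer vector, word -> community id),
#'   `modularity_score` (direct evaluation of weighted Newman modularity on
#'   the assignment, see [modularity_score()]), `resolution`, `seed`.
#' @export
detect_communities <- function(lag, resolution = 1, seed = 1L) {
  stopifnot(inherits(lag, "lag"))
  seed <- check_seed(seed)
  if (lag_node_count(lag) == 0L) stop("empty graph", call. = FALSE)
  g <- undirected_projection(lag)
  comm <- with_seed(seed, igraph::cluster_louvain(
    g, weights = igraph::E(g)$weight, resolution = resolution))
  memb <- igraph::membership(comm)
  assignment <- relabel_communities(memb)
  structure(list(
    assignment = assignment,
    modularity_score = modularity_score(lag, assignment),
    resolution = resolution,
    seed = seed), class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  sizes <- table(x$assignment)
  cat("<community_partition>", length(sizes), "communities, modularity",
      sprintf("%.3f", x$modularity_score), "\n")
  cat("  sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  invisible(x)
}

# weighted undirected projection; reciprocal edge weights summed
undirected_projection <- function(lag) {
  igraph::as_undirected(lag$graph, mode = "collapse",
                        edge.attr.comb = list(weight = "sum", "ignore"))
}

# contiguous ids from 0, largest community first, ties by smallest member
relabel_communities <- function(membership) {
  words <- names(membership)
  split_words <- split(words, membership)
  ord <- order(-lengths(split_words),
               vapply(split_words, function(w) min(w), ""))
  out <- integer(length(membership))
  names(out) <- words
  for (new_id in seq_along(ord)) {
    out[split_words[[ord[new_id]]]] <- new_id - 1L
  }
  out
}

#' Weighted Newman modularity of a node assignment
#'
#' Direct evaluation (no optimisation) of the standard weighted modularity
#' Q = sum_c [ W_c / m - (S_c / 2m)^2 ] on the undirected weighted
#' projection of the lag, where W_c is the total weight of edges inside
#' community c, S_c the total strength of its nodes and m the total edge
#' weight. Placing all nodes in one community gives exactly 0.
#'
#' @param lag a `lag`.
#' @param assignment named vector (word -> community label) covering every
#'   node of the graph.
#' @return Modularity score in `[-0.5, 1]`.
#' @export
modularity_score <- function(lag, assignment) {
  stopifnot(inherits(lag, "lag"))
  nodes <- lag_nodes(lag)
  if (is.null(names(assignment)) || !all(nodes %in% names(assignment))) {
    stop("assignment must cover every node of the graph", call. = FALSE)
  }
  g <- undirected_projection(lag)
  w <- igraph::E(g)$weight
  m <- sum(w)
  if (m == 0) return(0)
  el <- igraph::as_edgelist(g, names = TRUE)
  memb <- assignment[igraph::V(g)$name]
  names(memb) <- igraph::V(g)$name
  within <- memb[el[, 1L]] == memb[el[, 2L]]
  strength <- igraph::strength(g, weights = w)
  s_c <- tapply(strength, memb[names(strength)], sum)
  sum(w[within]) / m - sum((s_c / (2 * m))^2)
}

#' Anchor-word cluster table
#'
#' Tabulates a community partition the way availability studies present
#' modularity clusters: one row block per community, the anchor being the
#' member with highest total degree in the graph (ties broken
#' lexicographically), remaining members sorted by degree descending.
#' Communities are ordered by size descending.
#'
#' @param lag the `lag` the partition was computed on.
#' @param partition a [detect_communities()] result, or any named
#'   community-label vector.
#' @param min_size drop communities smaller than this (default 1 = keep
#'   all).
#' @param top_n_nodes if given, restrict to the `top_n_nodes` words of
#'   highest total degree before tabulating; only communities intersecting
#'   that set appear.
#' @return data.frame `community, anchor, member, degree, rank` with one
#'   row per member (`rank` 1 is the anchor).
#' @export
cluster_table <- function(lag, partition, min_size = 1L, top_n_nodes = NULL) {
  stopifnot(inherits(lag, "lag"))
  assignment <- if (inherits(partition, "community_partition")) {
    partition$assignment
  } else {
    partition
  }
  nodes <- lag_nodes(lag)
  if (!all(nodes %in% names(assignment))) {
    stop("partition does not cover every node", call. = FALSE)
  }
  deg <- igraph::degree(lag$graph, mode = "all")
  words <- nodes
  if (!is.null(top_n_nodes)) {
    ord <- order(-deg[words], words)
    words <- words[ord][seq_len(min(top_n_nodes, length(words)))]
  }
  memb <- assignment[words]
  groups <- split(words, memb)
  groups <- groups[lengths(groups) >= min_size]
  if (length(groups) == 0L) {
    return(data.frame(community = integer(), anchor = character(),
                      member = character(), degree = integer(),
                      rank = integer(), stringsAsFactors = FALSE))
  }
  groups <- groups[order(-lengths(groups),
                         vapply(groups, function(w) min(w), ""))]
  rows <- lapply(seq_along(groups), function(i) {
    members <- groups[[i]]
    members <- members[order(-deg[members], members)]
    data.frame(community = i - 1L, anchor = members[[1L]], member = members,
               degree = as.integer(deg[members]),
               rank = seq_along(members), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to score recovery of planted communities. 1 means identical
#' partitions; independent partitions score about 0.
#'
#' @param a,b vectors of community labels over the same items (matched by
#'   name when both are named, by position otherwise).
#' @return The adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (length(common) == 0L) stop("no shared items", call. = FALSE)
    a <- a[common]; b <- b[common]
  }
  if (length(a) != length(b)) stop("label vectors differ in length",
                                   call. = FALSE)
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
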