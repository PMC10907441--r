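# Brute-force reference implementations, independent of igraph and of the
# package's own code paths. All work on plain base-R matrices.

# binary directed adjacency matrix of a lag, in lag_nodes() order
adj_of <- function(lag) {
  nodes <- lag_nodes(lag)
  A <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  e <- lag_edges(lag)
  if (nrow(e) > 0L) A[cbind(e$source, e$target)] <- TRUE
  A
}

# weighted directed adjacency matrix
wadj_of <- function(lag) {
  nodes <- lag_nodes(lag)
  W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  e <- lag_edges(lag)
  if (nrow(e) > 0L) W[cbind(e$source, e$target)] <- e$weight
  W
}

oracle_density <- function(A) {
  n <- nrow(A)
  sum(A) / (n * (n - 1))
}

# clustering of node i: density of the directed subgraph on the pooled
# in/out neighbourhood
oracle_clustering <- function(A, i) {
  nb <- setdiff(which(A[i, ] | A[, i]), i)
  k <- length(nb)
  if (k < 2L) return(0)
  sum(A[nb, nb]) / (k * (k - 1))
}

# Floyd-Warshall hop distances
oracle_distances <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  d[A] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# directed unweighted betweenness via shortest-path counting on the
# Floyd-Warshall distance matrix
oracle_betweenness <- function(A) {
  n <- nrow(A)
  d <- oracle_distances(A)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (t in order(d[s, ])) {
      if (t == s || !is.finite(d[s, t])) next
      preds <- which(A[, t] & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  b <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t || !is.finite(d[s, t]) || sigma[s, t] == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  names(b) <- rownames(A)
  b
}

# weighted Newman modularity from the symmetric projection W + t(W)
oracle_modularity <- function(Wdir, memb) {
  W <- Wdir + t(Wdir)
  two_m <- sum(W)
  if (two_m == 0) return(0)
  k <- rowSums(W)
  same <- outer(memb, memb, "==")
  sum((W - outer(k, k) / two_m) * same) / two_m
}

# all set partitions of 1..n as membership vectors (restricted growth)
all_partitions <- function(n) {
  out <- list()
  grow <- function(memb, mx) {
    if (length(memb) == n) {
      out[[length(out) + 1L]] <<- memb
      return(invisible())
    }
    for (b in seq_len(mx + 1L)) grow(c(memb, b), max(mx, b))
  }
  grow(integer(0), 0L)
  out
}

# random weighted lag on n nodes with edge probability p
rand_test_lag <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- runif(nrow(pairs)) < p
  e <- pairs[keep, , drop = FALSE]
  e$weight <- if (nrow(e) > 0L) sample(1:4, nrow(e), replace = TRUE)
              else integer(0)
  lag_from_edges(e, nodes = nodes, prompt = "test")
}

# directed clique on the given node names
clique_lag <- function(nodes, prompt = "clique") {
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs$weight <- 1L
  lag_from_edges(pairs, prompt = prompt)
}
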