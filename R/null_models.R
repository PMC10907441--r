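#' Uniform random directed graph matched by size
#'
#' Samples a simple directed graph with exactly `n` nodes and `m` edges
#' uniformly at random: `m` distinct ordered node pairs (no self-loops) are
#' drawn without replacement, all with weight 1. This is the G(n, m) null
#' used to benchmark observed lexical availability graphs against graphs of
#' the same size and density.
#'
#' @param n node count.
#' @param m edge count, `0 <= m <= n (n - 1)`.
#' @param seed integer RNG seed; the draw is deterministic given the seed.
#' @param prompt label for the generated graph.
#' @return A `lag` with nodes `r001, r002, ...`.
#' @export
random_lag <- function(n, m, seed, prompt = "random") {
  seed <- check_seed(seed)
  if (n < 1L) stop("`n` must be at least 1", call. = FALSE)
  cap <- n * (n - 1)
  if (m < 0L || m > cap) {
    stop("`m` must lie in [0, n(n-1)] = [0, ", cap, "]", call. = FALSE)
  }
  nodes <- sprintf("r%03d", seq_len(n))
  if (m == 0L) {
    return(lag_from_edges(
      data.frame(source = character(), target = character(),
                 weight = integer(), stringsAsFactors = FALSE),
      nodes = nodes, prompt = prompt))
  }
  idx <- with_seed(seed, sample.int(cap, m))
  # enumerate ordered pairs row-wise, skipping the diagonal
  src <- (idx - 1L) %/% (n - 1L) + 1L
  off <- (idx - 1L) %% (n - 1L) + 1L
  dst <- off + (off >= src)
  lag_from_edges(
    data.frame(source = nodes[src], target = nodes[dst], weight = 1L,
               stringsAsFactors = FALSE),
    nodes = nodes, prompt = prompt)
}

#' Bernoulli random directed graph matched by density
#'
#' Density-matched variant of [random_lag()]: each of the n(n-1) ordered
#' pairs is included independently with probability `p`, so the edge count
#' varies around p n(n-1). Provided for sensitivity analysis; the
#' exact-size G(n, m) model is the default null elsewhere.
#'
#' @param n node count.
#' @param p edge probability in `[0, 1]`.
#' @param seed integer RNG seed.
#' @param prompt label for the generated graph.
#' @return A `lag`.
#' @export
random_lag_gnp <- function(n, p, seed, prompt = "random_gnp") {
  seed <- check_seed(seed)
  if (n < 1L) stop("`n` must be at least 1", call. = FALSE)
  if (p < 0 || p > 1) stop("`p` must be in [0, 1]", call. = FALSE)
  cap <- n * (n - 1)
  keep <- with_seed(seed, which(stats::runif(cap) < p))
  nodes <- sprintf("r%03d", seq_len(n))
  if (length(keep) == 0L) {
    return(lag_from_edges(
      data.frame(source = character(), target = character(),
                 weight = integer(), stringsAsFactors = FALSE),
      nodes = nodes, prompt = prompt))
  }
  src <- (keep - 1L) %/% (n - 1L) + 1L
  off <- (keep - 1L) %% (n - 1L) + 1L
  dst <- off + (off >= src)
  lag_from_edges(
    data.frame(source = nodes[src], target = nodes[dst], weight = 1L,
               stringsAsFactors = FALSE),
    nodes = nodes, prompt = prompt)
}

#' Small-world comparison against a matched random ensemble
#'
#' Compares an observed graph with an ensemble of G(n, m) random digraphs
#' of exactly the same node and edge counts. For each replicate the mean
#' clustering coefficient, average shortest-path length and diameter are
#' computed (path statistics in both directed and undirected mode, since
#' symmetrization conventions differ between tools); ensemble means and
#' standard deviations are reported together with the observed/random
#' ratios. The small-world verdict requires clustering well above the
#' random baseline while path lengths stay comparable.
#'
#' @param lag observed `lag` with at least 2 nodes.
#' @param replicates ensemble size (default 50).
#' @param seed integer RNG seed; replicate r uses the derived seed
#'   `seed * 1000 + r`.
#' @param clustering_threshold verdict requires
#'   `clustering_ratio >= clustering_threshold` (default 5).
#' @param path_threshold verdict requires `path_ratio <= path_threshold`
#'   (default 2).
#' @param mode which path-statistics mode drives the ratios and verdict
#'   (default `"directed"`).
#' @return An object of class `small_world_report`: list with `observed`
#'   (a [metrics_summary()] plus undirected path stats), `random`
#'   (data.frame `metric, mean, sd`), `clustering_ratio`, `path_ratio`,
#'   `small_world` (logical verdict), `replicates`, `seed`, `thresholds`.
#' @export
small_world_report <- function(lag, replicates = 50L, seed = 1L,
                               clustering_threshold = 5,
                               path_threshold = 2,
                               mode = c("directed", "undirected")) {
  stopifnot(inherits(lag, "lag"))
  mode <- match.arg(mode)
  seed <- check_seed(seed)
  if (replicates < 1L) stop("`replicates` must be at least 1", call. = FALSE)
  n <- lag_node_count(lag)
  m <- lag_edge_count(lag)
  if (n < 2L) stop("observed graph needs at least 2 nodes", call. = FALSE)

  obs <- metrics_summary(lag, mode = "directed")
  obs_und <- path_stats(lag, mode = "undirected")
  observed <- c(unclass(obs)[setdiff(names(unclass(obs)), "mode")],
                list(avg_shortest_path_undirected = obs_und$avg_shortest_path,
                     diameter_undirected = obs_und$diameter))

  metric_names <- c("mean_clustering", "avg_shortest_path", "diameter",
                    "avg_shortest_path_undirected", "diameter_undirected")
  draws <- matrix(NA_real_, nrow = replicates, ncol = length(metric_names),
                  dimnames = list(NULL, metric_names))
  for (r in seq_len(replicates)) {
    rg <- random_lag(n, m, seed = seed * 1000L + r)
    ps_d <- path_stats(rg, "directed")
    ps_u <- path_stats(rg, "undirected")
    draws[r, ] <- c(mean_clustering(rg), ps_d$avg_shortest_path,
                    ps_d$diameter, ps_u$avg_shortest_path, ps_u$diameter)
  }
  random <- data.frame(metric = metric_names,
                       mean = apply(draws, 2L, mean),
                       sd = apply(draws, 2L, stats::sd),
                       row.names = NULL, stringsAsFactors = FALSE)

  rnd <- function(metric) random$mean[random$metric == metric]
  path_metric <- if (mode == "directed") "avg_shortest_path" else
    "avg_shortest_path_undirected"
  obs_path <- if (mode == "directed") observed$avg_shortest_path else
    observed$avg_shortest_path_undirected
  clustering_ratio <- observed$mean_clustering / rnd("mean_clustering")
  path_ratio <- obs_path / rnd(path_metric)
  structure(list(
    observed = observed,
    random = random,
    clustering_ratio = clustering_ratio,
    path_ratio = path_ratio,
    small_world = is.finite(clustering_ratio) && is.finite(path_ratio) &&
      clustering_ratio >= clustering_threshold &&
      path_ratio <= path_threshold,
    replicates = as.integer(replicates),
    seed = seed,
    mode = mode,
    thresholds = list(clustering = clustering_threshold,
                      path = path_threshold)),
    class = "small_world_report")
}

#' @export
print.small_world_report <- function(x, ...) {
  cat("<small_world_report>", x$replicates, "matched G(n,m) replicates\n")
  cat(sprintf("  observed: clustering %.3f  avg path %.3f  diameter %g\n",
              x$observed$mean_clustering, x$observed$avg_shortest_path,
              x$observed$diameter))
  rnd <- function(m) x$random$mean[x$random$metric == m]
  cat(sprintf("  random:   clustering %.3f  avg path %.3f  diameter %.2f\n",
              rnd("mean_clustering"), rnd("avg_shortest_path"),
              rnd("diameter")))
  cat(sprintf("  ratios: clustering %.2f  path %.2f  -> small world: %s\n",
              x$clustering_ratio, x$path_ratio, x$small_world))
  invisible(x)
}
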