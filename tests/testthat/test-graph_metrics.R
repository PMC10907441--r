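test_that("density uses the directed denominator", {
  g <- clique_lag(c("a", "b", "c"))
  expect_equal(lag_density(g), 1)
  single <- lag_from_edges(data.frame(source = character(),
                                      target = character(),
                                      weight = integer()),
                           nodes = "a")
  expect_error(lag_density(single), "undefined")
})

test_that("node clustering is the density of the pooled neighbourhood", {
  g3 <- clique_lag(c("a", "b", "c"))
  for (w in c("a", "b", "c")) {
    nc <- node_clustering(g3, w)
    expect_equal(nc$k, 2L)
    expect_equal(nc$r, 2L)
    expect_equal(nc$value, 1)
  }
  # star: no edges among leaves
  star <- lag_from_edges(data.frame(
    source = "hub", target = paste0("leaf", 1:4), weight = 1L))
  expect_equal(node_clustering(star, "hub")$value, 0)
  expect_equal(node_clustering(star, "leaf1")$value, 0)  # k = 1 convention
  # A->B, B->C, A->C, C->A: B's neighbourhood {A, C} carries both A->C, C->A
  g <- lag_from_edges(data.frame(source = c("A", "B", "A", "C"),
                                 target = c("B", "C", "C", "A"),
                                 weight = 1L))
  nc <- node_clustering(g, "B")
  expect_equal(nc$k, 2L)
  expect_equal(nc$r, 2L)
  expect_equal(nc$value, 1)
  expect_error(node_clustering(g, "nope"), "unknown node")
})

test_that("mean clustering averages over the whole vertex set", {
  expect_equal(mean_clustering(clique_lag(letters[1:3])), 1)
  chainy <- lag_from_edges(data.frame(source = c("a", "b"),
                                      target = c("b", "c"), weight = 1L))
  expect_equal(mean_clustering(chainy), 0)
  g <- rand_test_lag(6, 0.5, seed = 3)
  A <- adj_of(g)
  manual <- mean(vapply(seq_len(nrow(A)),
                        function(i) oracle_clustering(A, i), numeric(1)))
  expect_equal(mean_clustering(g), manual)
  # excluding low-degree nodes changes only the averaging set
  prof <- clustering_profile(g)
  expect_equal(mean_clustering(g, include_low_degree = FALSE),
               mean(prof$value[prof$k >= 2]))
})

test_that("path statistics match closed forms and hand counts", {
  cyc <- lag_from_edges(data.frame(source = letters[1:5],
                                   target = letters[c(2:5, 1)],
                                   weight = 1L))
  ps <- path_stats(cyc, "directed")
  expect_equal(unname(ps$eccentricity), rep(4, 5))
  expect_equal(ps$diameter, 4)
  expect_equal(ps$avg_shortest_path, 2.5)
  expect_equal(ps$reachable_pair_fraction, 1)

  two <- lag_from_edges(data.frame(source = c("a", "c"),
                                   target = c("b", "d"), weight = 1L))
  ps2 <- path_stats(two, "directed")
  expect_equal(ps2$diameter, 1)
  expect_equal(ps2$reachable_pair_fraction, 2 / 12)
  expect_equal(ps2$avg_shortest_path, 1)
})

test_that("distances, eccentricity and betweenness match brute force", {
  for (s in 1:6) {
    g <- rand_test_lag(sample(4:8, 1), runif(1, 0.2, 0.6), seed = 100 + s)
    A <- adj_of(g)
    d <- oracle_distances(A)
    ps <- path_stats(g, "directed")
    off <- d[row(d) != col(d)]
    expect_equal(ps$avg_shortest_path, mean(off[is.finite(off)]))
    expect_equal(ps$diameter, max(off[is.finite(off)]))
    expect_equal(ps$reachable_pair_fraction,
                 mean(is.finite(off)))
    cent <- centralities(g)
    expect_equal(cent$betweenness, unname(oracle_betweenness(A)[cent$word]))
  }
})

test_that("adding an edge never lengthens any shortest path", {
  g <- rand_test_lag(7, 0.25, seed = 9)
  d0 <- oracle_distances(adj_of(g))
  e <- lag_edges(g)
  nodes <- lag_nodes(g)
  missing <- expand.grid(source = nodes, target = nodes,
                         stringsAsFactors = FALSE)
  missing <- missing[missing$source != missing$target, ]
  key <- paste(missing$source, missing$target)
  missing <- missing[!key %in% paste(e$source, e$target), ]
  pick <- missing[1:3, ]
  for (i in seq_len(nrow(pick))) {
    e2 <- rbind(e, data.frame(source = pick$source[i],
                              target = pick$target[i], weight = 1L))
    d1 <- oracle_distances(adj_of(lag_from_edges(e2, nodes = nodes)))
    expect_true(all(d1 <= d0))
  }
})

test_that("centralities agree with symmetry and hand computation", {
  g3 <- clique_lag(c("a", "b", "c"))
  cent <- centralities(g3)
  for (ms in c("degree", "weighted_degree", "eccentricity", "closeness",
               "harmonic_closeness", "betweenness")) {
    expect_equal(length(unique(cent[[ms]])), 1L)
  }
  path <- lag_from_edges(data.frame(source = c("A", "B"),
                                    target = c("B", "C"), weight = 1L))
  pc <- centralities(path)
  expect_equal(pc$betweenness[pc$word == "B"], 1)
  expect_equal(pc$betweenness[pc$word %in% c("A", "C")], c(0, 0))
  expect_equal(pc$eccentricity[pc$word == "A"], 2)
  expect_equal(pc$eccentricity[pc$word == "C"], 0)  # reaches nothing
  expect_equal(pc$closeness[pc$word == "C"], 0)
  expect_equal(pc$harmonic_closeness[pc$word == "A"], (1 + 1 / 2) / 2)

  hub <- lag_from_edges(data.frame(
    source = c("hub", "hub", "hub", "l1", "l2", "l3"),
    target = c("l1", "l2", "l3", "hub", "hub", "hub"),
    weight = c(5L, 5L, 5L, 1L, 1L, 1L)))
  hc <- centralities(hub)
  for (ms in c("degree", "weighted_degree", "closeness",
               "harmonic_closeness", "betweenness")) {
    expect_equal(hc$word[which.max(hc[[ms]])], "hub")
  }
  expect_equal(hc$word[which.min(hc$eccentricity)], "hub")
})

test_that("weighted degree sums in- and out-weights", {
  g <- lag_from_edges(data.frame(source = c("a", "b", "c"),
                                 target = c("b", "a", "a"),
                                 weight = c(3L, 2L, 4L)))
  cent <- centralities(g)
  expect_equal(cent$weighted_degree[cent$word == "a"], 3 + 2 + 4)
  expect_equal(cent$degree[cent$word == "a"], 3L)
})

test_that("top_central ranks deterministically with lexicographic ties", {
  tab <- data.frame(word = c("c", "a", "b"),
                    degree = c(2, 2, 2), weighted_degree = c(5, 3, 1),
                    eccentricity = c(3, 2, 4), closeness = 0,
                    harmonic_closeness = 0, betweenness = 0)
  expect_equal(top_central(tab, "degree", 3), c("a", "b", "c"))
  expect_equal(top_central(tab, "weighted_degree", 2), c("c", "a"))
  expect_equal(top_central(tab, "eccentricity", 1), "a")
  expect_equal(top_central(tab, "betweenness", 2, min_value = 1),
               character(0))
  expect_error(top_central(tab, "pagerank", 2), "unknown measure")
})

test_that("ranking overlap returns count and Jaccard fraction", {
  ten <- paste0("w", 1:10)
  expect_equal(ranking_overlap(ten, ten), list(count = 10L, jaccard = 1))
  expect_equal(ranking_overlap(ten, paste0("v", 1:5)),
               list(count = 0L, jaccard = 0))
  a <- paste0("w", 1:10)
  b <- c(paste0("w", 1:8), paste0("v", 1:5))
  ov <- ranking_overlap(a, b)
  expect_equal(ov$count, 8L)
  expect_equal(ov$jaccard, 8 / 15)
  expect_error(ranking_overlap(character(0), a), "non-empty")
})

test_that("mean clustering of uniform digraphs approaches the density", {
  reps <- 12
  vals <- vapply(seq_len(reps), function(r) {
    mean_clustering(random_lag(236, 939, seed = 5000 + r))
  }, numeric(1))
  target <- 939 / (236 * 235)
  se <- sd(vals) / sqrt(reps)
  expect_lt(abs(mean(vals) - target), 3 * se)
})
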