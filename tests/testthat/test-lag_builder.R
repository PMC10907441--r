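test_that("a single chain yields its contiguous directed edges", {
  corp <- fluency_corpus(list(s1 = c("dog", "cat", "lion", "tiger")),
                         "animals")
  g <- build_lag(corp)
  expect_equal(lag_node_count(g), 4L)
  e <- lag_edges(g)
  expect_equal(e[order(e$source), c("source", "target")],
               data.frame(source = c("cat", "dog", "lion"),
                          target = c("lion", "cat", "tiger")),
               ignore_attr = TRUE)
  expect_true(all(e$weight == 1L))
})

test_that("single-word chains contribute a node and no edge", {
  g <- build_lag(fluency_corpus(list(s1 = "dog"), "animals"))
  expect_equal(lag_node_count(g), 1L)
  expect_equal(lag_edge_count(g), 0L)
})

test_that("reverse pairs are distinct edges", {
  corp <- fluency_corpus(list(s1 = c("A", "B", "C"), s2 = c("D", "B", "A")),
                         "x")
  g <- build_lag(corp)
  expect_equal(lag_node_count(g), 4L)
  e <- lag_edges(g)
  expect_equal(nrow(e), 4L)
  key <- paste(e$source, e$target)
  expect_setequal(key, c("A B", "B C", "D B", "B A"))
  expect_true(all(e$weight == 1L))
})

test_that("edge weights count chains containing the pair", {
  corp <- fluency_corpus(list(s1 = c("a", "b", "c"),
                              s2 = c("a", "b"),
                              s3 = c("b", "a")), "x")
  g <- build_lag(corp)
  e <- lag_edges(g)
  expect_equal(e$weight[e$source == "a" & e$target == "b"], 2L)
  expect_equal(e$weight[e$source == "b" & e$target == "a"], 1L)
  # total weight equals the number of transitions
  expect_equal(sum(e$weight), sum(lengths(corp$chains) - 1L))
  # no informant can contribute more than once to a pair
  expect_true(all(e$weight <= informant_count(corp)))
})

test_that("building is additive over corpora", {
  set.seed(7)
  mk <- function(ids) {
    chains <- lapply(ids, function(i) sample(letters[1:10], sample(2:8, 1)))
    names(chains) <- ids
    fluency_corpus(chains, "x")
  }
  ca <- mk(paste0("a", 1:5))
  cb <- mk(paste0("b", 1:5))
  cab <- fluency_corpus(c(ca$chains, cb$chains), "x")
  wa <- lag_edges(build_lag(ca)); wb <- lag_edges(build_lag(cb))
  wab <- lag_edges(build_lag(cab))
  combined <- aggregate(weight ~ source + target, data = rbind(wa, wb), sum)
  merged <- merge(wab, combined, by = c("source", "target"))
  expect_equal(nrow(merged), nrow(wab))
  expect_equal(merged$weight.x, merged$weight.y)
})

test_that("unedited chains with repetitions are refused", {
  corp <- fluency_corpus(list(s1 = c("a", "b", "a")), "x")
  expect_error(build_lag(corp), "edit_corpus")
})

test_that("pruning removes light edges and isolated nodes", {
  e <- data.frame(source = c("a", "b", "c"), target = c("b", "c", "d"),
                  weight = c(1L, 2L, 3L))
  g <- lag_from_edges(e, prompt = "x")
  p <- prune_lag(g, 2L)
  expect_equal(lag_edges(p)$weight, 3L)
  expect_setequal(lag_nodes(p), c("c", "d"))
  # keep isolated endpoints when asked
  p2 <- prune_lag(g, 2L, drop_isolated = FALSE)
  expect_setequal(lag_nodes(p2), c("a", "b", "c", "d"))
  # threshold 0 is the identity; original is untouched
  expect_equal(lag_edges(prune_lag(g, 0L)), lag_edges(g))
  expect_equal(lag_edge_count(g), 3L)
  # threshold at or above the max weight empties the graph
  expect_equal(lag_node_count(prune_lag(g, 3L)), 0L)
  expect_error(prune_lag(g, -1), "non-negative")
})

test_that("pruning is monotone in the threshold", {
  g <- rand_test_lag(9, 0.4, seed = 11)
  prev_nodes <- lag_node_count(g); prev_edges <- lag_edge_count(g)
  for (th in 0:4) {
    p <- prune_lag(g, th)
    expect_lte(lag_node_count(p), prev_nodes)
    expect_lte(lag_edge_count(p), prev_edges)
    prev_nodes <- lag_node_count(p); prev_edges <- lag_edge_count(p)
  }
})

test_that("lag_from_edges validates its input", {
  bad_loop <- data.frame(source = "a", target = "a", weight = 1L)
  expect_error(lag_from_edges(bad_loop), "self-loop")
  bad_w <- data.frame(source = "a", target = "b", weight = 0L)
  expect_error(lag_from_edges(bad_w), "positive integers")
  dup <- data.frame(source = c("a", "a"), target = c("b", "b"),
                    weight = c(1L, 2L))
  expect_error(lag_from_edges(dup), "duplicate")
})

test_that("exports round-trip and are Gephi-compatible formats", {
  g <- rand_test_lag(8, 0.3, seed = 5)
  f_csv <- tempfile(fileext = ".csv")
  write_lag(g, f_csv, "edgelist")
  back <- lag_from_edges(utils::read.csv(f_csv, stringsAsFactors = FALSE),
                         nodes = lag_nodes(g), prompt = g$prompt)
  expect_equal(lag_edges(back), lag_edges(g))
  expect_setequal(lag_nodes(back), lag_nodes(g))

  f_gml <- tempfile(fileext = ".graphml")
  write_lag(g, f_gml, "graphml")
  gg <- igraph::read_graph(f_gml, format = "graphml")
  expect_equal(igraph::ecount(gg), lag_edge_count(g))
  expect_equal(sort(igraph::E(gg)$weight), sort(lag_edges(g)$weight))

  f_gexf <- tempfile(fileext = ".gexf")
  write_lag(g, f_gexf, "gexf")
  doc <- xml2::read_xml(f_gexf)
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:node", ns)),
               lag_node_count(g))
  edges <- xml2::xml_find_all(doc, "//d1:edge", ns)
  expect_equal(length(edges), lag_edge_count(g))
  w <- as.integer(xml2::xml_attr(edges, "weight"))
  expect_equal(sort(w), sort(lag_edges(g)$weight))
})
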