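#' Lexical availability graphs
#'
#' A `lag` is a directed, integer-weighted simple graph whose nodes are word
#' types and whose edges are the contiguous ordered word pairs observed in
#' fluency chains: a chain DOG, CAT, LION, TIGER contributes the three
#' directed edges DOG->CAT, CAT->LION, LION->TIGER. The weight of an edge
#' (a, b) is the number of chains in which b immediately follows a; because
#' chains are duplicate-free this equals the number of informants producing
#' the pair. (a, b) and (b, a) are distinct edges and self-loops cannot
#' occur. The graph may be disconnected.
#'
#' @name lag
NULL

new_lag <- function(graph, prompt) {
  structure(list(graph = graph, prompt = prompt), class = "lag")
}

#' Build the lexical availability graph of a corpus
#'
#' @param corpus an edited [fluency_corpus] (chains must be duplicate-free;
#'   run [edit_corpus()] first).
#' @return A `lag` object. An empty corpus is impossible by construction of
#'   `fluency_corpus`; single-word chains contribute their node and no edge.
#' @examples
#' corp <- fluency_corpus(list(s1 = c("dog", "cat", "lion", "tiger")),
#'                        "animals")
#' g <- build_lag(corp)
#' lag_edges(g)
#' @export
build_lag <- function(corpus) {
  stopifnot(inherits(corpus, "fluency_corpus"))
  dup <- vapply(corpus$chains, anyDuplicated, integer(1)) > 0L
  if (any(dup)) {
    stop("chains contain within-chain repetitions (",
         paste(utils::head(names(corpus$chains)[dup], 3L), collapse = ", "),
         " ...); run edit_corpus() first", call. = FALSE)
  }
  nodes <- sort(unique(unlist(corpus$chains, use.names = FALSE)))
  src <- character(0); dst <- character(0)
  for (w in corpus$chains) {
    if (length(w) >= 2L) {
      src <- c(src, w[-length(w)])
      dst <- c(dst, w[-1L])
    }
  }
  if (length(src) == 0L) {
    g <- igraph::make_empty_graph(directed = TRUE) +
      igraph::vertices(nodes)
    return(new_lag(g, corpus$prompt))
  }
  key <- paste(src, dst, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  el <- cbind(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))
  g <- igraph::graph_from_edgelist(el, directed = TRUE)
  igraph::E(g)$weight <- as.integer(tab)
  iso <- setdiff(nodes, igraph::V(g)$name)
  if (length(iso) > 0L) g <- g + igraph::vertices(iso)
  new_lag(g, corpus$prompt)
}

#' Assemble a lag from an explicit edge list
#'
#' Low-level constructor used when a graph is given directly (printed
#' examples, round-trips of exported edge lists) rather than built from
#' chains.
#'
#' @param edges data.frame with columns `source`, `target`, `weight`
#'   (positive integers); may have zero rows.
#' @param nodes optional character vector of node names; edge endpoints are
#'   always included, extra names become isolated nodes.
#' @param prompt graph label.
#' @return A `lag` object.
#' @export
lag_from_edges <- function(edges, nodes = NULL, prompt = "unlabelled") {
  stopifnot(is.data.frame(edges),
            all(c("source", "target", "weight") %in% names(edges)))
  if (nrow(edges) > 0L) {
    if (any(edges$source == edges$target)) {
      stop("self-loops are not allowed in a lag", call. = FALSE)
    }
    if (any(edges$weight < 1 | edges$weight != trunc(edges$weight))) {
      stop("edge weights must be positive integers", call. = FALSE)
    }
    if (anyDuplicated(paste(edges$source, edges$target, sep = "\r"))) {
      stop("duplicate ordered pairs in edge list", call. = FALSE)
    }
  }
  all_nodes <- sort(unique(c(as.character(edges$source),
                             as.character(edges$target),
                             as.character(nodes %||% character(0)))))
  g <- igraph::make_empty_graph(directed = TRUE) + igraph::vertices(all_nodes)
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(
      g, rbind(as.character(edges$source), as.character(edges$target)),
      weight = as.integer(edges$weight))
  }
  new_lag(g, prompt)
}

#' @export
print.lag <- function(x, ...) {
  cat("<lag> prompt:", x$prompt,
      " nodes:", lag_node_count(x),
      " edges:", lag_edge_count(x), "\n")
  invisible(x)
}

#' Accessors for lag objects
#'
#' @param lag a `lag` object.
#' @return `lag_nodes()`: character vector of node names. `lag_edges()`:
#'   data.frame `source,target,weight`. `lag_node_count()` /
#'   `lag_edge_count()`: integer N and E (weights excluded).
#'   `lag_graph()`: the underlying [igraph][igraph::graph] object.
#' @export
lag_nodes <- function(lag) {
  stopifnot(inherits(lag, "lag"))
  igraph::V(lag$graph)$name
}

#' @rdname lag_nodes
#' @export
lag_edges <- function(lag) {
  stopifnot(inherits(lag, "lag"))
  if (igraph::ecount(lag$graph) == 0L) {
    return(data.frame(source = character(), target = character(),
                      weight = integer(), stringsAsFactors = FALSE))
  }
  el <- igraph::as_edgelist(lag$graph, names = TRUE)
  out <- data.frame(source = el[, 1L], target = el[, 2L],
                    weight = igraph::E(lag$graph)$weight,
                    stringsAsFactors = FALSE)
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname lag_nodes
#' @export
lag_node_count <- function(lag) igraph::vcount(lag$graph)

#' @rdname lag_nodes
#' @export
lag_edge_count <- function(lag) igraph::ecount(lag$graph)

#' @rdname lag_nodes
#' @export
lag_graph <- function(lag) {
  stopifnot(inherits(lag, "lag"))
  lag$graph
}

#' Prune a lag by edge weight
#'
#' Removes every edge whose weight is less than or equal to
#' `max_removed_weight` — i.e. keeps only associations produced by at least
#' `max_removed_weight + 1` informants — and optionally drops the isolated
#' nodes this leaves behind. The input graph is not modified.
#'
#' @param lag a `lag`.
#' @param max_removed_weight non-negative integer; edges with weight at or
#'   below it are removed (`0` leaves the graph unchanged).
#' @param drop_isolated drop nodes with no remaining incident edge
#'   (default `TRUE`).
#' @return The pruned `lag`.
#' @export
prune_lag <- function(lag, max_removed_weight, drop_isolated = TRUE) {
  stopifnot(inherits(lag, "lag"))
  if (length(max_removed_weight) != 1L || max_removed_weight < 0) {
    stop("`max_removed_weight` must be a non-negative integer", call. = FALSE)
  }
  g <- lag$graph
  if (igraph::ecount(g) > 0L) {
    g <- igraph::delete_edges(
      g, igraph::E(g)[igraph::E(g)$weight <= max_removed_weight])
  }
  if (isTRUE(drop_isolated)) {
    g <- igraph::delete_vertices(
      g, igraph::V(g)[igraph::degree(g, mode = "all") == 0])
  }
  new_lag(g, lag$prompt)
}

#' Export a lag
#'
#' Writes the graph as GEXF or GraphML (edge weights as the `weight`
#' attribute, readable by Gephi) or as a weighted edge-list CSV
#' `source,target,weight`.
#'
#' @param lag a `lag`.
#' @param path output file path.
#' @param format `"gexf"`, `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_lag <- function(lag, path, format = c("gexf", "graphml", "edgelist")) {
  stopifnot(inherits(lag, "lag"))
  format <- match.arg(format)
  switch(format,
    graphml = igraph::write_graph(lag$graph, path, format = "graphml"),
    edgelist = utils::write.csv(lag_edges(lag), path, row.names = FALSE,
                                fileEncoding = "UTF-8"),
    gexf = write_gexf(lag, path))
  invisible(path)
}

# Minimal GEXF 1.3 writer: directed graph, string node labels, float edge
# weights. Kept to the subset Gephi needs.
write_gexf <- function(lag, path) {
  nodes <- lag_nodes(lag)
  edges <- lag_edges(lag)
  doc <- xml2::xml_new_root(
    "gexf", xmlns = "http://gexf.net/1.3", version = "1.3")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "directed",
                               mode = "static")
  nd <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_along(nodes)) {
    xml2::xml_add_child(nd, "node", id = nodes[[i]], label = nodes[[i]])
  }
  ed <- xml2::xml_add_child(graph, "edges")
  if (nrow(edges) > 0L) {
    for (i in seq_len(nrow(edges))) {
      xml2::xml_add_child(ed, "edge", id = as.character(i - 1L),
                          source = edges$source[[i]],
                          target = edges$target[[i]],
                          weight = as.character(edges$weight[[i]]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
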