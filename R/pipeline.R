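#' Run the full lexical availability analysis
#'
#' End-to-end orchestration for one prompt: edit the corpus, build the
#' graph (optionally also a weight-pruned version), and for each graph
#' compute the structural summary, the centrality table with top-k lists
#' and their pairwise overlaps, the modularity communities with the
#' anchor-word cluster table, and the matched-random small-world report;
#' the availability index is computed on the corpus. All tables are written
#' as CSV/JSON plus GEXF/GraphML exports, and a manifest records the
#' configuration and seeds needed to reproduce the bundle exactly.
#'
#' @param corpus a [fluency_corpus]; alternatively give `input`.
#' @param input path to a chain file, read with [read_chains()].
#' @param dialect,prompt passed to [read_chains()] when `input` is used.
#' @param out_dir output directory (created if needed).
#' @param rules [edit_rules()] applied before analysis.
#' @param prune_threshold if non-`NULL`, additionally analyse the graph
#'   pruned at this maximum removed weight (results under `pruned/`).
#' @param path_mode path-statistics mode for summaries and the small-world
#'   verdict.
#' @param resolution,community_seed community detection parameters.
#' @param null_replicates,null_seed small-world ensemble parameters.
#' @param top_k length of the per-measure top-central word lists.
#' @param min_community_size smallest community kept in the cluster table.
#' @return Invisibly, the report bundle: a named list with the corpus and
#'   every computed object (`lag`, `metrics`, `centralities`, `top_lists`,
#'   `overlaps`, `partition`, `clusters`, `availability`, `small_world`,
#'   `pruned` when requested, `manifest`, `out_dir`).
#' @export
run_pipeline <- function(corpus = NULL, input = NULL,
                         dialect = c("long", "lines"), prompt = NULL,
                         out_dir, rules = edit_rules(),
                         prune_threshold = NULL,
                         path_mode = c("directed", "undirected"),
                         resolution = 1, community_seed = 1L,
                         null_replicates = 50L, null_seed = 1L,
                         top_k = 10L, min_community_size = 1L) {
  path_mode <- match.arg(path_mode)
  dialect <- match.arg(dialect)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.null(corpus)) {
    if (is.null(input)) stop("give either `corpus` or `input`", call. = FALSE)
    corpus <- stage("ingest", read_chains(input, dialect, prompt = prompt))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  edited <- stage("edit", edit_corpus(corpus, rules))
  write_edit_log(edited, file.path(out_dir, "edit_log.csv"))

  lag <- stage("build", build_lag(edited))
  availability <- stage("availability", lexical_availability(edited))
  utils::write.csv(availability, file.path(out_dir, "availability.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")

  analyse <- function(g, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    metrics <- stage("metrics", metrics_summary(g, mode = path_mode))
    cent <- stage("centralities", centralities(g))
    top_lists <- lapply(stats::setNames(nm = centrality_measures),
                        function(ms) top_central(cent, ms, top_k))
    pairs <- utils::combn(centrality_measures, 2L)
    overlaps <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      ov <- ranking_overlap(top_lists[[pairs[1L, i]]],
                            top_lists[[pairs[2L, i]]])
      data.frame(measure_a = pairs[1L, i], measure_b = pairs[2L, i],
                 count = ov$count, jaccard = ov$jaccard,
                 stringsAsFactors = FALSE)
    }))
    partition <- stage("communities",
                       detect_communities(g, resolution = resolution,
                                          seed = community_seed))
    clusters <- cluster_table(g, partition, min_size = min_community_size)
    sw <- stage("null_models",
                small_world_report(g, replicates = null_replicates,
                                   seed = null_seed, mode = path_mode))

    utils::write.csv(cent, file.path(dir, "centralities.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    top_df <- do.call(rbind, lapply(names(top_lists), function(ms) {
      data.frame(measure = ms, rank = seq_along(top_lists[[ms]]),
                 word = top_lists[[ms]], stringsAsFactors = FALSE)
    }))
    utils::write.csv(top_df, file.path(dir, "top_central.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(overlaps, file.path(dir, "ranking_overlaps.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(clusters, file.path(dir, "communities.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    jsonlite::write_json(unclass(metrics), file.path(dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      list(assignment = as.list(partition$assignment),
           modularity_score = partition$modularity_score,
           resolution = partition$resolution, seed = partition$seed),
      file.path(dir, "partition.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      list(observed = sw$observed, random = sw$random,
           clustering_ratio = sw$clustering_ratio,
           path_ratio = sw$path_ratio, small_world = sw$small_world,
           replicates = sw$replicates, seed = sw$seed, mode = sw$mode,
           thresholds = sw$thresholds),
      file.path(dir, "small_world.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_lag(g, file.path(dir, "lag.gexf"), "gexf")
    write_lag(g, file.path(dir, "lag.graphml"), "graphml")
    write_lag(g, file.path(dir, "lag_edges.csv"), "edgelist")
    list(lag = g, metrics = metrics, centralities = cent,
         top_lists = top_lists, overlaps = overlaps, partition = partition,
         clusters = clusters, small_world = sw)
  }

  bundle <- analyse(lag, out_dir)
  if (!is.null(prune_threshold)) {
    pruned_lag <- stage("prune", prune_lag(lag, prune_threshold))
    bundle$pruned <- analyse(pruned_lag, file.path(out_dir, "pruned"))
  }
  manifest <- list(
    schema_version = "1",
    package_version = as.character(utils::packageVersion("lexavail")),
    prompt = edited$prompt,
    informants = informant_count(edited),
    rules = unclass(rules),
    prune_threshold = prune_threshold,
    path_mode = path_mode,
    resolution = resolution,
    community_seed = community_seed,
    null_replicates = null_replicates,
    null_seed = null_seed,
    top_k = top_k,
    min_community_size = min_community_size)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bundle$corpus <- edited
  bundle$availability <- availability
  bundle$manifest <- manifest
  bundle$out_dir <- out_dir
  invisible(bundle)
}

#' Synthetic quickstart run
#'
#' Generates a synthetic fluency corpus at the generator defaults (5
#' clusters of 12 words, 100 informants, mean chain length 14, switch
#' probability 0.08, erratic rate 0.03) and runs the whole pipeline on it,
#' including a weight-2 pruning pass. The planted ground truth is attached
#' so recovery can be inspected.
#'
#' @param seed integer seed driving the generator and every stochastic
#'   stage.
#' @param out_dir output directory (default: fresh directory under the
#'   session temp dir).
#' @param null_replicates small-world ensemble size (default 50).
#' @return Invisibly, the [run_pipeline()] bundle with an extra
#'   `ground_truth` element.
#' @export
lag_demo <- function(seed = 1L, out_dir = tempfile("lag_demo"),
                     null_replicates = 50L) {
  seed <- check_seed(seed)
  lex <- make_lexicon(seed = seed)
  corpus <- simulate_chains(lex, seed = seed)
  bundle <- run_pipeline(corpus, out_dir = out_dir, prune_threshold = 2L,
                         community_seed = seed, null_seed = seed,
                         null_replicates = null_replicates)
  bundle$ground_truth <- ground_truth(lex)
  invisible(bundle)
}
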