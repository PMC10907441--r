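#' Synthetic modular lexicon
#'
#' Builds the ground-truth lexicon the chain simulator walks over: a set of
#' disjoint semantic clusters, each with one high-availability anchor word
#' and geometrically decaying retrieval weights for the remaining members.
#' This emulates the graded availability observed in fluency data, where a
#' few anchor words dominate production within each semantic field.
#'
#' @param n_clusters number of clusters (default 5).
#' @param cluster_size words per cluster (default 12).
#' @param anchor_boost anchor weight as a multiple of the next-heaviest
#'   word's weight (default 3; 1 gives flat anchors).
#' @param weight_ratio geometric ratio of successive non-anchor weights
#'   (default 0.75, a Zipf-like decay).
#' @param seed integer seed recorded for provenance (the construction is
#'   deterministic).
#' @return An object of class `synthetic_lexicon`: list with `clusters`
#'   (list of named weight vectors, one per cluster; names are the words),
#'   `cluster_weights` (relative entry probabilities, uniform), `seed`.
#' @export
make_lexicon <- function(n_clusters = 5L, cluster_size = 12L,
                         anchor_boost = 3, weight_ratio = 0.75, seed = 1L) {
  seed <- check_seed(seed)
  if (n_clusters < 1L || cluster_size < 1L) {
    stop("need at least 1 cluster of at least 1 word", call. = FALSE)
  }
  if (anchor_boost <= 0 || weight_ratio <= 0) {
    stop("`anchor_boost` and `weight_ratio` must be positive", call. = FALSE)
  }
  clusters <- lapply(seq_len(n_clusters), function(c) {
    words <- sprintf("c%02dw%02d", c, seq_len(cluster_size))
    w <- if (cluster_size == 1L) {
      anchor_boost
    } else {
      tail_w <- weight_ratio^(0:(cluster_size - 2L))
      c(anchor_boost * tail_w[[1L]], tail_w)
    }
    names(w) <- words
    w
  })
  structure(list(clusters = clusters,
                 cluster_weights = rep(1, n_clusters),
                 seed = seed),
            class = "synthetic_lexicon")
}

#' @export
print.synthetic_lexicon <- function(x, ...) {
  cat("<synthetic_lexicon>", length(x$clusters), "clusters,",
      sum(lengths(x$clusters)), "words\n")
  invisible(x)
}

#' Planted ground truth of a synthetic lexicon
#'
#' @param lexicon a [make_lexicon()] result.
#' @return List with `partition` (named integer vector, word -> planted
#'   cluster id from 0), `anchors` (character vector, the max-weight word
#'   of each cluster) and `weights` (named vector of planted retrieval
#'   weights), for recovery scoring against detected communities.
#' @export
ground_truth <- function(lexicon) {
  stopifnot(inherits(lexicon, "synthetic_lexicon"))
  partition <- integer(0)
  anchors <- character(length(lexicon$clusters))
  for (c in seq_along(lexicon$clusters)) {
    w <- lexicon$clusters[[c]]
    ids <- rep(c - 1L, length(w))
    names(ids) <- names(w)
    partition <- c(partition, ids)
    best <- names(w)[w == max(w)]
    anchors[[c]] <- sort(best)[[1L]]
  }
  list(partition = partition, anchors = anchors,
       weights = unlist(unname(lexicon$clusters)))
}

#' Simulate fluency response chains
#'
#' Generates one chain per informant by a clustered retrieval walk over the
#' lexicon: the informant enters a cluster (probability proportional to
#' `cluster_weights`), samples words within it without replacement with
#' probability proportional to the planted weights, and after each word
#' either jumps erratically to a uniformly random unused word anywhere in
#' the lexicon (probability `erratic_rate`), or switches to a fresh cluster
#' (probability `p_switch`, and always when the current cluster is
#' exhausted), or continues in the current cluster. Chains therefore
#' contain no repetitions by construction. Chain lengths follow a shifted
#' negative binomial (minimum 1), truncated at vocabulary exhaustion.
#'
#' @param lexicon a [make_lexicon()] result.
#' @param n_informants number of chains (default 100).
#' @param mean_length mean chain length (default 14).
#' @param dispersion negative-binomial size parameter of the length
#'   distribution; smaller values give more variable lengths (default 6,
#'   putting most lengths between roughly 5 and 25).
#' @param p_switch per-step cluster-switch probability (default 0.08).
#' @param erratic_rate per-step probability of a uniform jump to any unused
#'   word (default 0.03).
#' @param seed integer RNG seed; the corpus is deterministic given the
#'   seed.
#' @param prompt label of the generated corpus (default `"synthetic"`).
#' @return A [fluency_corpus] with informants `s001, s002, ...`.
#' @export
simulate_chains <- function(lexicon, n_informants = 100L, mean_length = 14,
                            dispersion = 6, p_switch = 0.08,
                            erratic_rate = 0.03, seed = 1L,
                            prompt = "synthetic") {
  stopifnot(inherits(lexicon, "synthetic_lexicon"))
  seed <- check_seed(seed)
  if (n_informants < 1L) stop("`n_informants` must be >= 1", call. = FALSE)
  if (p_switch < 0 || p_switch > 1 || erratic_rate < 0 || erratic_rate > 1) {
    stop("`p_switch` and `erratic_rate` must be probabilities", call. = FALSE)
  }
  if (mean_length < 1) stop("`mean_length` must be >= 1", call. = FALSE)
  word_cluster <- ground_truth(lexicon)$partition + 1L
  vocab <- names(word_cluster)
  weights <- unlist(unname(lexicon$clusters))[vocab]
  n_clusters <- length(lexicon$clusters)

  chains <- with_seed(seed, {
    out <- vector("list", n_informants)
    for (inf in seq_len(n_informants)) {
      L <- 1L + stats::rnbinom(1L, size = dispersion, mu = mean_length - 1)
      L <- min(L, length(vocab))
      unused <- rep(TRUE, length(vocab))
      pick_cluster <- function(exclude = 0L) {
        open <- which(vapply(seq_len(n_clusters), function(c) {
          any(unused[word_cluster == c])
        }, logical(1)))
        cand <- setdiff(open, exclude)
        if (length(cand) == 0L) cand <- open
        if (length(cand) == 1L) return(cand)
        sample(cand, 1L, prob = lexicon$cluster_weights[cand])
      }
      pick_word <- function(cluster) {
        pool <- which(unused & word_cluster == cluster)
        if (length(pool) == 1L) return(pool)
        sample(pool, 1L, prob = weights[pool])
      }
      cur <- pick_cluster()
      chain <- integer(L)
      for (t in seq_len(L)) {
        if (!any(unused)) { chain <- chain[seq_len(t - 1L)]; break }
        if (t > 1L && stats::runif(1L) < erratic_rate) {
          pool <- which(unused)
          w_i <- if (length(pool) == 1L) pool else sample(pool, 1L)
          cur <- word_cluster[[w_i]]
        } else {
          if (t > 1L && (stats::runif(1L) < p_switch ||
                         !any(unused[word_cluster == cur]))) {
            cur <- pick_cluster(exclude = cur)
          } else if (!any(unused[word_cluster == cur])) {
            cur <- pick_cluster(exclude = cur)
          }
          w_i <- pick_word(cur)
        }
        chain[[t]] <- w_i
        unused[[w_i]] <- FALSE
      }
      out[[inf]] <- vocab[chain]
    }
    names(out) <- sprintf("s%03d", seq_len(n_informants))
    out
  })
  fluency_corpus(chains, prompt)
}
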