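#' Positional frequency profiles
#'
#' Tallies, for every word of a corpus, how many chains produced it at each
#' list position: f[j, i] is the number of informants who wrote word j as
#' their i-th response. The column count n is the length of the longest
#' chain in the sample.
#'
#' @param corpus an edited [fluency_corpus].
#' @return Integer matrix (words x positions) with attributes `I_1` (the
#'   informant count) and `n` (maximal position in the sample). Rows are in
#'   alphabetical word order.
#' @export
positional_frequencies <- function(corpus) {
  stopifnot(inherits(corpus, "fluency_corpus"))
  n <- max(lengths(corpus$chains))
  words <- sort(unique(unlist(corpus$chains, use.names = FALSE)))
  f <- matrix(0L, nrow = length(words), ncol = n,
              dimnames = list(words, seq_len(n)))
  for (w in corpus$chains) {
    idx <- cbind(match(w, words), seq_along(w))
    f[idx] <- f[idx] + 1L
  }
  attr(f, "I_1") <- informant_count(corpus)
  attr(f, "n") <- n
  f
}

#' Lexical availability index
#'
#' The availability of a word combines how often and how early it is
#' produced: positional frequencies are discounted by an exponential decay
#' in list position and normalised by the informant count,
#'
#'   D(j) = sum_i exp(-decay * (i - 1) / (n - 1)) * f\[j, i\] / I_1,
#'
#' with decay = 2.3 by default. A word produced first by every informant
#' scores exactly 1; D never exceeds the word's relative frequency. When
#' n = 1 the exponent is taken as 0 (limit convention), so D reduces to
#' relative frequency.
#'
#' @param freqs a positional frequency matrix from
#'   [positional_frequencies()], or any integer matrix with positions as
#'   columns.
#' @param I_1 informant count used for normalisation; defaults to the
#'   matrix's `I_1` attribute.
#' @param decay positive decay constant (default 2.3, the convention of the
#'   classical availability formula).
#' @param per_word_n use each word's own maximal attested position as n
#'   instead of the sample-wide maximum (default `FALSE`, the sample-wide
#'   convention).
#' @return data.frame `rank, word, availability, total_frequency,
#'   max_position`, sorted by availability descending (ties broken
#'   lexicographically).
#' @examples
#' corp <- fluency_corpus(list(s1 = c("a", "b"), s2 = c("b", "a")), "demo")
#' availability_index(positional_frequencies(corp))
#' @export
availability_index <- function(freqs, I_1 = attr(freqs, "I_1"), decay = 2.3,
                               per_word_n = FALSE) {
  stopifnot(is.matrix(freqs))
  if (is.null(I_1) || I_1 < 1) stop("`I_1` must be a positive informant count",
                                    call. = FALSE)
  if (decay <= 0) stop("`decay` must be positive", call. = FALSE)
  if (any(freqs < 0) || any(freqs != trunc(freqs))) {
    stop("frequencies must be non-negative integers", call. = FALSE)
  }
  n <- ncol(freqs)
  words <- rownames(freqs)
  max_pos <- apply(freqs, 1L, function(row) {
    hit <- which(row > 0)
    if (length(hit) == 0L) 0L else max(hit)
  })
  pos_weight <- function(n_eff) {
    i <- seq_len(n)
    if (n_eff <= 1L) ifelse(i == 1L, 1, 0) else
      exp(-decay * (i - 1) / (n_eff - 1))
  }
  D <- if (per_word_n) {
    vapply(seq_along(words), function(j) {
      sum(pos_weight(max_pos[[j]]) * freqs[j, ]) / I_1
    }, numeric(1))
  } else {
    as.numeric(freqs %*% pos_weight(n)) / I_1
  }
  ord <- order(-D, words)
  out <- data.frame(rank = seq_along(words), word = words[ord],
                    availability = D[ord],
                    total_frequency = as.integer(rowSums(freqs))[ord],
                    max_position = as.integer(max_pos)[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Availability index straight from a corpus
#'
#' Convenience wrapper: [positional_frequencies()] followed by
#' [availability_index()].
#'
#' @inheritParams availability_index
#' @param corpus an edited [fluency_corpus].
#' @return See [availability_index()].
#' @export
lexical_availability <- function(corpus, decay = 2.3, per_word_n = FALSE) {
  availability_index(positional_frequencies(corpus), decay = decay,
                     per_word_n = per_word_n)
}
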