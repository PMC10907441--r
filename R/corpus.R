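#' Fluency-task corpora
#'
#' A `fluency_corpus` holds the response chains of one elicitation prompt:
#' for each informant, the ordered sequence of distinct words they produced
#' for that cue (e.g. "animals"). It is the raw unit from which lexical
#' availability graphs and availability indices are computed.
#'
#' @param chains named list; one character vector of word tokens per
#'   informant, named by informant id, in production order.
#' @param prompt single string labelling the cue category.
#' @return An object of class `fluency_corpus`: a list with elements
#'   `prompt` (string) and `chains` (named list of character vectors).
#'   `informant_count()` gives the number of informants.
#' @examples
#' fluency_corpus(list(s1 = c("dog", "cat"), s2 = c("cat", "lion")), "animals")
#' @export
fluency_corpus <- function(chains, prompt) {
  if (length(prompt) != 1L || !is.character(prompt) || !nzchar(prompt)) {
    stop("`prompt` must be a single non-empty string", call. = FALSE)
  }
  if (!is.list(chains) || length(chains) == 0L) {
    stop("`chains` must be a non-empty list of character vectors",
         call. = FALSE)
  }
  ids <- names(chains)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every chain must be named by its informant id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("at most one chain per informant per prompt; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  for (id in ids) {
    w <- chains[[id]]
    if (!is.character(w) || length(w) < 1L) {
      stop("chain for informant '", id,
           "' must be a character vector of length >= 1", call. = FALSE)
    }
    if (any(!nzchar(trimws(w)))) {
      stop("chain for informant '", id, "' contains empty tokens",
           call. = FALSE)
    }
  }
  structure(list(prompt = prompt, chains = chains),
            class = "fluency_corpus")
}

#' @export
print.fluency_corpus <- function(x, ...) {
  lens <- lengths(x$chains)
  cat("<fluency_corpus> prompt:", x$prompt, "\n")
  cat("  informants:", length(x$chains),
      " chain lengths:", min(lens), "-", max(lens),
      " (mean", round(mean(lens), 1), ")\n")
  invisible(x)
}

#' Number of informants in a corpus
#'
#' @param corpus a [fluency_corpus].
#' @return Integer count of distinct informants (the `I1` of the
#'   availability-index normalisation).
#' @export
informant_count <- function(corpus) {
  stopifnot(inherits(corpus, "fluency_corpus"))
  length(corpus$chains)
}

#' Read fluency response chains from a text file
#'
#' Two dialects are supported. `"long"` is a CSV/TSV table with header
#' `informant_id,prompt,position,word`, one row per produced word;
#' positions must be contiguous 1..L within each chain. `"lines"` has one
#' chain per line, `informant_id: w1, w2, ...`.
#'
#' @param path path to the input file (UTF-8).
#' @param dialect `"long"` or `"lines"`.
#' @param prompt for multi-prompt long files, which prompt to load. For the
#'   lines dialect this labels the corpus (default `"unknown"`).
#' @param sep field separator for the long dialect; guessed from the header
#'   line (tab if present, comma otherwise) when `NULL`.
#' @return A [fluency_corpus]. Malformed rows abort with the offending
#'   line number.
#' @export
read_chains <- function(path, dialect = c("long", "lines"), prompt = NULL,
                        sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0L) stop("empty corpus: no data in ", path, call. = FALSE)
  if (dialect == "long") {
    read_chains_long(raw, path, prompt, sep)
  } else {
    read_chains_lines(raw, prompt %||% "unknown")
  }
}

read_chains_long <- function(raw, path, prompt, sep) {
  if (is.null(sep)) sep <- if (grepl("\t", raw[[1L]])) "\t" else ","
  tab <- utils::read.table(text = raw, header = TRUE, sep = sep,
                           quote = "\"", stringsAsFactors = FALSE,
                           fileEncoding = "", comment.char = "")
  need <- c("informant_id", "prompt", "position", "word")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("format error: missing column(s) ", paste(miss, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  tab$.line <- seq_len(nrow(tab)) + 1L  # header is line 1
  if (!is.numeric(tab$position) || any(tab$position != trunc(tab$position))) {
    bad <- tab$.line[which(is.na(suppressWarnings(as.integer(tab$position))) |
                             tab$position != trunc(tab$position))[1L]]
    stop("format error: non-integer position at line ", bad, call. = FALSE)
  }
  prompts <- unique(tab$prompt)
  if (is.null(prompt)) {
    if (length(prompts) > 1L) {
      stop("file contains multiple prompts (",
           paste(prompts, collapse = ", "),
           "); pass `prompt =` to select one", call. = FALSE)
    }
    prompt <- prompts
  } else {
    tab <- tab[tab$prompt == prompt, , drop = FALSE]
    if (nrow(tab) == 0L) {
      stop("empty corpus: no rows for prompt '", prompt, "'", call. = FALSE)
    }
  }
  key <- paste(tab$informant_id, tab$position, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- tab$.line[duplicated(key)][1L]
    stop("format error: duplicate (informant, prompt, position) at line ",
         bad, call. = FALSE)
  }
  chains <- list()
  for (id in unique(tab$informant_id)) {
    rows <- tab[tab$informant_id == id, , drop = FALSE]
    rows <- rows[order(rows$position), , drop = FALSE]
    expected <- seq_len(nrow(rows))
    if (!identical(as.integer(rows$position), as.integer(expected))) {
      off <- which(rows$position != expected)[1L]
      stop("format error: positions for informant '", id,
           "' are not contiguous 1..L (line ", rows$.line[off], ")",
           call. = FALSE)
    }
    chains[[as.character(id)]] <- trimws(as.character(rows$word))
  }
  fluency_corpus(chains, prompt)
}

read_chains_lines <- function(raw, prompt) {
  chains <- list()
  for (i in seq_along(raw)) {
    line <- raw[[i]]
    colon <- regexpr(":", line, fixed = TRUE)
    if (colon < 0L) {
      stop("format error: line ", i, " has no 'informant_id:' prefix",
           call. = FALSE)
    }
    id <- trimws(substr(line, 1L, colon - 1L))
    words <- trimws(strsplit(substr(line, colon + 1L, nchar(line)),
                             ",", fixed = TRUE)[[1L]])
    words <- words[nzchar(words)]
    if (!nzchar(id) || length(words) == 0L) {
      stop("format error: empty informant id or word list at line ", i,
           call. = FALSE)
    }
    if (!is.null(chains[[id]])) {
      stop("format error: informant '", id, "' appears twice (line ", i, ")",
           call. = FALSE)
    }
    chains[[id]] <- words
  }
  fluency_corpus(chains, prompt)
}

#' Editing rules for fluency corpora
#'
#' Mirrors the hand-editing conventions of lexical availability studies:
#' within-informant repetitions are discarded (first occurrence kept),
#' multi-word responses are joined into a single token (e.g. `fresh-air`),
#' spelling is corrected through an explicit user-supplied table, and case
#' is folded so the analysis is case-insensitive. Spelling correction is
#' deliberately table-driven, never automatic.
#'
#' @param lowercase fold tokens to lower case (default `TRUE`).
#' @param dedupe_within_chain drop repeated words within a chain, keeping
#'   the first occurrence (default `TRUE`).
#' @param multiword_joiner single non-space token used to join internal
#'   whitespace (default `"-"`).
#' @param spelling_map optional named character vector `c(wrong = "right")`
#'   applied token-wise before joining and case folding.
#' @return An object of class `edit_rules`.
#' @export
edit_rules <- function(lowercase = TRUE, dedupe_within_chain = TRUE,
                       multiword_joiner = "-", spelling_map = NULL) {
  if (length(multiword_joiner) != 1L || !nzchar(multiword_joiner) ||
      grepl("\\s", multiword_joiner)) {
    stop("`multiword_joiner` must be a single non-space token", call. = FALSE)
  }
  if (!is.null(spelling_map)) {
    if (!is.character(spelling_map) || is.null(names(spelling_map)) ||
        any(!nzchar(names(spelling_map))) || any(!nzchar(spelling_map))) {
      stop("`spelling_map` must be a named character vector with non-empty ",
           "keys and values", call. = FALSE)
    }
  }
  structure(list(lowercase = isTRUE(lowercase),
                 dedupe_within_chain = isTRUE(dedupe_within_chain),
                 multiword_joiner = multiword_joiner,
                 spelling_map = spelling_map),
            class = "edit_rules")
}

#' Apply editing rules to a corpus
#'
#' Per chain, tokens are trimmed, corrected through `spelling_map`, internal
#' whitespace is replaced by the joiner, case is optionally folded, and
#' within-chain repetitions are removed keeping the first occurrence.
#' Positions recompact to 1..L so downstream positional indices see gap-free
#' ranks. A chain emptied by editing is dropped with a warning.
#'
#' The operation is idempotent: editing an already edited corpus is a no-op.
#'
#' @param corpus a [fluency_corpus].
#' @param rules an [edit_rules] object.
#' @return The edited [fluency_corpus], with attribute `"edit_log"`: a
#'   data.frame (`informant_id`, `original`, `edited`, `rule`) recording
#'   every change. Write it out with [write_edit_log()].
#' @examples
#' corp <- fluency_corpus(list(s1 = c("Dog", "cat", "dog", "fresh air")),
#'                        "countryside")
#' edited <- edit_corpus(corp, edit_rules())
#' edited$chains$s1  # "dog" "cat" "fresh-air"
#' @export
edit_corpus <- function(corpus, rules = edit_rules()) {
  stopifnot(inherits(corpus, "fluency_corpus"))
  if (!inherits(rules, "edit_rules")) stop("`rules` must be edit_rules()")
  log <- list()
  note <- function(id, orig, new, rule) {
    log[[length(log) + 1L]] <<- data.frame(
      informant_id = id, original = orig, edited = new, rule = rule,
      stringsAsFactors = FALSE)
  }
  out <- list()
  for (id in names(corpus$chains)) {
    w <- trimws(corpus$chains[[id]])
    if (!is.null(rules$spelling_map)) {
      hit <- w %in% names(rules$spelling_map)
      if (any(hit)) {
        fixed <- unname(rules$spelling_map[w[hit]])
        for (k in which(hit)) note(id, w[k], rules$spelling_map[[w[k]]],
                                   "spelling")
        w[hit] <- fixed
      }
    }
    multi <- grepl("\\s", w)
    if (any(multi)) {
      joined <- gsub("\\s+", rules$multiword_joiner, w[multi])
      for (k in seq_along(joined)) note(id, w[multi][k], joined[k],
                                        "multiword_join")
      w[multi] <- joined
    }
    if (rules$lowercase) {
      low <- tolower(w)
      for (k in which(low != w)) note(id, w[k], low[k], "lowercase")
      w <- low
    }
    if (rules$dedupe_within_chain) {
      dup <- duplicated(w)
      for (k in which(dup)) note(id, w[k], NA_character_, "dedupe")
      w <- w[!dup]
    }
    w <- w[nzchar(w)]
    if (length(w) == 0L) {
      warning("chain for informant '", id, "' emptied by editing; dropped",
              call. = FALSE)
      note(id, NA_character_, NA_character_, "chain_dropped")
      next
    }
    out[[id]] <- w
  }
  if (length(out) == 0L) stop("editing removed every chain", call. = FALSE)
  res <- fluency_corpus(out, corpus$prompt)
  attr(res, "edit_log") <- if (length(log) > 0L) {
    do.call(rbind, log)
  } else {
    data.frame(informant_id = character(), original = character(),
               edited = character(), rule = character(),
               stringsAsFactors = FALSE)
  }
  res
}

#' Write the edit log of an edited corpus as CSV
#'
#' @param corpus a corpus returned by [edit_corpus()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_edit_log <- function(corpus, path) {
  log <- attr(corpus, "edit_log")
  if (is.null(log)) stop("corpus has no edit log; run edit_corpus() first",
                         call. = FALSE)
  utils::write.csv(log, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a corpus in the long dialect
#'
#' Emits the same `informant_id,prompt,position,word` CSV that
#' [read_chains()] consumes, so simulated corpora round-trip through the
#' reader.
#'
#' @param corpus a [fluency_corpus].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "fluency_corpus"))
  rows <- lapply(names(corpus$chains), function(id) {
    w <- corpus$chains[[id]]
    data.frame(informant_id = id, prompt = corpus$prompt,
               position = seq_along(w), word = w, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
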