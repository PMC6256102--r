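# Shared matching infrastructure: a "match session" holds per-tree match
# indexes plus two caches keyed over a fixed tree list:
#   - prefix_env:  word prefix -> logical vector "tree contains a word with
#                  this prefix" (a necessary condition for any pattern that
#                  constrains that word)
#   - match_env:   canonical pattern text -> logical vector of full matcher
#                  results
# Learned patterns only constrain words with literal prefixes, so the cheap
# containment test prunes almost every (pattern, tree) pair before the
# matcher runs; results are cached so cross-validation folds share work.

build_match_session <- function(trees) {
  s <- new.env(parent = emptyenv())
  s$trees <- trees
  s$n <- length(trees)
  s$words <- lapply(trees, function(t) unique(tolower(t$word)))
  s$all_words <- unlist(s$words, use.names = FALSE)
  s$word_tree <- rep.int(seq_len(s$n), lengths(s$words))
  s$idxs <- vector("list", s$n)
  s$prefix_env <- new.env(parent = emptyenv())
  s$match_env <- new.env(parent = emptyenv())
  s$extract_cache <- new.env(parent = emptyenv())
  s
}

session_idx <- function(s, i) {
  idx <- s$idxs[[i]]
  if (is.null(idx)) {
    idx <- tree_match_index(s$trees[[i]])
    s$idxs[[i]] <- idx
  }
  idx
}

session_prefix_hits <- function(s, prefix, exact = FALSE) {
  key <- paste0(if (exact) "=" else "^", prefix)
  hits <- s$prefix_env[[key]]
  if (is.null(hits)) {
    w <- if (exact) s$all_words == prefix else startsWith(s$all_words, prefix)
    hits <- logical(s$n)
    hits[s$word_tree[w]] <- TRUE
    s$prefix_env[[key]] <- hits
  }
  hits
}

# word constraints usable for containment pre-filtering
collect_word_filters <- function(node) {
  out <- list()
  cns <- node$constraints$word
  if (!is.null(cns)) {
    if (!is.null(cns$prefix)) {
      out[[1]] <- list(prefix = cns$prefix, exact = FALSE)
    } else if (cns$type == "exact") {
      out[[1]] <- list(prefix = cns$lc, exact = TRUE)
    }
  }
  for (rc in node$children) {
    out <- c(out, collect_word_filters(rc$node))
  }
  out
}

# logical vector over the session's trees: does `pattern` match each tree?
session_pattern_hits <- function(s, pattern) {
  key <- pattern$text
  hits <- s$match_env[[key]]
  if (!is.null(hits)) return(hits)
  cand <- rep(TRUE, s$n)
  for (f in collect_word_filters(pattern$root)) {
    cand <- cand & session_prefix_hits(s, f$prefix, f$exact)
    if (!any(cand)) break
  }
  hits <- logical(s$n)
  for (i in which(cand)) {
    idx <- session_idx(s, i)
    for (j in seq_len(idx$n)) {
      if (match_at(pattern$root, j, idx)) { hits[i] <- TRUE; break }
    }
  }
  s$match_env[[key]] <- hits
  hits
}
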