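#' Rank words by information gain for one class label
#'
#' Binarizes the corpus labels for `class_id` into target-vs-rest and scores
#' every lowercased word type by the Shannon information gain of its
#' presence/absence indicator against the binary label,
#' `IG(w) = H(label) - H(label | w present)`. Sentences whose label for the
#' class is `NA` (dropped at load time) are excluded. Ties are broken
#' lexicographically.
#'
#' @param corpus A [dtc_corpus()].
#' @param class_id Declared class id.
#' @param target_label The label value (`"x"` or `"y"`) to binarize against.
#' @param n Number of words to return (all distinct words if fewer exist).
#' @return A tibble with columns `word` and `gain`, ordered by decreasing
#'   gain then word.
#' @export
information_gain_words <- function(corpus, class_id, target_label, n = 30) {
  labels <- corpus[[class_id]]
  keep <- !is.na(labels)
  labels <- labels[keep]
  trees <- corpus$tree[keep]
  if (length(labels) == 0L) stop("corpus has no usable sentences for class '",
                                 class_id, "'", call. = FALSE)
  target <- labels == target_label
  sent_words <- lapply(trees, function(t) unique(tolower(t$word)))
  word <- unlist(sent_words, use.names = FALSE)
  in_target <- rep(target, lengths(sent_words))
  n_tot <- length(labels)
  n_t <- sum(target)
  present_t <- tapply(in_target, word, sum)
  present <- tapply(in_target, word, length)
  words <- names(present)
  a <- as.vector(present_t)            # target sentences containing w
  b <- as.vector(present) - a          # rest sentences containing w
  c_ <- n_t - a
  d <- (n_tot - n_t) - b
  h <- function(p) ifelse(p <= 0 | p >= 1, 0, -p * log2(p) - (1 - p) * log2(1 - p))
  h_prior <- h(n_t / n_tot)
  p_pres <- (a + b) / n_tot
  h_cond <- p_pres * h(ifelse(a + b > 0, a / (a + b), 0)) +
    (1 - p_pres) * h(ifelse(c_ + d > 0, c_ / (c_ + d), 0))
  gain <- h_prior - h_cond
  ord <- order(-gain, words, method = "radix")
  out <- tibble::tibble(word = words[ord], gain = gain[ord])
  utils::head(out, n)
}

#' Weighted accuracy of one pattern on a class training set
#'
#' A pattern paired with label `label` handles a sentence correctly when it
#' matches a sentence whose gold label equals `label`, or does not match a
#' sentence whose gold label differs. The per-label accuracy is the fraction
#' of sentences of that gold label handled correctly; the weighted accuracy
#' is the unweighted mean of the three per-label accuracies, so rare labels
#' count as much as the dominant neutral label. A label with no sentences
#' contributes accuracy 1 (the pattern cannot err on absent instances).
#'
#' @inheritParams information_gain_words
#' @param pattern A [parse_pattern()] result or pattern text.
#' @param label The label value the pattern predicts (`"x"` or `"y"`).
#' @return Numeric score in `[0, 1]`, with the three per-label accuracies in
#'   the `"per_label"` attribute.
#' @export
pattern_weighted_accuracy <- function(pattern, label, corpus, class_id) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  labels <- corpus[[class_id]]
  keep <- !is.na(labels)
  if (!any(keep)) stop("corpus has no usable sentences for class '",
                       class_id, "'", call. = FALSE)
  labels <- labels[keep]
  idxs <- lapply(corpus$tree[keep], tree_match_index)
  hits <- semgrex_matches_many(pattern, idxs)
  score_pattern(hits, labels, label)
}

score_pattern <- function(hits, labels, label) {
  accs <- vapply(c("x", "y", "neutral"), function(L) {
    i <- labels == L
    if (!any(i)) return(1)
    correct <- ifelse(hits[i], L == label, L != label)
    mean(correct)
  }, numeric(1))
  structure(mean(accs), per_label = accs)
}

#' Fit a dependency-tree pattern classifier
#'
#' Trains the classifier for one opinion class: for each non-neutral label,
#' the top `n_x` / `n_y` words by information gain are selected
#' ([information_gain_words()]), candidate patterns are extracted from every
#' tree carrying that label ([extract_patterns()]), and every distinct
#' (pattern, label) pair is scored by [pattern_weighted_accuracy()] on the
#' full class training set (neutral sentences included). The model is the
#' resulting list of patterns sorted by descending score; ties go to the
#' longer (more specific) serialized pattern, then lexicographically, so
#' training is fully deterministic. Defaults `n_x = n_y = 30` and `m = 4`.
#'
#' @inheritParams information_gain_words
#' @param n_x,n_y Word-selection caps for the `x` and `y` labels.
#' @param m Maximum selected words per pattern.
#' @param negation_label Relation label treated as negation (kept verbatim
#'   in patterns).
#' @param fallback `"majority"` (classify unmatched sentences as the most
#'   common training label) or `"backup"` (delegate to `backup`).
#' @param backup Optional function `function(text) -> label` used when
#'   `fallback = "backup"`.
#' @param top_k Optional truncation of the ranked list (default keeps all
#'   patterns).
#' @param .session,.rows Internal: a shared match session and the indices of
#'   `corpus`'s rows within it, used by cross-validation to reuse matcher
#'   results across folds.
#' @return A `dtc_model`.
#' @examples
#' corpus <- generate_corpus(synth_config(n_per_label = 5, seed = 1))
#' model <- dtc(corpus, "wait_time")
#' tidy(model)
#' @export
dtc <- function(corpus, class_id, n_x = 30, n_y = 30, m = 4,
                negation_label = "neg", fallback = c("majority", "backup"),
                backup = NULL, top_k = NULL,
                .session = NULL, .rows = NULL) {
  stopifnot(n_x >= 1, n_y >= 1, m >= 1)
  fallback <- match.arg(fallback)
  if (fallback == "backup" && !is.function(backup)) {
    stop("fallback = 'backup' requires a backup classifier function",
         call. = FALSE)
  }
  if (!class_id %in% corpus_classes(corpus)) {
    stop("unknown class id '", class_id, "'", call. = FALSE)
  }
  labels <- corpus[[class_id]]
  keep <- !is.na(labels)
  labels <- labels[keep]
  trees <- corpus$tree[keep]
  if (length(labels) == 0L) stop("empty corpus for class '", class_id, "'",
                                 call. = FALSE)
  for (L in c("x", "y")) {
    if (!any(labels == L)) {
      warning("no '", L, "' sentences for class '", class_id,
              "'; training on available labels only", call. = FALSE)
    }
  }
  # a shared match session (cross-validation reuses one across folds)
  if (is.null(.session)) {
    .session <- build_match_session(trees)
    .rows <- seq_along(trees)
  } else {
    .rows <- .rows[keep]
  }

  cache <- .session$extract_cache
  cand <- list()
  for (L in c("x", "y")) {
    n_cap <- if (L == "x") n_x else n_y
    if (!any(labels == L)) next
    W <- information_gain_words(corpus, class_id, L, n = n_cap)$word
    for (t in trees[labels == L]) {
      cand[[length(cand) + 1L]] <-
        extract_patterns(t, W, label = L, m = m,
                         negation_label = negation_label, cache = cache)
    }
  }
  ranked <- if (length(cand) > 0L) dplyr::bind_rows(cand) else
    tibble::tibble(pattern = list(), pattern_text = character(0),
                   label = character(0))
  ranked <- dplyr::distinct(ranked, .data$pattern_text, .data$label,
                            .keep_all = TRUE)

  if (nrow(ranked) > 0L) {
    ranked$score <- vapply(seq_len(nrow(ranked)), function(i) {
      hits <- session_pattern_hits(.session, ranked$pattern[[i]])[.rows]
      as.numeric(score_pattern(hits, labels, ranked$label[[i]]))
    }, numeric(1))
    ord <- order(-ranked$score, -nchar(ranked$pattern_text),
                 ranked$pattern_text, method = "radix")
    ranked <- ranked[ord, ]
    if (!is.null(top_k)) ranked <- utils::head(ranked, top_k)
  } else {
    warning("no patterns extracted for class '", class_id,
            "'; the model will always fall back", call. = FALSE)
    ranked$score <- numeric(0)
  }

  counts <- table(factor(labels, levels = c("neutral", "x", "y")))
  majority <- names(counts)[which.max(counts)]  # ties: neutral, then x, then y

  structure(list(
    class_id = class_id,
    ranked = ranked,
    config = list(n_x = n_x, n_y = n_y, m = m,
                  negation_label = negation_label, top_k = top_k),
    fallback = fallback,
    backup = backup,
    majority_label = majority,
    n_train = length(labels)
  ), class = "dtc_model")
}

#' @export
print.dtc_model <- function(x, ...) {
  cat("Dependency-tree pattern classifier\n")
  cat("  class:          ", x$class_id, "\n", sep = "")
  cat("  ranked patterns:", nrow(x$ranked), "\n")
  cat("  fallback:       ", x$fallback, " (majority label: ",
      x$majority_label, ")\n", sep = "")
  if (nrow(x$ranked) > 0L) {
    top <- utils::head(x$ranked, 5)
    cat("  top patterns:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %.4f  %s  %s\n", top$score[i], top$label[i],
                  top$pattern_text[i]))
    }
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the ranked pattern list of a fitted model
#'
#' @param x A `dtc_model`.
#' @param ... Unused.
#' @return A tibble with columns `rank`, `pattern_text`, `label`, `score`.
#' @export
tidy.dtc_model <- function(x, ...) {
  tibble::tibble(
    rank = seq_len(nrow(x$ranked)),
    pattern_text = x$ranked$pattern_text,
    label = x$ranked$label,
    score = if (nrow(x$ranked) > 0L) x$ranked$score else numeric(0)
  )
}

#' One-row summary of a fitted model
#' @param x A `dtc_model`.
#' @param ... Unused.
#' @export
glance.dtc_model <- function(x, ...) {
  tibble::tibble(
    class_id = x$class_id,
    n_patterns = nrow(x$ranked),
    n_train = x$n_train,
    majority_label = x$majority_label,
    n_x = x$config$n_x, n_y = x$config$n_y, m = x$config$m
  )
}

#' Write / read a fitted model as plain text
#'
#' The model file is a `#`-prefixed header (class id, configuration,
#' majority label) followed by one ranked pattern per line,
#' `score<TAB>label<TAB>pattern`. The representation round-trips exactly
#' (scores are written with full precision), so identical training runs
#' produce byte-identical files.
#'
#' @param model A `dtc_model`.
#' @param path File path.
#' @return `write_dtc_model()` returns `path` invisibly; `read_dtc_model()`
#'   returns a `dtc_model` (with `fallback = "majority"`; backup functions
#'   are not serialized).
#' @export
write_dtc_model <- function(model, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(
    "# dtc model",
    paste0("# class_id: ", model$class_id),
    paste0("# n_x: ", model$config$n_x),
    paste0("# n_y: ", model$config$n_y),
    paste0("# m: ", model$config$m),
    paste0("# negation_label: ", model$config$negation_label),
    paste0("# fallback: ", model$fallback),
    paste0("# majority_label: ", model$majority_label),
    paste0("# n_train: ", model$n_train)
  )
  writeLines(hdr, con, useBytes = TRUE)
  if (nrow(model$ranked) > 0L) {
    writeLines(sprintf("%.17g\t%s\t%s", model$ranked$score,
                       model$ranked$label, model$ranked$pattern_text),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_dtc_model
#' @export
read_dtc_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get <- function(key) {
    v <- sub(paste0("^# ", key, ": "), "", grep(paste0("^# ", key, ":"),
                                                hdr, value = TRUE)[1])
    if (length(v) == 0L || is.na(v)) stop("model file missing header '", key,
                                          "'", call. = FALSE)
    v
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  ranked <- tibble::tibble(
    pattern = lapply(parts, function(p) parse_pattern(p[3])),
    pattern_text = vapply(parts, `[`, character(1), 3L),
    label = vapply(parts, `[`, character(1), 2L),
    score = as.numeric(vapply(parts, `[`, character(1), 1L))
  )
  structure(list(
    class_id = get("class_id"),
    ranked = ranked,
    config = list(n_x = as.integer(get("n_x")), n_y = as.integer(get("n_y")),
                  m = as.integer(get("m")),
                  negation_label = get("negation_label"), top_k = NULL),
    fallback = get("fallback"),
    backup = NULL,
    majority_label = get("majority_label"),
    n_train = as.integer(get("n_train"))
  ), class = "dtc_model")
}
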