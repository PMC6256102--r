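#' Labeled sentence corpora
#'
#' A corpus is a tibble with one row per sentence: a `text` column, a `tree`
#' list-column of [dep_tree()] objects, and one character column per declared
#' opinion class holding a three-valued label. Each opinion class (an aspect
#' of care such as wait time) takes one of `"x"` (yes), `"y"` (no) or
#' `"neutral"` (the sentence does not address the class); `NA` marks a
#' sentence that was dropped for that class because annotators assigned both
#' `x` and `y`. The declared class ids are stored in the `"classes"`
#' attribute.
#'
#' @param text Character vector of sentence texts.
#' @param tree List of `dep_tree` objects.
#' @param labels A data frame / tibble of label columns (one per class), or a
#'   named list of character vectors.
#' @param classes Character vector of declared class ids (defaults to the
#'   label column names).
#' @return A `dtc_corpus` tibble.
#' @export
dtc_corpus <- function(text, tree, labels, classes = NULL) {
  labels <- tibble::as_tibble(labels)
  if (is.null(classes)) classes <- names(labels)
  stopifnot(length(text) == length(tree), nrow(labels) == length(text))
  for (cl in setdiff(classes, names(labels))) {
    labels[[cl]] <- rep("neutral", length(text))
  }
  bad <- setdiff(names(labels), classes)
  if (length(bad) > 0L) {
    stop("undeclared class id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (cl in classes) {
    v <- labels[[cl]]
    if (!all(v %in% c("x", "y", "neutral", NA))) {
      stop("labels for class '", cl,
           "' must be one of 'x', 'y', 'neutral'", call. = FALSE)
    }
  }
  out <- tibble::tibble(text = as.character(text), tree = tree)
  out <- dplyr::bind_cols(out, labels[classes])
  attr(out, "classes") <- classes
  class(out) <- c("dtc_corpus", class(out))
  out
}

#' @describeIn dtc_corpus Declared class ids of a corpus.
#' @param corpus A `dtc_corpus`.
#' @export
corpus_classes <- function(corpus) attr(corpus, "classes")

#' Read a labeled corpus from JSON-lines
#'
#' The corpus file holds one JSON record per line. The first record declares
#' the opinion classes, `{"classes": ["wait_time", ...]}`; every following
#' record is a sentence, `{"text": ..., "tree": ... | "conllu": ...,
#' "labels": {...}}`. Trees are given either as a bracketed-dialect string
#' (`"tree"`) or as inline CoNLL-U rows (`"conllu"`, a string or array of
#' row strings). Labels map class ids to `"x"`, `"y"` or `"neutral"`; a
#' missing class means neutral (the sentence is simply not about that
#' class). A record whose labels assign both `x` and `y` to one class (which
#' can happen when independent annotations are unioned) gets `NA` for that
#' class with a warning and is excluded from that class's training and
#' evaluation.
#'
#' @param path Path to a JSON-lines corpus file.
#' @return A [dtc_corpus()] tibble.
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty corpus file: ", path, call. = FALSE)
  header <- jsonlite::fromJSON(lines[[1]], simplifyVector = TRUE)
  if (is.null(header$classes)) {
    stop("corpus file must start with a header record {\"classes\": [...]}",
         call. = FALSE)
  }
  classes <- as.character(header$classes)
  records <- lines[-1]
  n <- length(records)
  text <- character(n)
  trees <- vector("list", n)
  labs <- matrix("neutral", nrow = n, ncol = length(classes),
                 dimnames = list(NULL, classes))
  for (r in seq_len(n)) {
    rec <- tryCatch(
      jsonlite::fromJSON(records[[r]], simplifyVector = FALSE),
      error = function(e) {
        stop(sprintf("corpus record %d: invalid JSON (%s)", r,
                     conditionMessage(e)), call. = FALSE)
      }
    )
    text[r] <- rec$text %||% ""
    trees[[r]] <- tryCatch({
      if (!is.null(rec$tree)) {
        parse_bracketed_tree(rec$tree)
      } else if (!is.null(rec$conllu)) {
        tl <- read_conllu(unlist(rec$conllu, use.names = FALSE))
        if (length(tl) != 1L) stop("expected exactly one CoNLL-U sentence")
        tl[[1]]
      } else {
        stop("record has neither 'tree' nor 'conllu'")
      }
    }, error = function(e) {
      stop(sprintf("corpus record %d: %s", r, conditionMessage(e)),
           call. = FALSE)
    })
    for (cl in names(rec$labels)) {
      if (!cl %in% classes) {
        stop(sprintf("corpus record %d: undeclared class '%s'", r, cl),
             call. = FALSE)
      }
      v <- unique(unlist(rec$labels[[cl]], use.names = FALSE))
      if (all(c("x", "y") %in% v)) {
        warning(sprintf(
          "corpus record %d assigns both 'x' and 'y' for class '%s'; dropping the sentence for that class",
          r, cl), call. = FALSE)
        labs[r, cl] <- NA_character_
      } else {
        bad <- setdiff(v, c("x", "y", "neutral"))
        if (length(bad) > 0L) {
          stop(sprintf("corpus record %d: bad label '%s' for class '%s'",
                       r, bad[1], cl), call. = FALSE)
        }
        v <- setdiff(v, "neutral")
        labs[r, cl] <- if (length(v) == 0L) "neutral" else v
      }
    }
  }
  dtc_corpus(text, trees, tibble::as_tibble(labs), classes = classes)
}

#' Write a labeled corpus to JSON-lines
#'
#' Inverse of [read_corpus()]: emits the class-declaration header followed by
#' one record per sentence with the tree in the bracketed dialect.
#'
#' @param corpus A [dtc_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  classes <- corpus_classes(corpus)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(classes = classes)), con, useBytes = TRUE)
  for (r in seq_len(nrow(corpus))) {
    labels <- lapply(classes, function(cl) corpus[[cl]][r])
    names(labels) <- classes
    labels <- labels[!vapply(labels, is.na, logical(1))]
    rec <- list(
      text = corpus$text[r],
      tree = format(corpus$tree[[r]]),
      labels = labels
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con, useBytes = TRUE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
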