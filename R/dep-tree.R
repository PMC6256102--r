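#' Dependency trees
#'
#' A dependency tree represents the grammatical structure of one sentence:
#' every word is a node, and every node except the root is attached to exactly
#' one governor (head) word by a typed relation such as `nsubj` or `neg`.
#' Nodes are stored in serialization order, indices are 1-based, and sibling
#' order follows node order (it is preserved on round trips but carries no
#' matching semantics).
#'
#' @param word Character vector of surface tokens (non-empty strings).
#' @param parent Integer vector of governor indices; `0` marks the root.
#' @param rel Character vector of relation labels; `NA` for the root.
#' @param pos,lemma Optional character vectors of part-of-speech tags and
#'   lemmas (`NA` where unknown).
#'
#' @return An object of class `dep_tree`.
#' @examples
#' dep_tree(
#'   word = c("are", "there", "never"),
#'   parent = c(0L, 1L, 1L),
#'   rel = c(NA, "expl", "neg"),
#'   pos = c("VBP", "EX", "RB")
#' )
#' @export
dep_tree <- function(word, parent, rel, pos = NULL, lemma = NULL) {
  n <- length(word)
  word <- as.character(word)
  parent <- as.integer(parent)
  rel <- as.character(rel)
  pos <- if (is.null(pos)) rep(NA_character_, n) else as.character(pos)
  lemma <- if (is.null(lemma)) rep(NA_character_, n) else as.character(lemma)
  if (length(parent) != n || length(rel) != n || length(pos) != n ||
      length(lemma) != n) {
    stop("dep_tree: all fields must have the same length", call. = FALSE)
  }
  t <- structure(
    list(word = word, parent = parent, rel = rel, pos = pos, lemma = lemma),
    class = "dep_tree"
  )
  validate_dep_tree(t)
  t
}

validate_dep_tree <- function(t) {
  n <- length(t$word)
  if (n == 0L) stop("dep_tree: tree must have at least one node", call. = FALSE)
  if (any(is.na(t$word) | t$word == "")) {
    stop("dep_tree: every node needs a non-empty word", call. = FALSE)
  }
  roots <- which(t$parent == 0L)
  if (length(roots) != 1L) {
    stop("dep_tree: exactly one root (parent 0) required, found ",
         length(roots), call. = FALSE)
  }
  if (any(t$parent < 0L | t$parent > n)) {
    stop("dep_tree: governor index out of range", call. = FALSE)
  }
  if (any(is.na(t$rel[-roots]) | t$rel[-roots] == "")) {
    stop("dep_tree: every non-root node needs a relation label", call. = FALSE)
  }
  # acyclicity / connectedness: every node must reach the root
  for (i in seq_len(n)) {
    j <- i
    steps <- 0L
    while (t$parent[j] != 0L) {
      j <- t$parent[j]
      steps <- steps + 1L
      if (steps > n) stop("dep_tree: cycle in governor links", call. = FALSE)
    }
  }
  invisible(t)
}

#' @export
print.dep_tree <- function(x, ...) {
  cat("<dep_tree: ", n_nodes(x), " nodes>\n", sep = "")
  cat(format(x), "\n")
  invisible(x)
}

#' Number of nodes in a dependency tree
#' @param t A `dep_tree`.
#' @return Integer count.
#' @export
n_nodes <- function(t) length(t$word)

tree_root <- function(t) which(t$parent == 0L)

tree_children <- function(t, i) which(t$parent == i)

tree_descendants <- function(t, i) {
  out <- integer(0)
  frontier <- tree_children(t, i)
  while (length(frontier) > 0L) {
    out <- c(out, frontier)
    frontier <- which(t$parent %in% frontier)
  }
  sort(out)
}

#' Parse the bracketed dependency-tree dialect
#'
#' Reads trees written as `[word/POS rel>child rel>[subtree] ...]`, the
#' compact one-line serialization of a dependency tree with parts of speech:
#' a node is `word/POS`, a leaf child is `rel>word/POS`, and an internal
#' child is `rel>[...]`. Token indices are assigned in serialization
#' (pre-order) order and child order is preserved, so
#' `format()` of the result reproduces the input byte for byte.
#'
#' @param text A single string in the bracketed dialect.
#' @return A [dep_tree()].
#' @examples
#' t <- parse_bracketed_tree(
#'   "[are/VBP expl>there/EX neg>never/RB nsubj>[times/NNS compound>[wait/NN amod>long/JJ]]]"
#' )
#' n_nodes(t)
#' format(t)
#' @export
parse_bracketed_tree <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  st <- new.env(parent = emptyenv())
  st$s <- text
  st$i <- 1L
  st$n <- nchar(text)
  st$word <- character(0)
  st$parent <- integer(0)
  st$rel <- character(0)
  st$pos <- character(0)

  bt_error <- function(st, msg) {
    stop(sprintf("bracketed tree parse error at offset %d: %s", st$i, msg),
         call. = FALSE)
  }
  peek <- function(st) if (st$i > st$n) "" else substr(st$s, st$i, st$i)
  skip_ws <- function(st) {
    while (st$i <= st$n && grepl("^\\s$", substr(st$s, st$i, st$i))) {
      st$i <- st$i + 1L
    }
  }
  # a word/POS token: characters up to whitespace, ']' or end
  read_token <- function(st) {
    start <- st$i
    while (st$i <= st$n && !grepl("^[][\\s]$", substr(st$s, st$i, st$i), perl = TRUE)) {
      st$i <- st$i + 1L
    }
    if (st$i == start) bt_error(st, "expected a word/POS token")
    substr(st$s, start, st$i - 1L)
  }
  add_node <- function(st, token, parent, rel) {
    slash <- regexpr("/[^/]*$", token)
    if (slash < 2L || slash == nchar(token)) {
      bt_error(st, sprintf("token '%s' is missing its /POS suffix", token))
    }
    st$word <- c(st$word, substr(token, 1L, slash - 1L))
    st$pos <- c(st$pos, substr(token, slash + 1L, nchar(token)))
    st$parent <- c(st$parent, parent)
    st$rel <- c(st$rel, rel)
    length(st$word)
  }
  # parses "[word/POS child*]" and returns node index
  parse_subtree <- function(st, parent, rel) {
    if (peek(st) != "[") bt_error(st, "expected '['")
    st$i <- st$i + 1L
    skip_ws(st)
    idx <- add_node(st, read_token(st), parent, rel)
    skip_ws(st)
    while (peek(st) != "]") {
      if (peek(st) == "") bt_error(st, "unbalanced brackets: missing ']'")
      parse_child(st, idx)
      skip_ws(st)
    }
    st$i <- st$i + 1L
    idx
  }
  # parses "rel>word/POS" or "rel>[subtree]"
  parse_child <- function(st, parent) {
    start <- st$i
    while (st$i <= st$n &&
           !grepl("^[]>[\\s]$", substr(st$s, st$i, st$i), perl = TRUE)) {
      st$i <- st$i + 1L
    }
    if (peek(st) != ">" || st$i == start) {
      st$i <- start
      bt_error(st, "expected a 'rel>' prefix before a child")
    }
    rel <- substr(st$s, start, st$i - 1L)
    st$i <- st$i + 1L
    if (peek(st) == "[") {
      parse_subtree(st, parent, rel)
    } else {
      add_node(st, read_token(st), parent, rel)
    }
  }

  skip_ws(st)
  if (peek(st) != "[") bt_error(st, "tree must start with '['")
  parse_subtree(st, 0L, NA_character_)
  skip_ws(st)
  if (st$i <= st$n) bt_error(st, "trailing text after closing ']'")
  dep_tree(st$word, st$parent, st$rel, pos = st$pos)
}

#' @describeIn parse_bracketed_tree Serialize a tree back to the bracketed
#'   dialect (the round-trip inverse of the parser).
#' @param x A `dep_tree`.
#' @param ... Unused.
#' @export
format.dep_tree <- function(x, ...) {
  fmt_node <- function(i) {
    tok <- paste0(x$word[i], "/", ifelse(is.na(x$pos[i]), "_", x$pos[i]))
    kids <- tree_children(x, i)
    if (length(kids) == 0L) return(tok)
    parts <- vapply(kids, function(k) {
      sub <- fmt_node(k)
      if (length(tree_children(x, k)) > 0L) sub <- paste0("[", sub, "]")
      paste0(x$rel[k], ">", sub)
    }, character(1))
    paste(c(tok, parts), collapse = " ")
  }
  paste0("[", fmt_node(tree_root(x)), "]")
}
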