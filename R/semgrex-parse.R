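#' Semgrex-style tree patterns
#'
#' Patterns over dependency trees in the governor-direction subset of the
#' semgrex language. A node is written `{}` (wildcard, matches any node) or
#' `{attr:value;...}` with attributes `word`, `lemma` or `pos` and values
#' that are exact strings or `/regex/` forms; `A > B` requires an edge from
#' A to B with any relation, `A >rel B` requires relation `rel`, and
#' `A >> B` requires B anywhere below A. Relations are all relative to the
#' leading node of their group; parentheses start a new group whose own
#' leading node anchors its relations. The dependent-direction operators
#' `<` and `<<` are not part of this subset.
#'
#' All attribute comparisons at match time are case-insensitive; relation
#' labels compare by exact string equality.
#'
#' @param text Pattern source text.
#' @return `parse_pattern()` returns a `semgrex_pattern`; `format()` returns
#'   its canonical text (attributes in word/lemma/pos order, direct children
#'   before indirect, then by serialized form), which is the equality key
#'   used for pattern deduplication.
#' @examples
#' p <- parse_pattern("{} >neg {} >> ({word:wait} > {word:long})")
#' format(p)
#' @export
parse_pattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  st <- new.env(parent = emptyenv())
  st$s <- text
  st$i <- 1L
  st$n <- nchar(text)

  perr <- function(st, msg) {
    stop(sprintf("semgrex parse error at position %d: %s", st$i, msg),
         call. = FALSE)
  }
  peek <- function(st) if (st$i > st$n) "" else substr(st$s, st$i, st$i)
  skip_ws <- function(st) {
    while (st$i <= st$n && grepl("^\\s$", substr(st$s, st$i, st$i))) {
      st$i <- st$i + 1L
    }
    # '&' may optionally join relation constraints; it carries no meaning
    if (peek(st) == "&") {
      st$i <- st$i + 1L
      skip_ws(st)
    }
  }

  parse_node <- function(st) {
    if (peek(st) != "{") perr(st, "expected a node '{...}'")
    close <- regexpr("}", substr(st$s, st$i, st$n), fixed = TRUE)
    if (close < 0L) perr(st, "unclosed node: missing '}'")
    body <- substr(st$s, st$i + 1L, st$i + close - 2L)
    st$i <- st$i + close
    constraints <- list()
    if (nzchar(trimws(body))) {
      for (part in strsplit(body, ";", fixed = TRUE)[[1]]) {
        kv <- strsplit(part, ":", fixed = TRUE)[[1]]
        if (length(kv) != 2L) perr(st, sprintf("bad attribute constraint '%s'", part))
        attr_name <- trimws(kv[1])
        value <- trimws(kv[2])
        if (!attr_name %in% c("word", "lemma", "pos")) {
          perr(st, sprintf("unknown attribute '%s'", attr_name))
        }
        if (grepl("^/.*/$", value)) {
          rx <- substr(value, 2L, nchar(value) - 1L)
          ok <- tryCatch({grepl(rx, "", perl = TRUE); TRUE},
                         error = function(e) FALSE, warning = function(w) FALSE)
          if (!ok) perr(st, sprintf("invalid regex /%s/", rx))
          constraints[[attr_name]] <- make_constraint("regex", rx)
        } else {
          constraints[[attr_name]] <- make_constraint("exact", value)
        }
      }
    }
    list(constraints = constraints, children = list())
  }

  parse_relation <- function(st) {
    if (peek(st) == "<") perr(st, "dependent-direction operators '<'/'<<' are not supported")
    if (peek(st) != ">") perr(st, "expected a relation '>'")
    st$i <- st$i + 1L
    if (peek(st) == ">") {
      st$i <- st$i + 1L
      return(list(kind = "indirect", type = NULL))
    }
    start <- st$i
    while (st$i <= st$n &&
           !grepl("^[\\s({]$", substr(st$s, st$i, st$i), perl = TRUE)) {
      st$i <- st$i + 1L
    }
    type <- if (st$i > start) substr(st$s, start, st$i - 1L) else NULL
    list(kind = "direct", type = type)
  }

  # pattern := node (rel operand)* ; operand := node | '(' pattern ')'
  parse_group <- function(st) {
    skip_ws(st)
    head <- parse_node(st)
    skip_ws(st)
    while (peek(st) %in% c(">", "<")) {
      rc <- parse_relation(st)
      skip_ws(st)
      ch <- peek(st)
      if (ch == "(") {
        st$i <- st$i + 1L
        target <- parse_group(st)
        skip_ws(st)
        if (peek(st) != ")") perr(st, "expected ')'")
        st$i <- st$i + 1L
      } else if (ch == "{") {
        target <- parse_node(st)
      } else {
        perr(st, "dangling relation: expected a node or '(' after it")
      }
      rc$node <- target
      head$children[[length(head$children) + 1L]] <- rc
      skip_ws(st)
    }
    head
  }

  root <- parse_group(st)
  skip_ws(st)
  if (st$i <= st$n) perr(st, "trailing text after pattern")
  new_semgrex_pattern(root)
}

# attribute constraint with precomputed fast paths: `lc` for exact
# comparison, `prefix` when the regex is a literal prefix form "w.*"
make_constraint <- function(type, value) {
  cns <- list(type = type, value = value)
  if (type == "exact") {
    cns$lc <- tolower(value)
  } else if (grepl("^[a-z0-9_'-]+\\.\\*$", value)) {
    cns$prefix <- substr(value, 1L, nchar(value) - 2L)
  }
  cns
}

new_semgrex_pattern <- function(root) {
  p <- structure(list(root = root), class = "semgrex_pattern")
  p$text <- serialize_pattern_node(root)
  p
}

# canonical serialization; children ordered: direct before indirect,
# then lexicographically (C locale) on the serialized fragment
serialize_pattern_node <- function(node) {
  desc <- serialize_descriptor(node$constraints)
  if (length(node$children) == 0L) return(desc)
  frags <- vapply(node$children, function(rc) {
    relstr <- if (rc$kind == "indirect") ">>"
              else if (is.null(rc$type)) ">"
              else paste0(">", rc$type)
    sub <- serialize_pattern_node(rc$node)
    if (length(rc$node$children) > 0L) sub <- paste0("(", sub, ")")
    paste(relstr, sub)
  }, character(1))
  kind_rank <- vapply(node$children, function(rc) rc$kind == "indirect", logical(1))
  ord <- order(kind_rank, frags, method = "radix")
  paste(c(desc, frags[ord]), collapse = " ")
}

serialize_descriptor <- function(constraints) {
  if (length(constraints) == 0L) return("{}")
  parts <- character(0)
  for (a in c("word", "lemma", "pos")) {
    cns <- constraints[[a]]
    if (is.null(cns)) next
    v <- if (cns$type == "regex") paste0("/", cns$value, "/") else cns$value
    parts <- c(parts, paste0(a, ":", v))
  }
  paste0("{", paste(parts, collapse = ";"), "}")
}

#' @rdname parse_pattern
#' @param x A `semgrex_pattern`.
#' @param ... Unused.
#' @export
format.semgrex_pattern <- function(x, ...) x$text

#' @export
print.semgrex_pattern <- function(x, ...) {
  cat("<semgrex_pattern> ", x$text, "\n", sep = "")
  invisible(x)
}

pattern_n_nodes <- function(node) {
  1L + sum(vapply(node$children, function(rc) pattern_n_nodes(rc$node),
                  integer(1)))
}

# number of nodes carrying at least one attribute constraint
pattern_n_constrained <- function(node) {
  (length(node$constraints) > 0L) +
    sum(vapply(node$children, function(rc) pattern_n_constrained(rc$node),
               integer(1)))
}
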