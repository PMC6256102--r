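#' Match a semgrex pattern against a dependency tree
#'
#' Returns `TRUE` when the pattern's nodes can be mapped to tree nodes so
#' that every attribute constraint holds (case-insensitively; regexes must
#' match the whole attribute value) and every relation constraint holds: a
#' direct constraint needs one governor-to-dependent edge (with an equal
#' relation label when the constraint is typed), an indirect constraint
#' needs a governor-to-descendant path of length one or more. The pattern
#' root may map to any tree node, and the mapping need not be injective, so
#' a pattern can match "any part of the tree".
#'
#' @param pattern A [parse_pattern()] result (or pattern source text).
#' @param tree A [dep_tree()].
#' @return Logical scalar.
#' @examples
#' t <- parse_bracketed_tree(
#'   "[are/VBP expl>there/EX neg>never/RB nsubj>[times/NNS compound>[wait/NN amod>long/JJ]]]"
#' )
#' semgrex_matches("{} >neg {} >> ({word:wait} > {word:long})", t)
#' semgrex_matches("{word:zebra}", t)
#' @export
semgrex_matches <- function(pattern, tree) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  stopifnot(inherits(pattern, "semgrex_pattern"), inherits(tree, "dep_tree"))
  idx <- tree_match_index(tree)
  any(vapply(seq_len(idx$n), function(i) match_at(pattern$root, i, idx),
             logical(1)))
}

# precomputed lowercase attributes + adjacency for one tree
tree_match_index <- function(tree) {
  n <- n_nodes(tree)
  children <- lapply(seq_len(n), function(i) which(tree$parent == i))
  descendants <- vector("list", n)
  # compute descendant sets bottom-up over the parent vector
  ord <- order(depth_vec(tree), decreasing = TRUE)
  for (i in ord) {
    kids <- children[[i]]
    descendants[[i]] <- c(kids, unlist(descendants[kids], use.names = FALSE))
  }
  list(
    n = n,
    word = tolower(tree$word),
    lemma = tolower(tree$lemma),
    pos = tolower(tree$pos),
    rel = tree$rel,
    children = children,
    descendants = descendants
  )
}

depth_vec <- function(tree) {
  n <- n_nodes(tree)
  d <- integer(n)
  for (i in seq_len(n)) {
    j <- i
    while (tree$parent[j] != 0L) {
      d[i] <- d[i] + 1L
      j <- tree$parent[j]
    }
  }
  d
}

match_at <- function(pnode, i, idx) {
  if (!descriptor_ok(pnode$constraints, i, idx)) return(FALSE)
  for (rc in pnode$children) {
    cand <- if (rc$kind == "indirect") {
      idx$descendants[[i]]
    } else if (is.null(rc$type)) {
      idx$children[[i]]
    } else {
      kids <- idx$children[[i]]
      kids[idx$rel[kids] == rc$type]
    }
    if (length(cand) == 0L) return(FALSE)
    hit <- FALSE
    for (j in cand) {
      if (match_at(rc$node, j, idx)) { hit <- TRUE; break }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

descriptor_ok <- function(constraints, i, idx) {
  for (a in names(constraints)) {
    value <- idx[[a]][i]
    if (is.na(value)) return(FALSE)
    cns <- constraints[[a]]
    ok <- if (cns$type == "exact") {
      value == cns$lc
    } else if (!is.null(cns$prefix)) {
      startsWith(value, cns$prefix)
    } else {
      grepl(paste0("^(?:", cns$value, ")$"), value,
            perl = TRUE, ignore.case = TRUE)
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

# matches() for many trees with one pattern, reusing the parsed pattern
semgrex_matches_many <- function(pattern, indexes) {
  vapply(indexes, function(idx) {
    any(vapply(seq_len(idx$n), function(i) match_at(pattern$root, i, idx),
               logical(1)))
  }, logical(1))
}
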