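#' Pattern trees: pruned, wildcarded working trees
#'
#' During pattern extraction a dependency tree is reduced to a "pattern
#' tree": nodes whose word starts with a selected high-information word keep
#' that word (lowercased), all other surviving nodes become wildcards
#' (`NA` word, printed `*`), and edges are either direct (optionally typed)
#' or indirect. Pattern trees are an intermediate form between dependency
#' trees and semgrex patterns.
#'
#' @name ptree
#' @keywords internal
NULL

new_ptree <- function(word, parent, kind, type) {
  pt <- list(word = word, parent = as.integer(parent),
             kind = kind, type = type)
  class(pt) <- "dtc_ptree"
  pt
}

csort <- function(x) x[order(x, method = "radix")]

as_ptree <- function(t) {
  if (inherits(t, "dtc_ptree")) return(t)
  stopifnot(inherits(t, "dep_tree"))
  new_ptree(t$word, t$parent, rep("direct", n_nodes(t)), t$rel)
}

ptree_children <- function(pt, i) which(pt$parent == i)

#' @export
format.dtc_ptree <- function(x, ...) {
  if (length(x$word) == 0L) return("<empty>")
  fmt <- function(i) {
    tok <- if (is.na(x$word[i])) "*" else x$word[i]
    kids <- ptree_children(x, i)
    if (length(kids) == 0L) return(tok)
    parts <- vapply(kids, function(k) {
      sub <- fmt(k)
      if (length(ptree_children(x, k)) > 0L) sub <- paste0("[", sub, "]")
      op <- if (x$kind[k] == "indirect") ">>"
            else if (is.na(x$type[k])) ">"
            else paste0(x$type[k], ">")
      paste0(op, sub)
    }, character(1))
    paste(c(tok, parts), collapse = " ")
  }
  paste0("[", fmt(which(x$parent == 0L)), "]")
}

#' @export
print.dtc_ptree <- function(x, ...) {
  cat("<pattern tree> ", format(x), "\n", sep = "")
  invisible(x)
}

# lexicographically smallest word in `words` that is a case-insensitive
# prefix of each tree word; NA where none
match_word_set <- function(tree_words, words) {
  lw <- tolower(tree_words)
  out <- rep(NA_character_, length(lw))
  for (w in csort(words)) {
    hit <- is.na(out) & !is.na(lw) & startsWith(lw, w)
    hit[is.na(hit)] <- FALSE
    out[hit] <- w
  }
  out
}

#' Prune a tree to high-information words
#'
#' Repeatedly removes leaves whose word does not start with any word in
#' `words` (case-insensitive prefix, so `wait` covers `waited`) and whose
#' incoming relation is not the negation label; then replaces every
#' surviving node whose word starts with no selected word by a wildcard.
#' Surviving selected nodes carry the (lowercased) selected word itself,
#' mirroring the `/w.*/` prefix constraints of the final patterns.
#'
#' @param tree A [dep_tree()] or pattern tree.
#' @param words Character vector of selected words (lowercase).
#' @param negation_label Relation label that protects a negator leaf
#'   (default `"neg"`; configurable because newer dependency schemes rename
#'   it).
#' @return A pattern tree, or `NULL` when everything is pruned.
#' @examples
#' t <- parse_bracketed_tree(
#'   "[are/VBP expl>there/EX neg>never/RB nsubj>[times/NNS compound>[wait/NN amod>long/JJ]]]"
#' )
#' prune_tree(t, c("wait", "long"))
#' @export
prune_tree <- function(tree, words, negation_label = "neg") {
  pt <- as_ptree(tree)
  n <- length(pt$word)
  word_w <- match_word_set(pt$word, words)
  protected <- !is.na(word_w)
  neg_kept <- !is.na(pt$type) & pt$type == negation_label &
    pt$kind == "direct"
  alive <- rep(TRUE, n)
  repeat {
    has_child <- tabulate(pt$parent[alive & pt$parent > 0L], nbins = n) > 0L
    drop <- alive & !has_child & !protected & !neg_kept
    if (!any(drop)) break
    alive[drop] <- FALSE
  }
  if (!any(alive)) return(NULL)
  keep <- which(alive)
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  parent <- pt$parent[keep]
  parent[parent > 0L] <- remap[parent[parent > 0L]]
  new_ptree(word_w[keep], parent, pt$kind[keep], pt$type[keep])
}

#' Collapse single-child wildcards
#'
#' Second reduction step of pattern extraction: while the root is a wildcard
#' with exactly one child, descend to the child; then remove every interior
#' wildcard node that has exactly one child, reattaching the child to its
#' grandparent with an indirect relation. Wildcards with two or more
#' children are retained (they become `{}` nodes).
#'
#' @param pt A pattern tree from [prune_tree()].
#' @return A pattern tree.
#' @export
collapse_tree <- function(pt) {
  stopifnot(inherits(pt, "dtc_ptree"))
  repeat {
    n <- length(pt$word)
    root <- which(pt$parent == 0L)
    kids <- ptree_children(pt, root)
    # descend past a single-child wildcard root
    if (is.na(pt$word[root]) && length(kids) == 1L) {
      keep <- setdiff(seq_len(n), root)
      sub <- c(kids, tree_desc_ptree(pt, kids))
      keep <- intersect(keep, sub)
      pt <- ptree_subset(pt, keep, new_root = kids)
      next
    }
    # remove one interior single-child wildcard, rewiring indirectly
    cand <- which(is.na(pt$word) & pt$parent > 0L &
                    tabulate(pt$parent, nbins = n) == 1L &
                    seq_len(n) %in% pt$parent)
    cand <- cand[vapply(cand, function(i) length(ptree_children(pt, i)) == 1L,
                        logical(1))]
    if (length(cand) == 0L) break
    i <- cand[[1]]
    child <- ptree_children(pt, i)
    pt$parent[child] <- pt$parent[i]
    pt$kind[child] <- "indirect"
    pt$type[child] <- NA_character_
    pt <- ptree_subset(pt, setdiff(seq_len(n), i),
                       new_root = which(pt$parent == 0L))
  }
  pt
}

tree_desc_ptree <- function(pt, i) {
  out <- integer(0)
  frontier <- ptree_children(pt, i)
  while (length(frontier) > 0L) {
    out <- c(out, frontier)
    frontier <- which(pt$parent %in% frontier)
  }
  out
}

ptree_subset <- function(pt, keep, new_root) {
  keep <- sort(keep)
  n <- length(pt$word)
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  parent <- pt$parent[keep]
  parent[keep == new_root] <- 0L
  parent[parent > 0L] <- remap[parent[parent > 0L]]
  kind <- pt$kind[keep]
  type <- pt$type[keep]
  kind[keep == new_root] <- "direct"
  type[keep == new_root] <- NA_character_
  new_ptree(pt$word[keep], parent, kind, type)
}

# canonical pattern text straight from a collapsed pattern tree; must agree
# byte-for-byte with serialize_pattern_node() on the equivalent AST
ptree_canonical_text <- function(pt, negation_label = "neg") {
  ser <- function(i) {
    desc <- if (is.na(pt$word[i])) "{}" else
      paste0("{word:/", pt$word[i], ".*/}")
    kids <- ptree_children(pt, i)
    if (length(kids) == 0L) return(desc)
    frags <- character(length(kids))
    indirect <- logical(length(kids))
    for (z in seq_along(kids)) {
      k <- kids[z]
      indirect[z] <- pt$kind[k] == "indirect"
      relstr <- if (indirect[z]) ">>"
                else if (!is.na(pt$type[k]) && pt$type[k] == negation_label)
                  paste0(">", negation_label)
                else ">"
      sub <- ser(k)
      if (length(ptree_children(pt, k)) > 0L) sub <- paste0("(", sub, ")")
      frags[z] <- paste(relstr, sub)
    }
    ord <- order(indirect, frags, method = "radix")
    paste(c(desc, frags[ord]), collapse = " ")
  }
  ser(which(pt$parent == 0L))
}

# convert a collapsed pattern tree to a semgrex pattern
ptree_to_pattern <- function(pt, negation_label = "neg") {
  build <- function(i) {
    constraints <- list()
    if (!is.na(pt$word[i])) {
      w <- pt$word[i]
      constraints$word <- list(type = "regex", value = paste0(w, ".*"),
                               prefix = w)
    }
    node <- list(constraints = constraints, children = list())
    for (k in ptree_children(pt, i)) {
      type <- if (!is.na(pt$type[k]) && pt$type[k] == negation_label &&
                  pt$kind[k] == "direct") negation_label else NULL
      node$children[[length(node$children) + 1L]] <- list(
        kind = pt$kind[k], type = type, node = build(k)
      )
    }
    node
  }
  new_semgrex_pattern(build(which(pt$parent == 0L)))
}

ptree_words <- function(pt) csort(unique(pt$word[!is.na(pt$word)]))

#' Extract candidate semgrex patterns from one tree
#'
#' Enumerates the patterns a labeled dependency tree contributes: every
#' combination of `min(length(words), m)` selected words seeds a working
#' copy, which is pruned ([prune_tree()]) and collapsed ([collapse_tree()]);
#' each new pattern is recorded and every combination of two or more of its
#' surviving words is reduced in turn, until no new pattern appears.
#' Patterns whose nodes are all wildcards are suppressed (they would match
#' any tree), and duplicates are removed by canonical serialization.
#'
#' Combinations containing words absent from the tree prune to the same
#' result as their present-word subset, so only distinct present-word
#' subsets are actually evaluated; the emitted set is identical to the
#' full enumeration.
#'
#' @inheritParams prune_tree
#' @param label Class label value (`"x"` or `"y"`) to pair with each pattern.
#' @param m Maximum number of selected words per pattern (default 4).
#' @param cache Optional environment memoizing extraction across trees that
#'   reduce to the same working tree.
#' @return A tibble with columns `pattern` (list of `semgrex_pattern`),
#'   `pattern_text` and `label`.
#' @examples
#' t <- parse_bracketed_tree("[wait/NN]")
#' extract_patterns(t, "wait", label = "x", m = 1)
#' @export
extract_patterns <- function(tree, words, label, m = 4,
                             negation_label = "neg", cache = NULL) {
  stopifnot(m >= 1)
  words <- sort(unique(tolower(words)), method = "radix")
  pt <- as_ptree(tree)
  present <- words[vapply(words, function(w) {
    any(startsWith(tolower(pt$word), w), na.rm = TRUE)
  }, logical(1))]
  k <- min(length(words), m)
  n_absent <- length(words) - length(present)
  smin <- max(0L, k - n_absent)
  smax <- min(k, length(present))

  # structural pre-prune: drops everything no combination can keep, and
  # descends past unprotected single-child roots (any later prune+collapse
  # would discard them anyway), which canonicalizes the working tree so the
  # cache can be shared across trees with the same reduced form
  pt0 <- prune_keep_words(pt, present, negation_label)
  pt0 <- strip_root_chain(pt0, present, negation_label)
  if (is.null(pt0) || smax < smin) {
    return(tibble::tibble(pattern = list(), pattern_text = character(0),
                          label = character(0)))
  }

  key <- NULL
  if (!is.null(cache)) {
    key <- paste(format(pt0), paste(present, collapse = "\r"),
                 smin, smax, negation_label, sep = "\n")
    hit <- cache[[key]]
    if (!is.null(hit)) {
      hit$label <- rep(label, nrow(hit))
      return(hit)
    }
  }

  emitted <- new.env(parent = emptyenv())
  queued <- new.env(parent = emptyenv())
  stack <- vector("list", 64L)
  top <- 0L
  push <- function(pt, C) {
    top <<- top + 1L
    if (top > length(stack)) length(stack) <<- 2L * top
    stack[[top]] <<- list(pt = pt, C = C)
  }
  out_pat <- list()
  out_txt <- character(0)
  for (s in seq.int(smin, smax)) {
    combos <- if (s == 0L) list(character(0)) else
      utils::combn(present, s, simplify = FALSE)
    for (C in combos) push(pt0, C)
  }
  while (top > 0L) {
    item <- stack[[top]]
    top <- top - 1L
    pruned <- prune_tree(item$pt, item$C, negation_label)
    if (is.null(pruned)) next
    pruned <- collapse_tree(pruned)
    if (all(is.na(pruned$word))) next  # all-wildcard patterns match anything
    txt <- ptree_canonical_text(pruned, negation_label)
    if (!is.null(emitted[[txt]])) next
    emitted[[txt]] <- TRUE
    pat <- ptree_to_pattern(pruned, negation_label)
    out_pat[[length(out_pat) + 1L]] <- pat
    out_txt <- c(out_txt, txt)
    wrds <- ptree_words(pruned)
    if (length(wrds) >= 2L) {
      base_key <- txt
      for (s in seq.int(2L, length(wrds))) {
        for (C2 in utils::combn(wrds, s, simplify = FALSE)) {
          qk <- paste(base_key, paste(C2, collapse = " "))
          if (is.null(queued[[qk]])) {
            queued[[qk]] <- TRUE
            push(pruned, C2)
          }
        }
      }
    }
  }
  res <- tibble::tibble(pattern = out_pat, pattern_text = out_txt,
                        label = rep(label, length(out_txt)))
  ord <- order(res$pattern_text, method = "radix")
  res <- res[ord, ]
  if (!is.null(cache)) cache[[key]] <- res
  res
}

# drop root nodes that no selected word protects while they have exactly
# one child: every subsequent prune leaves them as single-child wildcard
# roots, which collapse_tree descends past, so the emitted patterns are
# unchanged
strip_root_chain <- function(pt, words, negation_label) {
  if (is.null(pt)) return(NULL)
  repeat {
    root <- which(pt$parent == 0L)
    kids <- ptree_children(pt, root)
    if (length(kids) != 1L) return(pt)
    w <- match_word_set(pt$word[root], words)
    if (!is.na(w)) return(pt)
    pt <- ptree_subset(pt, setdiff(seq_along(pt$word), root), new_root = kids)
  }
}

# like prune_tree but keeps original words on protected nodes (no
# wildcarding), used once per tree before seeding combinations
prune_keep_words <- function(pt, words, negation_label) {
  n <- length(pt$word)
  word_w <- match_word_set(pt$word, words)
  protected <- !is.na(word_w)
  neg_kept <- !is.na(pt$type) & pt$type == negation_label & pt$kind == "direct"
  alive <- rep(TRUE, n)
  repeat {
    has_child <- tabulate(pt$parent[alive & pt$parent > 0L], nbins = n) > 0L
    drop <- alive & !has_child & !protected & !neg_kept
    if (!any(drop)) break
    alive[drop] <- FALSE
  }
  if (!any(alive)) return(NULL)
  keep <- which(alive)
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  parent <- pt$parent[keep]
  parent[parent > 0L] <- remap[parent[parent > 0L]]
  new_ptree(pt$word[keep], parent, pt$kind[keep], pt$type[keep])
}
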