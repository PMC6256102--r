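#' Planted motifs for synthetic corpora
#'
#' A motif is the ground-truth discriminative construct of a synthetic
#' label: a small dependency-tree fragment (for example a negation edge over
#' a "wait"/"long" subtree) plus the content words that carry its signal.
#' Sentences of the motif's label embed the fragment under random filler
#' structure; [planted_pattern()] gives the semgrex pattern the fragment
#' collapses to, used as recovery ground truth.
#'
#' @param label `"x"` or `"y"`.
#' @param template A [dep_tree()] fragment.
#' @param content Character vector of the template's content words (at least
#'   one must occur in the template).
#' @param negation_label Negation relation label used in the template.
#' @return A `dtc_motif`.
#' @examples
#' m <- motif("x",
#'   parse_bracketed_tree("[are/VBP neg>never/RB nsubj>[times/NNS compound>[wait/NN amod>long/JJ]]]"),
#'   content = c("wait", "long"))
#' format(planted_pattern(m))
#' @export
motif <- function(label, template, content, negation_label = "neg") {
  stopifnot(label %in% c("x", "y"), inherits(template, "dep_tree"))
  content <- tolower(content)
  covered <- match_word_set(template$word, content)
  if (!any(!is.na(covered))) {
    stop("motif template must contain at least one content word",
         call. = FALSE)
  }
  structure(list(label = label, template = template, content = content,
                 negation_label = negation_label), class = "dtc_motif")
}

#' @rdname motif
#' @param m A `dtc_motif`.
#' @export
planted_pattern <- function(m) {
  stopifnot(inherits(m, "dtc_motif"))
  pt <- prune_tree(m$template, m$content, m$negation_label)
  ptree_to_pattern(collapse_tree(pt), m$negation_label)
}

motif_depth <- function(m) max(depth_vec(m$template)) + 1L

default_synth_classes <- function() {
  list(
    wait_time = list(
      x = motif(
        "x",
        parse_bracketed_tree(
          "[are/VBP expl>there/EX neg>never/RB nsubj>[times/NNS compound>[wait/NN amod>long/JJ]]]"
        ),
        content = c("wait", "long")
      ),
      y = motif(
        "y",
        parse_bracketed_tree(
          "[waited/VBD nmod>[room/NN compound>waiting/NN] nmod>[hour/NN case>over/IN]]"
        ),
        content = c("room", "hour")
      )
    )
  )
}

#' Configure the synthetic corpus generator
#'
#' The generator emulates the statistical shape of an aspect-labeled review
#' corpus: for each opinion class, sentences of the `x` and `y` labels embed
#' that label's planted motif under random filler structure, and an equal
#' number of neutral sentences contain filler only. Trees are emitted
#' directly (gold trees, no parser in the loop) so the learning algorithm is
#' isolated from parser variance; the sentence text is just the token join.
#'
#' By default (`vocab = NULL`) filler tokens are unique placeholder types,
#' so no accidental lexical overlap creates spurious discriminative signal
#' and the planted motifs are the only separating structure. Supplying a
#' finite `vocab` makes filler words recur across sentences, which produces
#' the spurious low-scoring patterns real corpora induce.
#'
#' @param classes Named list of per-class motif pairs (elements `x` and `y`,
#'   each a [motif()]). Default: a single "wait_time" class whose `x` motif
#'   is a negated long-wait construction and whose `y` motif is a
#'   waiting-room/hour construction.
#' @param n_per_label Sentences generated per (class, label) for each of
#'   `x`, `y` and `neutral`.
#' @param vocab Character vector of filler words, or `NULL` for unique
#'   placeholder tokens.
#' @param label_noise Probability that a sentence's label for a class is
#'   flipped to one of the other two labels.
#' @param motif_dropout Probability that a motif sentence omits its motif
#'   (keeping its label).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @param max_depth Maximum tree depth; motifs deeper than this are a
#'   configuration error.
#' @param filler_range Length-2 integer vector, min/max filler words per
#'   sentence.
#' @return A `dtc_synth_config`.
#' @export
synth_config <- function(classes = default_synth_classes(), n_per_label = 30,
                         vocab = NULL, label_noise = 0, motif_dropout = 0,
                         seed = 1, max_depth = 8,
                         filler_range = c(6L, 12L)) {
  stopifnot(n_per_label >= 1, label_noise >= 0, label_noise <= 1,
            motif_dropout >= 0, motif_dropout <= 1,
            length(filler_range) == 2L, filler_range[1] >= 1L)
  for (cl in names(classes)) {
    for (L in c("x", "y")) {
      m <- classes[[cl]][[L]]
      if (!inherits(m, "dtc_motif")) {
        stop("class '", cl, "' needs motifs for both 'x' and 'y'",
             call. = FALSE)
      }
      if (motif_depth(m) > max_depth) {
        stop("motif for class '", cl, "' label '", L,
             "' is deeper than max_depth", call. = FALSE)
      }
    }
  }
  structure(list(classes = classes, n_per_label = n_per_label, vocab = vocab,
                 label_noise = label_noise, motif_dropout = motif_dropout,
                 seed = seed, max_depth = max_depth,
                 filler_range = as.integer(filler_range)),
            class = "dtc_synth_config")
}

# relation labels used for filler structure; the negation label is reserved
# for motifs so planted negations stay discriminative
filler_relations <- c("nsubj", "dobj", "nmod", "amod", "advmod", "case",
                      "det", "compound", "conj", "cc", "mark", "aux")

#' Generate a labeled synthetic corpus
#'
#' @param config A [synth_config()].
#' @return A [dtc_corpus()] tibble with one class column per configured
#'   class and a logical `has_motif` column recording whether the sentence
#'   actually embeds its motif (the recovery ground truth).
#' @examples
#' corpus <- generate_corpus(synth_config(n_per_label = 2, seed = 7))
#' corpus$wait_time
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "dtc_synth_config"))
  class_ids <- names(config$classes)
  used <- new.env(parent = emptyenv())
  next_filler <- function() {
    if (!is.null(config$vocab)) return(sample(config$vocab, 1L))
    # unique random placeholder ids: random (not sequential) so that
    # lexicographic tie-breaking during word selection does not correlate
    # with generation order
    repeat {
      id <- sprintf("w%06d", sample.int(999999L, 1L))
      if (is.null(used[[id]])) {
        used[[id]] <- TRUE
        return(id)
      }
    }
  }
  withr::with_seed(config$seed, {
    rows <- list()
    for (cl in class_ids) {
      for (L in c("x", "y", "neutral")) {
        for (s in seq_len(config$n_per_label)) {
          embed <- L %in% c("x", "y") &&
            stats::runif(1) >= config$motif_dropout
          template <- if (embed) config$classes[[cl]][[L]]$template else NULL
          tree <- random_filler_tree(template, next_filler,
                                     config$filler_range, config$max_depth)
          labs <- stats::setNames(rep("neutral", length(class_ids)),
                                  class_ids)
          labs[cl] <- L
          # label noise: flip each class label to a uniform other label
          for (cl2 in class_ids) {
            if (stats::runif(1) < config$label_noise) {
              labs[cl2] <- sample(setdiff(c("x", "y", "neutral"),
                                          labs[cl2]), 1L)
            }
          }
          rows[[length(rows) + 1L]] <- list(
            text = NA_character_, tree = tree, labels = labs,
            has_motif = isTRUE(embed)
          )
        }
      }
    }
    labels <- do.call(rbind, lapply(rows, function(r) r$labels))
    trees <- lapply(rows, function(r) r$tree)
    corpus <- dtc_corpus(
      text = vapply(trees, function(t) paste(t$word, collapse = " "),
                    character(1)),
      tree = trees,
      labels = tibble::as_tibble(as.data.frame(labels,
                                               stringsAsFactors = FALSE)),
      classes = class_ids
    )
    corpus$has_motif <- vapply(rows, function(r) r$has_motif, logical(1))
    corpus
  })
}

# build a random filler skeleton and graft the motif template (if any)
# under a random filler node; filler words attach to nodes above max_depth
random_filler_tree <- function(template, next_filler, filler_range,
                               max_depth) {
  n_fill <- sample(seq.int(filler_range[1], filler_range[2]), 1L)
  word <- next_filler()
  parent <- 0L
  rel <- NA_character_
  pos <- "NN"
  depth <- 1L
  for (i in seq_len(n_fill - 1L)) {
    ok <- which(depth < max_depth)
    host <- ok[sample.int(length(ok), 1L)]
    word <- c(word, next_filler())
    parent <- c(parent, host)
    rel <- c(rel, sample(filler_relations, 1L))
    pos <- c(pos, sample(c("NN", "VB", "JJ", "RB", "IN", "DT"), 1L))
    depth <- c(depth, depth[host] + 1L)
  }
  if (!is.null(template)) {
    hosts <- which(depth + max(depth_vec(template)) + 1L <= max_depth)
    if (length(hosts) == 0L) hosts <- which(depth == 1L)
    host <- hosts[sample.int(length(hosts), 1L)]
    offset <- length(word)
    t_parent <- template$parent + offset
    t_parent[template$parent == 0L] <- host
    t_rel <- template$rel
    t_rel[template$parent == 0L] <- sample(filler_relations, 1L)
    word <- c(word, template$word)
    parent <- c(parent, t_parent)
    rel <- c(rel, t_rel)
    pos <- c(pos, template$pos)
  }
  dep_tree(word, parent, rel, pos = pos)
}
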