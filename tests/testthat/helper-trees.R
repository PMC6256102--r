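# fixtures and generators shared across test files

fig_tree_negated_wait <- function() {
  parse_bracketed_tree(paste0(
    "[are/VBP expl>there/EX neg>never/RB ",
    "nsubj>[times/NNS compound>[wait/NN amod>long/JJ]]]"
  ))
}

fig_tree_waiting_room <- function() {
  path <- system.file("extdata", "trees", "waiting_room_hour.tree",
                      package = "dtclass")
  parse_bracketed_tree(trimws(readLines(path, warn = FALSE))[1])
}

sample_wait_pattern <- "{} >neg {} >> ({word:wait} > {word:long})"

tree_vocab <- c("wait", "long", "time", "doctor", "staff", "visit", "room",
                "hour", "never", "friendly")
rel_vocab <- c("nsubj", "dobj", "amod", "nmod", "neg", "case", "det")
pos_vocab <- c("NN", "VB", "JJ", "RB")

random_tree <- function(max_nodes = 8) {
  n <- sample.int(max_nodes, 1)
  word <- sample(tree_vocab, n, replace = TRUE)
  parent <- c(0L, if (n > 1) vapply(2:n, function(i) {
    sample.int(i - 1L, 1)
  }, integer(1)))
  rel <- c(NA, sample(rel_vocab, n - 1, replace = TRUE))
  dep_tree(word, parent, rel, pos = sample(pos_vocab, n, replace = TRUE))
}

# random pattern source text with at most `max_nodes` nodes
random_pattern_text <- function(max_nodes = 4) {
  budget <- new.env()
  budget$left <- sample.int(max_nodes, 1)
  node_text <- function() {
    roll <- runif(1)
    if (roll < 0.3) "{}"
    else if (roll < 0.6) paste0("{word:", sample(tree_vocab, 1), "}")
    else if (roll < 0.8) paste0("{word:/", substr(sample(tree_vocab, 1), 1, 3), ".*/}")
    else paste0("{pos:", sample(pos_vocab, 1), "}")
  }
  gen <- function() {
    budget$left <- budget$left - 1L
    out <- node_text()
    while (budget$left > 0L && runif(1) < 0.6) {
      rel <- sample(c(">", ">>", paste0(">", sample(rel_vocab, 1))), 1)
      budget$left <- budget$left - 1L
      child <- if (budget$left > 0L && runif(1) < 0.3) {
        saved <- budget$left
        sub <- gen()
        budget$left <- min(budget$left, saved)
        paste0("(", sub, ")")
      } else {
        node_text()
      }
      out <- paste(out, rel, child)
    }
    out
  }
  gen()
}

# --- independent brute-force matcher -------------------------------------
# enumerates every assignment of pattern nodes to tree nodes and checks all
# constraints explicitly; used as the oracle for semgrex_matches()

flatten_pattern <- function(p) {
  nodes <- list()
  edges <- list()
  walk <- function(node) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- node$constraints
    for (rc in node$children) {
      cid <- walk(rc$node)
      edges[[length(edges) + 1L]] <<- list(from = id, to = cid,
                                           kind = rc$kind, type = rc$type)
    }
    id
  }
  walk(p$root)
  list(nodes = nodes, edges = edges)
}

brute_force_matches <- function(pattern, tree) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  flat <- flatten_pattern(pattern)
  k <- length(flat$nodes)
  n <- n_nodes(tree)
  attr_of <- function(a, i) {
    v <- switch(a, word = tree$word[i], lemma = tree$lemma[i],
                pos = tree$pos[i])
    tolower(v)
  }
  node_ok <- function(constraints, i) {
    for (a in names(constraints)) {
      v <- attr_of(a, i)
      if (is.na(v)) return(FALSE)
      cns <- constraints[[a]]
      ok <- if (cns$type == "exact") identical(v, tolower(cns$value))
            else grepl(paste0("^(?:", cns$value, ")$"), v,
                       perl = TRUE, ignore.case = TRUE)
      if (!ok) return(FALSE)
    }
    TRUE
  }
  anc <- function(i) {  # ancestors of i (governor chain)
    out <- integer(0)
    while (tree$parent[i] != 0L) {
      i <- tree$parent[i]
      out <- c(out, i)
    }
    out
  }
  assignments <- as.matrix(expand.grid(rep(list(seq_len(n)), k)))
  for (r in seq_len(nrow(assignments))) {
    f <- assignments[r, ]
    ok <- all(vapply(seq_len(k), function(q) node_ok(flat$nodes[[q]], f[q]),
                     logical(1)))
    if (!ok) next
    for (e in flat$edges) {
      gi <- f[e$from]; di <- f[e$to]
      ok <- if (e$kind == "indirect") {
        gi %in% anc(di)
      } else {
        tree$parent[di] == gi &&
          (is.null(e$type) || identical(tree$rel[di], e$type))
      }
      if (!ok) break
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# small hand-labeled corpus builder: trees given as bracketed strings
make_corpus <- function(trees, labels, class_id = "wait_time") {
  trees <- lapply(trees, function(x) {
    if (is.character(x)) parse_bracketed_tree(x) else x
  })
  labs <- tibble::as_tibble(stats::setNames(list(labels), class_id))
  dtc_corpus(
    text = vapply(trees, function(t) paste(t$word, collapse = " "),
                  character(1)),
    tree = trees, labels = labs
  )
}
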