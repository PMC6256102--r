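test_that("bracketed dialect parses the negated-wait sentence correctly", {
  t <- fig_tree_negated_wait()
  expect_equal(n_nodes(t), 6)
  root <- which(t$parent == 0L)
  expect_equal(t$word[root], "are")
  # edge (are, neg, never)
  never <- which(t$word == "never")
  expect_equal(t$parent[never], root)
  expect_equal(t$rel[never], "neg")
  # governor path are -> times -> wait -> long
  long <- which(t$word == "long")
  wait <- t$parent[long]
  times <- t$parent[wait]
  expect_equal(t$word[wait], "wait")
  expect_equal(t$word[times], "times")
  expect_equal(t$parent[times], root)
  expect_equal(t$pos, c("VBP", "EX", "RB", "NNS", "NN", "JJ"))
})

test_that("bracketed dialect handles degenerate and chained trees", {
  t1 <- parse_bracketed_tree("[a/DT]")
  expect_equal(n_nodes(t1), 1)
  expect_equal(t1$word, "a")
  expect_equal(format(t1), "[a/DT]")

  s <- "[a/DT x>[b/NN y>c/JJ]]"
  t3 <- parse_bracketed_tree(s)
  expect_equal(n_nodes(t3), 3)
  expect_equal(t3$parent, c(0L, 1L, 2L))
  expect_identical(format(t3), s)
})

test_that("bracketed parse errors name the offset", {
  expect_error(parse_bracketed_tree("[a/DT x>[b/NN]"), "offset.*missing ']'")
  expect_error(parse_bracketed_tree("[are wait/NN]"), "offset.*POS")
  expect_error(parse_bracketed_tree("[a/DT b/NN]"), "offset.*rel")
  expect_error(parse_bracketed_tree("a/DT"), "start with")
})

test_that("parse and serialize are inverse on random trees", {
  withr::with_seed(101, {
    for (i in 1:500) {
      t <- random_tree(10)
      s <- format(t)
      expect_identical(format(parse_bracketed_tree(s)), s)
    }
  })
})

test_that("CoNLL-U reader builds trees from standard blocks", {
  trees <- read_conllu(c(
    "1\twait\t_\t_\t_\t_\t2\tnsubj\t_\t_",
    "2\tare\t_\t_\t_\t_\t0\troot\t_\t_"
  ))
  expect_length(trees, 1)
  t <- trees[[1]]
  expect_equal(t$word, c("wait", "are"))
  expect_equal(t$parent, c(2L, 0L))
  expect_equal(t$rel[1], "nsubj")
})

test_that("CoNLL-U and bracketed encodings of one sentence are isomorphic", {
  conllu <- c(
    "# sent_id = wait1",
    "1\tthere\t_\tEX\t_\t_\t2\texpl\t_\t_",
    "2\tare\t_\tVBP\t_\t_\t0\troot\t_\t_",
    "3\tnever\t_\tRB\t_\t_\t2\tneg\t_\t_",
    "4\tlong\t_\tJJ\t_\t_\t5\tamod\t_\t_",
    "5\twait\t_\tNN\t_\t_\t6\tcompound\t_\t_",
    "6\ttimes\t_\tNNS\t_\t_\t2\tnsubj\t_\t_"
  )
  tc <- read_conllu(conllu)[[1]]
  tb <- fig_tree_negated_wait()
  canon <- function(t, i) {
    kids <- which(t$parent == i)
    subs <- sort(vapply(kids, function(k) {
      paste0(t$rel[k], ">", canon(t, k))
    }, character(1)))
    paste0(t$word[i], "(", paste(subs, collapse = ","), ")")
  }
  expect_identical(canon(tc, which(tc$parent == 0L)),
                   canon(tb, which(tb$parent == 0L)))
})

test_that("CoNLL-U reader flags malformed sentences and empty input", {
  expect_length(read_conllu(character(0)), 0)
  expect_length(read_conllu(""), 0)
  two_roots <- c("1\ta\t_\t_\t_\t_\t0\troot\t_\t_",
                 "2\tb\t_\t_\t_\t_\t0\troot\t_\t_")
  expect_error(read_conllu(two_roots), "exactly one root")
  out_of_range <- c("1\ta\t_\t_\t_\t_\t5\tdep\t_\t_",
                    "2\tb\t_\t_\t_\t_\t0\troot\t_\t_")
  expect_error(read_conllu(out_of_range), "HEAD out of range")
  cyclic <- c("1\ta\t_\t_\t_\t_\t2\tdep\t_\t_",
              "2\tb\t_\t_\t_\t_\t1\tdep\t_\t_",
              "3\tc\t_\t_\t_\t_\t0\troot\t_\t_")
  expect_error(read_conllu(cyclic), "cycle")
})

test_that("corpus reader applies the default-neutral and conflict rules", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"classes": ["wait_time"]}',
    '{"text": "s1", "tree": "[slow/JJ]", "labels": {"wait_time": "y"}}',
    '{"text": "s2", "tree": "[fast/JJ]", "labels": {"wait_time": "x"}}',
    '{"text": "s3", "tree": "[hello/UH]", "labels": {}}'
  ), path)
  corpus <- read_corpus(path)
  expect_s3_class(corpus, "dtc_corpus")
  expect_equal(nrow(corpus), 3)
  expect_equal(corpus$wait_time, c("y", "x", "neutral"))
  expect_equal(corpus_classes(corpus), "wait_time")

  conflict <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"classes": ["wait_time"]}',
    '{"text": "s1", "tree": "[slow/JJ]", "labels": {"wait_time": ["x", "y"]}}'
  ), conflict)
  expect_warning(c2 <- read_corpus(conflict), "both 'x' and 'y'")
  expect_true(is.na(c2$wait_time[1]))

  undeclared <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"classes": ["wait_time"]}',
    '{"text": "s1", "tree": "[slow/JJ]", "labels": {"foo": "x"}}'
  ), undeclared)
  expect_error(read_corpus(undeclared), "undeclared class 'foo'")
})

test_that("corpus reader accepts inline CoNLL-U and bad trees name the record", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"classes": ["wait_time"]}',
    '{"text": "s1", "conllu": ["1\\twait\\t_\\t_\\t_\\t_\\t0\\troot\\t_\\t_"], "labels": {}}',
    '{"text": "s2", "tree": "[broken", "labels": {}}'
  ), path)
  expect_error(read_corpus(path), "record 2")
})

test_that("corpus write/read round-trips labels and trees", {
  corpus <- make_corpus(
    list("[slow/JJ]", "[fast/JJ nsubj>visit/NN]", "[hello/UH]"),
    c("y", "x", "neutral")
  )
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corpus, path)
  back <- read_corpus(path)
  expect_equal(back$wait_time, corpus$wait_time)
  expect_equal(vapply(back$tree, format, character(1)),
               vapply(corpus$tree, format, character(1)))
})
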