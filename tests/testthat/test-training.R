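# brute-force information gain from the 2x2 contingency table
ig_oracle <- function(present, target) {
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  n <- length(target)
  prior <- h(table(target) / n)
  cond <- 0
  for (v in c(TRUE, FALSE)) {
    i <- present == v
    if (any(i)) cond <- cond + mean(i) * h(table(target[i]) / sum(i))
  }
  prior - cond
}

test_that("information gain matches the contingency-table oracle", {
  # 3 x-sentences all contain "wait", 3 others none: IG = full prior entropy
  corpus <- make_corpus(
    list("[wait/NN]", "[wait/NN amod>long/JJ]", "[wait/NN det>the/DT]",
         "[staff/NN]", "[doctor/NN]", "[visit/NN]"),
    c("x", "x", "x", "neutral", "y", "neutral")
  )
  ig <- information_gain_words(corpus, "wait_time", "x", n = 30)
  expect_equal(ig$word[1], "wait")
  expect_equal(ig$gain[1], 1, tolerance = 1e-12)  # H(1/2) = 1 bit
  # all words agree with the oracle
  target <- corpus$wait_time == "x"
  for (r in seq_len(nrow(ig))) {
    present <- vapply(corpus$tree, function(t) {
      ig$word[r] %in% tolower(t$word)
    }, logical(1))
    expect_equal(ig$gain[r], ig_oracle(present, target), tolerance = 1e-12,
                 label = ig$word[r])
  }
})

test_that("ubiquitous words have zero gain and ties break lexicographically", {
  corpus <- make_corpus(
    list("[the/DT x>wait/NN]", "[the/DT x>staff/NN]"),
    c("x", "neutral")
  )
  ig <- information_gain_words(corpus, "wait_time", "x", n = 10)
  expect_equal(ig$gain[ig$word == "the"], 0, tolerance = 1e-12)
  # "staff" and "wait" have mirror-image tables -> equal gain; order is
  # lexicographic within the tie
  tied <- ig[ig$word %in% c("staff", "wait"), ]
  expect_equal(tied$gain[1], tied$gain[2], tolerance = 1e-12)
  expect_identical(tied$word, c("staff", "wait"))
  # n caps the list
  expect_equal(nrow(information_gain_words(corpus, "wait_time", "x", 2)), 2)
})

test_that("pattern weighted accuracy follows the per-label definition", {
  # pattern matches both x instances, misses the y, matches the neutral:
  # acc_x = 1, acc_y = 1 (unmatched non-target is correct), acc_0 = 0
  corpus <- make_corpus(
    list("[wait/NN]", "[wait/NN amod>long/JJ]", "[doctor/NN]",
         "[wait/VB nsubj>i/PRP]"),
    c("x", "x", "y", "neutral")
  )
  s <- pattern_weighted_accuracy("{word:wait}", "x", corpus, "wait_time")
  expect_equal(as.numeric(s), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(attr(s, "per_label")), c(1, 1, 0))

  # a pattern that matches everything scores 1/3 when all labels occur
  s_all <- pattern_weighted_accuracy("{}", "x", corpus, "wait_time")
  expect_equal(as.numeric(s_all), 1 / 3, tolerance = 1e-12)

  # a pattern matching exactly the target label scores 1
  s_perfect <- pattern_weighted_accuracy("{word:wait;pos:NN}", "x",
                                         corpus, "wait_time")
  expect_equal(as.numeric(s_perfect), 1, tolerance = 1e-12)
})

test_that("a perfectly separating planted pattern ranks first with score 1", {
  corpus <- make_corpus(
    list("[are/VBP neg>never/RB nsubj>[times/NNS compound>[wait/NN amod>long/JJ]]]",
         "[are/VBP neg>not/RB nsubj>[wait/NN amod>long/JJ]]",
         "[doctor/NN amod>great/JJ]",
         "[staff/NN amod>friendly/JJ]",
         "[waited/VBD nmod>hour/NN]",
         "[waited/VBD nmod>hours/NNS]"),
    c("x", "x", "neutral", "neutral", "y", "y")
  )
  model <- dtc(corpus, "wait_time", n_x = 5, n_y = 5, m = 3)
  expect_s3_class(model, "dtc_model")
  td <- tidy(model)
  expect_equal(td$score[1], 1)
  expect_true(all(diff(td$score) <= 0))           # non-increasing
  expect_true(all(td$score >= 0 & td$score <= 1))
  # top x-pattern matches exactly the x sentences
  top_x <- model$ranked$pattern[[min(which(model$ranked$label == "x"))]]
  hits <- vapply(corpus$tree, semgrex_matches, logical(1), pattern = top_x)
  expect_identical(hits, corpus$wait_time == "x")
})

test_that("training is deterministic and duplicate-invariant", {
  corpus <- generate_corpus(synth_config(n_per_label = 6, seed = 21))
  m1 <- dtc(corpus, "wait_time")
  m2 <- dtc(corpus, "wait_time")
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_dtc_model(m1, f1)
  write_dtc_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # duplicating every sentence leaves all scores unchanged (ratio invariance)
  doubled <- dtclass:::subset_corpus(corpus, rep(seq_len(nrow(corpus)), 2))
  m3 <- dtc(doubled, "wait_time")
  expect_identical(m1$ranked$pattern_text, m3$ranked$pattern_text)
  expect_equal(m1$ranked$score, m3$ranked$score, tolerance = 1e-12)
})

test_that("degenerate corpora warn and fall back", {
  corpus <- make_corpus(list("[doctor/NN]", "[staff/NN]"),
                        c("neutral", "neutral"))
  w <- capture_warnings(model <- dtc(corpus, "wait_time"))
  expect_true(any(grepl("no 'x' sentences", w)))
  expect_true(any(grepl("no patterns extracted", w)))
  expect_equal(nrow(model$ranked), 0)
  expect_equal(model$majority_label, "neutral")
  pred <- predict(model, corpus)
  expect_true(all(pred$via_fallback))
  expect_true(all(pred$predicted == "neutral"))
  expect_error(dtc(corpus, "nope"), "unknown class")
})

test_that("model files round-trip through write and read", {
  corpus <- generate_corpus(synth_config(n_per_label = 4, seed = 33))
  model <- dtc(corpus, "wait_time")
  path <- withr::local_tempfile()
  write_dtc_model(model, path)
  back <- read_dtc_model(path)
  expect_equal(back$class_id, model$class_id)
  expect_equal(back$majority_label, model$majority_label)
  expect_equal(back$config$m, model$config$m)
  expect_identical(back$ranked$pattern_text, model$ranked$pattern_text)
  expect_equal(back$ranked$score, model$ranked$score, tolerance = 1e-15)
  # re-serialization is byte-identical
  path2 <- withr::local_tempfile()
  write_dtc_model(back, path2)
  expect_identical(readLines(path2), readLines(path))
  # predictions agree
  p1 <- predict(model, corpus)
  p2 <- predict(back, corpus)
  expect_identical(p1$predicted, p2$predicted)
})
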