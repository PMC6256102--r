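# a model with a hand-written ranked list, bypassing training
manual_model <- function(ranked_df, majority = "neutral") {
  ranked_df$pattern <- lapply(ranked_df$pattern_text, parse_pattern)
  structure(list(
    class_id = "wait_time",
    ranked = tibble::as_tibble(ranked_df),
    config = list(n_x = 30, n_y = 30, m = 4, negation_label = "neg",
                  top_k = NULL),
    fallback = "majority",
    backup = NULL,
    majority_label = majority,
    n_train = 0L
  ), class = "dtc_model")
}

test_that("classification follows rank order and falls back on no match", {
  model <- manual_model(data.frame(
    pattern_text = c("{word:wait}", "{word:/wait.*/}"),
    label = c("x", "y"),
    score = c(0.9, 0.8)
  ))
  both <- parse_bracketed_tree("[wait/NN]")       # matched by both patterns
  p <- predict(model, both)
  expect_equal(p$predicted, "x")                  # rank order decides
  expect_false(p$via_fallback)
  expect_equal(p$pattern_text, "{word:wait}")

  lower_only <- parse_bracketed_tree("[waited/VBD]")
  expect_equal(predict(model, lower_only)$predicted, "y")

  nothing <- parse_bracketed_tree("[doctor/NN]")
  p3 <- predict(model, nothing)
  expect_equal(p3$predicted, "neutral")
  expect_true(p3$via_fallback)
  expect_true(is.na(p3$pattern_text))
})

test_that("a backup classifier receives unmatched sentences", {
  model <- manual_model(data.frame(
    pattern_text = "{word:wait}", label = "x", score = 1
  ))
  model$fallback <- "backup"
  model$backup <- function(text) if (grepl("slow", text)) "y" else "neutral"
  corpus <- make_corpus(list("[wait/NN]", "[slow/JJ]", "[fast/JJ]"),
                        c("x", "y", "neutral"))
  p <- predict(model, corpus)
  expect_equal(p$predicted, c("x", "y", "neutral"))
  expect_equal(p$via_fallback, c(FALSE, TRUE, TRUE))
})

test_that("evaluation reproduces the metric identities", {
  corpus <- make_corpus(
    list("[wait/NN]", "[wait/NN amod>long/JJ]", "[waited/VBD]",
         "[doctor/NN]", "[staff/NN]", "[visit/NN]"),
    c("x", "x", "y", "neutral", "neutral", "neutral")
  )
  # perfect classifier: weighted accuracy exactly 1
  perfect <- manual_model(data.frame(
    pattern_text = c("{word:wait;pos:NN}", "{word:waited}"),
    label = c("x", "y"), score = c(1, 1)
  ))
  ev <- dtc_evaluate(perfect, corpus)
  expect_equal(ev$weighted_accuracy, 1)
  expect_equal(sum(ev$predictions$via_fallback), 3)

  # constant-neutral classifier on a three-label corpus: exactly 1/3
  constant <- manual_model(data.frame(
    pattern_text = character(0), label = character(0), score = numeric(0)
  ))
  ev0 <- dtc_evaluate(constant, corpus)
  expect_identical(ev0$weighted_accuracy, 1 / 3)
  expect_equal(tidy(ev0)$accuracy, c(0, 0, 1))
})

test_that("evaluation measures derive from the confusion counts", {
  # gold x,x,y,y,0,0,0,0 with predictions giving confusion
  # [[2,0,0],[1,1,0],[0,0,4]] -> per-label (1.0, 0.5, 1.0), weighted 5/6
  corpus <- make_corpus(
    list("[wait/NN]", "[wait/NN det>the/DT]",
         "[wait/VB mark>to/TO]", "[waited/VBD]",
         "[doctor/NN]", "[staff/NN]", "[visit/NN]", "[nurse/NN]"),
    c("x", "x", "y", "y", "neutral", "neutral", "neutral", "neutral")
  )
  model <- manual_model(data.frame(
    pattern_text = c("{word:/wait.*/;pos:/NN.*/}", "{word:wait;pos:VB}",
                     "{word:waited}"),
    label = c("x", "x", "y"), score = c(0.9, 0.8, 0.7)
  ))
  ev <- dtc_evaluate(model, corpus)
  expect_equal(unclass(ev$confusion)[, ],
               matrix(c(2, 0, 0, 1, 1, 0, 0, 0, 4), nrow = 3, byrow = TRUE,
                      dimnames = dimnames(ev$confusion)))
  expect_equal(tidy(ev)$accuracy, c(1, 0.5, 1))
  expect_equal(ev$weighted_accuracy, 5 / 6)
  # internal consistency: weighted accuracy is the mean of per-label values
  expect_equal(ev$weighted_accuracy, mean(tidy(ev)$accuracy))
  # row sums equal gold label frequencies
  expect_equal(unname(rowSums(ev$confusion)), c(2, 2, 4))
  # predicted-correct ratio: 2 of 3 predicted x are gold x; 1 of 1 for y
  expect_equal(tidy(ev)$predicted_correct, c(2 / 3, 1, NA))
})

test_that("labels absent from the corpus are excluded with a warning", {
  corpus <- make_corpus(list("[wait/NN]", "[doctor/NN]"), c("x", "neutral"))
  model <- manual_model(data.frame(
    pattern_text = "{word:wait}", label = "x", score = 1
  ))
  expect_warning(ev <- dtc_evaluate(model, corpus), "absent")
  expect_true(is.na(tidy(ev)$accuracy[tidy(ev)$label == "y"]))
  expect_equal(ev$weighted_accuracy, 1)  # mean over present labels
})

test_that("cross-validation is stratified, seeded and reproducible", {
  corpus <- generate_corpus(synth_config(n_per_label = 10, seed = 77))
  cv1 <- dtc_cross_validate(corpus, "wait_time", k = 5, seed = 9,
                            n_x = 10, n_y = 10, m = 3)
  cv2 <- dtc_cross_validate(corpus, "wait_time", k = 5, seed = 9,
                            n_x = 10, n_y = 10, m = 3)
  expect_identical(tidy(cv1), tidy(cv2))
  expect_identical(cv1$mean_weighted_accuracy, cv2$mean_weighted_accuracy)
  # stratification: each fold holds 2 of each label
  expect_true(all(tidy(cv1)$n_test == 6))
  # separable planted motifs classify perfectly
  expect_equal(cv1$mean_weighted_accuracy, 1)
})

test_that("leave-one-out structure and degenerate fold warnings", {
  corpus <- generate_corpus(synth_config(n_per_label = 2, seed = 5))
  w <- capture_warnings(
    cv <- dtc_cross_validate(corpus, "wait_time", k = 6, seed = 1,
                             n_x = 5, n_y = 5, m = 2)
  )
  expect_true(any(grepl("fewer sentences than folds", w)))
  expect_equal(nrow(tidy(cv)), 6)
  # leave-one-out structure: 6 sentences over 6 folds, one held out each
  expect_true(all(tidy(cv)$n_test == 1))
  expect_error(dtc_cross_validate(corpus, "wait_time", k = 10),
               "exceeds")
})

test_that("tidiers and autoplot expose the evaluation results", {
  corpus <- generate_corpus(synth_config(n_per_label = 4, seed = 15))
  model <- dtc(corpus, "wait_time", n_x = 10, n_y = 10, m = 3)
  expect_s3_class(tidy(model), "tbl_df")
  expect_named(glance(model),
               c("class_id", "n_patterns", "n_train", "majority_label",
                 "n_x", "n_y", "m"))
  ev <- dtc_evaluate(model, corpus)
  expect_named(tidy(ev), c("label", "n", "accuracy", "predicted_correct"))
  expect_equal(glance(ev)$weighted_accuracy, ev$weighted_accuracy)
  p <- ggplot2::autoplot(ev)
  expect_s3_class(p, "ggplot")
})

test_that("relative improvement arithmetic", {
  expect_equal(relative_improvement(60, 50), 20)
  expect_equal(relative_improvement(50, 50), 0)
})
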