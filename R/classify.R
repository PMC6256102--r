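#' Classify sentences with a fitted pattern model
#'
#' Scans the ranked pattern list in order and assigns the label of the
#' highest-ranked matching pattern. When no pattern matches, the sentence is
#' classified by the fallback policy: the most common training label, or a
#' user-supplied backup classifier called with the sentence text.
#'
#' @param object A `dtc_model` from [dtc()].
#' @param newdata A [dtc_corpus()], a list of [dep_tree()] objects, or a
#'   single `dep_tree`.
#' @param ... Internal: `.session` / `.rows` to reuse a shared match
#'   session.
#' @return A tibble with one row per sentence: `predicted`, `pattern_text`
#'   (`NA` on fallback), `score`, `via_fallback`.
#' @export
predict.dtc_model <- function(object, newdata, ...) {
  dots <- list(...)
  if (inherits(newdata, "dep_tree")) newdata <- list(newdata)
  trees <- if (inherits(newdata, "dtc_corpus")) newdata$tree else newdata
  texts <- if (inherits(newdata, "dtc_corpus")) newdata$text else
    rep(NA_character_, length(trees))
  session <- dots$.session
  rows <- dots$.rows
  if (is.null(session)) {
    session <- build_match_session(trees)
    rows <- seq_along(trees)
  }
  ranked <- object$ranked
  n <- length(trees)
  predicted <- rep(NA_character_, n)
  pattern_text <- rep(NA_character_, n)
  score <- rep(NA_real_, n)
  open <- rep(TRUE, n)
  for (r in seq_len(nrow(ranked))) {
    if (!any(open)) break
    hits <- session_pattern_hits(session, ranked$pattern[[r]])[rows]
    take <- open & hits
    if (any(take)) {
      predicted[take] <- ranked$label[[r]]
      pattern_text[take] <- ranked$pattern_text[[r]]
      score[take] <- ranked$score[[r]]
      open[take] <- FALSE
    }
  }
  if (any(open)) {
    predicted[open] <- if (object$fallback == "backup" &&
                           is.function(object$backup)) {
      vapply(texts[open], object$backup, character(1), USE.NAMES = FALSE)
    } else {
      object$majority_label
    }
  }
  tibble::tibble(predicted = predicted, pattern_text = pattern_text,
                 score = score, via_fallback = open)
}

#' Evaluate a model on a labeled corpus
#'
#' Computes the three evaluation measures for one opinion class: the
#' per-label accuracy (fraction of sentences of each gold label classified
#' correctly), the predicted-correct ratio (among sentences *predicted*
#' `x` or `y`, the fraction whose gold label agrees), and the weighted
#' accuracy, the unweighted mean of the per-label accuracies. A gold label
#' absent from the corpus is reported as `NA` and excluded from the mean
#' with a warning. Sentences whose label is `NA` (dropped at load time) are
#' excluded from all denominators.
#'
#' @param model A `dtc_model`.
#' @param corpus A [dtc_corpus()] labeled for the model's class.
#' @param class_id Class id (defaults to the model's).
#' @param .session,.rows Internal: shared match session and row indices,
#'   used by cross-validation.
#' @return A `dtc_eval` object: per-label tibble, weighted accuracy, 3x3
#'   confusion matrix (gold rows, predicted columns) and the prediction
#'   tibble.
#' @export
dtc_evaluate <- function(model, corpus, class_id = model$class_id,
                         .session = NULL, .rows = NULL) {
  if (!class_id %in% corpus_classes(corpus)) {
    stop("corpus is not labeled for class '", class_id, "'", call. = FALSE)
  }
  labels <- corpus[[class_id]]
  keep <- which(!is.na(labels))
  if (length(keep) == 0L) stop("no usable sentences for class '", class_id,
                               "'", call. = FALSE)
  gold <- labels[keep]
  preds <- if (is.null(.session)) {
    predict(model, corpus$tree[keep])
  } else {
    predict(model, corpus$tree[keep], .session = .session,
            .rows = .rows[keep])
  }
  preds$gold <- gold
  levels3 <- c("x", "y", "neutral")
  confusion <- table(factor(gold, levels = levels3),
                     factor(preds$predicted, levels = levels3),
                     dnn = c("gold", "predicted"))
  per_label <- tibble::tibble(
    label = levels3,
    n = vapply(levels3, function(L) sum(gold == L), numeric(1),
               USE.NAMES = FALSE),
    accuracy = vapply(levels3, function(L) {
      i <- gold == L
      if (!any(i)) return(NA_real_)
      mean(preds$predicted[i] == L)
    }, numeric(1), USE.NAMES = FALSE),
    predicted_correct = vapply(levels3, function(L) {
      if (L == "neutral") return(NA_real_)
      i <- preds$predicted == L
      if (!any(i)) return(NA_real_)
      mean(gold[i] == L)
    }, numeric(1), USE.NAMES = FALSE)
  )
  missing <- per_label$label[is.na(per_label$accuracy)]
  if (length(missing) > 0L) {
    warning("label(s) absent from the corpus and excluded from the weighted accuracy: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(
    class_id = class_id,
    per_label = per_label,
    weighted_accuracy = mean(per_label$accuracy, na.rm = TRUE),
    confusion = confusion,
    predictions = preds
  ), class = "dtc_eval")
}

#' @export
print.dtc_eval <- function(x, ...) {
  cat("Evaluation for class '", x$class_id, "'\n", sep = "")
  cat(sprintf("  weighted accuracy: %.4f\n", x$weighted_accuracy))
  df <- as.data.frame(x$per_label)
  df$accuracy <- sprintf("%.4f", df$accuracy)
  df$predicted_correct <- sprintf("%.4f", df$predicted_correct)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @rdname dtc_evaluate
#' @param x A `dtc_eval`.
#' @param ... Unused.
#' @export
tidy.dtc_eval <- function(x, ...) x$per_label

#' @rdname dtc_evaluate
#' @export
glance.dtc_eval <- function(x, ...) {
  tibble::tibble(class_id = x$class_id,
                 weighted_accuracy = x$weighted_accuracy,
                 n = sum(x$per_label$n))
}

#' Plot per-label evaluation accuracies
#'
#' @param object A `dtc_eval`.
#' @param ... Unused.
#' @return A ggplot object: per-label accuracy bars with the weighted
#'   accuracy as a dashed reference line.
#' @export
autoplot.dtc_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_label, c("accuracy", "predicted_correct"),
                            names_to = "measure", values_to = "value")
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$value,
                                   fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$weighted_accuracy,
                        linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "ratio",
                  title = paste0("Class '", object$class_id, "'"),
                  subtitle = sprintf("weighted accuracy %.3f",
                                     object$weighted_accuracy)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stratified k-fold cross-validation
#'
#' Splits the class's usable sentences into `k` folds stratified by gold
#' label (each label's sentences are shuffled with the given seed and dealt
#' round-robin), trains on `k - 1` folds and evaluates on the held-out fold,
#' and reports per-fold and mean weighted accuracy. A label with fewer
#' sentences than folds simply misses some folds, with a warning.
#'
#' @inheritParams dtc
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @param ... Passed on to [dtc()].
#' @return A `dtc_cv` object with a per-fold tibble, the fold reports, and
#'   the mean weighted accuracy.
#' @export
dtc_cross_validate <- function(corpus, class_id, k = 10, seed = 1, ...) {
  stopifnot(k >= 2)
  labels <- corpus[[class_id]]
  usable <- which(!is.na(labels))
  if (k > length(usable)) stop("k exceeds the number of usable sentences",
                               call. = FALSE)
  low <- names(which(table(labels[usable]) < k))
  if (length(low) > 0L) {
    warning("label(s) with fewer sentences than folds (stratification degrades): ",
            paste(low, collapse = ", "), call. = FALSE)
  }
  # stratified, balanced assignment: each label's shuffled sentences go to
  # the currently least-loaded folds, so fold sizes differ by at most one
  # and every fold is non-empty when n >= k
  fold <- integer(length(usable))
  withr::with_seed(seed, {
    load <- integer(k)
    for (L in unique(labels[usable])) {
      i <- which(labels[usable] == L)
      i <- i[sample.int(length(i))]
      for (j in i) {
        cand <- which(load == min(load))
        f <- cand[sample.int(length(cand), 1L)]
        fold[j] <- f
        load[f] <- load[f] + 1L
      }
    }
  })
  session <- build_match_session(corpus$tree)
  reports <- vector("list", k)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    train_idx <- usable[fold != f]
    test_idx <- usable[fold == f]
    model <- dtc(subset_corpus(corpus, train_idx), class_id, ...,
                 .session = session, .rows = train_idx)
    rep_f <- suppressWarnings(
      dtc_evaluate(model, subset_corpus(corpus, test_idx), class_id,
                   .session = session, .rows = test_idx)
    )
    reports[[f]] <- rep_f
    rows[[f]] <- tibble::tibble(fold = f, n_test = length(test_idx),
                                weighted_accuracy = rep_f$weighted_accuracy)
  }
  folds <- dplyr::bind_rows(rows)
  structure(list(
    class_id = class_id,
    k = k,
    seed = seed,
    folds = folds,
    reports = reports,
    mean_weighted_accuracy = mean(folds$weighted_accuracy)
  ), class = "dtc_cv")
}

subset_corpus <- function(corpus, idx) {
  out <- corpus[idx, ]
  attr(out, "classes") <- attr(corpus, "classes")
  class(out) <- class(corpus)
  out
}

#' @export
print.dtc_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation for class '%s' (seed %d)\n",
              x$k, x$class_id, x$seed))
  cat(sprintf("  mean weighted accuracy: %.4f\n", x$mean_weighted_accuracy))
  invisible(x)
}

#' @rdname dtc_cross_validate
#' @param x A `dtc_cv`.
#' @export
tidy.dtc_cv <- function(x, ...) x$folds

#' @rdname dtc_cross_validate
#' @export
glance.dtc_cv <- function(x, ...) {
  tibble::tibble(class_id = x$class_id, k = x$k, seed = x$seed,
                 mean_weighted_accuracy = x$mean_weighted_accuracy)
}

#' Relative improvement between two reported accuracies
#'
#' Percentage improvement of `value` over `reference`,
#' `100 * (value - reference) / reference`; the arithmetic used when
#' comparing two classifiers' average weighted accuracies.
#'
#' @param value,reference Numeric values on the same scale.
#' @return Percentage improvement.
#' @examples
#' relative_improvement(57.05, 55.83)
#' @export
relative_improvement <- function(value, reference) {
  100 * (value - reference) / reference
}
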