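#' Two-stage laxity classification
#'
#' Stage 1 assigns each recording a speed class from the four pivot-segment
#' features; stage 2 assigns a CDP laxity grade with one model per class,
#' trained only on that class's training cases. A class never seen in
#' training makes its test cases "unclassifiable" rather than forcing a
#' guess, and the proportion of classifiable cases is reported alongside
#' the metrics. A raw-signal baseline (the 500 X-axis samples as features)
#' is provided for comparison; with small cohorts it performs near chance,
#' which is what motivates the pivot-segment preprocessing.
#'
#' @name classification
NULL

#' Train/test split specification
#'
#' @param per_grade_test_count Test cases drawn per eligible grade
#'   (default 3).
#' @param min_grade_count_for_test Grades with fewer cases than this
#'   contribute no test cases (default 3); mirrors holding back the
#'   two-subject grade-3 stratum from testing.
#' @param seed Seed for the without-replacement draw.
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(per_grade_test_count = 3,
                       min_grade_count_for_test = 3, seed = 1) {
  if (per_grade_test_count < 0 || min_grade_count_for_test < 0)
    stop("counts must be >= 0")
  structure(list(per_grade_test_count = as.integer(per_grade_test_count),
                 min_grade_count_for_test =
                   as.integer(min_grade_count_for_test),
                 seed = seed), class = "split_spec")
}

#' Stratified per-grade train/test split
#'
#' For each grade with at least `min_grade_count_for_test` cases, exactly
#' `per_grade_test_count` cases are drawn (seeded, without replacement)
#' into the test set; all remaining cases train. Disjoint and exhaustive.
#'
#' @param data data.frame with a `grade` column (e.g. from
#'   [recording_features()]).
#' @param spec A [split_spec()].
#' @return List with `train` and `test` data.frames.
#' @examples
#' d <- data.frame(id = 1:30, grade = rep(c(0, 1, 2, 3), c(10, 9, 9, 2)))
#' sp <- split_train_test(d, split_spec(seed = 7))
#' nrow(sp$test)  # 9: three per grade, none from the 2-case grade 3
#' @export
split_train_test <- function(data, spec = split_spec()) {
  if (nrow(data) == 0) stop("empty dataset")
  if (!"grade" %in% names(data)) stop("data must carry a grade column")
  test_idx <- integer(0)
  with_seed(spec$seed, {
    for (g in sort(unique(data$grade))) {
      rows <- which(data$grade == g)
      if (length(rows) >= spec$min_grade_count_for_test) {
        take <- min(spec$per_grade_test_count, length(rows))
        test_idx <- c(test_idx, sort(sample(rows, take)))
      }
    }
  })
  list(train = data[setdiff(seq_len(nrow(data)), test_idx), , drop = FALSE],
       test = data[test_idx, , drop = FALSE])
}

#' Raw-signal baseline classifier
#'
#' Fits one of the four methods directly on the raw X-axis samples (one
#' feature per sample), the approach the preprocessing pipeline is compared
#' against.
#'
#' @param recordings List of [gyro_recording()].
#' @param grades Vector of grade labels, one per recording.
#' @param method Classifier method, see [fit_classifier()].
#' @param seed Seed.
#' @param resample_to Resample recordings of differing length to this many
#'   samples by linear interpolation; `NULL` (default) errors on mixed
#'   lengths.
#' @return A `psm_model` whose `predict_raw` interface is
#'   [predict_baseline_raw()].
#' @export
train_baseline_raw <- function(recordings, grades, method = "svm", seed = 1,
                               resample_to = NULL) {
  x <- raw_matrix(recordings, resample_to)
  model <- fit_classifier(x, grades, method, seed = seed)
  model$resample_to <- resample_to
  model
}

#' @rdname train_baseline_raw
#' @param model Model from [train_baseline_raw()].
#' @export
predict_baseline_raw <- function(model, recordings) {
  predict_classifier(model, raw_matrix(recordings, model$resample_to))
}

raw_matrix <- function(recordings, resample_to = NULL) {
  lens <- vapply(recordings, function(r) length(r$x), integer(1))
  if (length(unique(lens)) > 1) {
    if (is.null(resample_to))
      stop("recordings have mixed lengths (", paste(unique(lens),
           collapse = ", "), "); set resample_to to interpolate")
  }
  n_out <- if (is.null(resample_to)) lens[1] else as.integer(resample_to)
  t(vapply(recordings, function(r) {
    if (length(r$x) == n_out) r$x
    else stats::approx(seq_along(r$x), r$x, n = n_out)$y
  }, numeric(n_out)))
}

#' Train stage 1: speed class from pivot features
#'
#' @param train data.frame with the [feature_columns()] and a `klass`
#'   column.
#' @param method Classifier method (default `"svm"`, the method found best
#'   for the class stage).
#' @param seed Seed.
#' @return A `psm_model`.
#' @export
train_stage1_class <- function(train, method = "svm", seed = 1) {
  fit_classifier(as.matrix(train[, feature_columns()]), train$klass,
                 method, seed = seed)
}

#' Train stage 2: laxity grade within each class
#'
#' One model per speed class present in training, fitted on that class's
#' cases only. Classes absent from training are flagged unclassifiable.
#'
#' @param train data.frame with [feature_columns()], `klass` and `grade`.
#' @param method Classifier method (default `"dt"`, the method found best
#'   for the grade stage).
#' @param seed Seed.
#' @return A list of class `stage2_models`: one `psm_model` per class label.
#' @export
train_stage2_grade <- function(train, method = "dt", seed = 1) {
  models <- list()
  for (k in sort(unique(train$klass))) {
    d <- train[train$klass == k, , drop = FALSE]
    models[[as.character(k)]] <-
      fit_classifier(as.matrix(d[, feature_columns()]), d$grade,
                     method, seed = seed)
  }
  structure(models, class = "stage2_models")
}

#' Two-stage prediction
#'
#' Stage 1 predicts the class from the features; stage 2 applies that
#' class's grade model. Cases routed to a class without a trained model are
#' returned as `"unclassifiable"`.
#'
#' @param stage1 Model from [train_stage1_class()].
#' @param stage2 Models from [train_stage2_grade()].
#' @param newdata data.frame with [feature_columns()].
#' @return Character vector of grades (or `"unclassifiable"`), with the
#'   stage-1 class predictions as attribute `"klass"`.
#' @export
predict_two_stage <- function(stage1, stage2, newdata) {
  x <- as.matrix(newdata[, feature_columns()])
  kl <- predict_classifier(stage1, x)
  out <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    m <- stage2[[kl[i]]]
    out[i] <- if (is.null(m)) "unclassifiable"
              else predict_classifier(m, x[i, , drop = FALSE])
  }
  attr(out, "klass") <- kl
  out
}

#' Evaluate predictions against truth
#'
#' Micro-averaged multi-class metrics: with complete single-label
#' predictions, accuracy, recall and precision coincide (each equals the
#' trace of the confusion matrix over its total), as do the published
#' per-method metric tables. Unclassifiable cases are excluded from the
#' confusion matrix and reported through the classifiability ratio.
#'
#' @param predictions Character/numeric vector; `"unclassifiable"` allowed.
#' @param truth Vector of true labels, same length.
#' @return A list of class `eval_report`: `accuracy`, `recall`, `precision`
#'   (percent), `f1` (0-1), `confusion_matrix` (rows = truth, columns =
#'   predicted), `n_test`, `n_classifiable`, `classifiability_pct`.
#' @examples
#' evaluate_predictions(c(0, 1, 1), c(0, 1, 0))$accuracy  # 66.67 (%)
#' @export
evaluate_predictions <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    stop("predictions and truth differ in length")
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  ok <- predictions != "unclassifiable"
  lev <- sort(unique(c(truth, predictions[ok])))
  cm <- table(factor(truth[ok], levels = lev),
              factor(predictions[ok], levels = lev))
  n_cl <- sum(ok)
  acc <- if (n_cl > 0) 100 * sum(diag(cm)) / n_cl else NA_real_
  structure(list(
    accuracy = acc, recall = acc, precision = acc,
    f1 = if (is.na(acc)) NA_real_ else acc / 100,
    confusion_matrix = cm, n_test = length(truth),
    n_classifiable = n_cl,
    classifiability_pct = 100 * n_cl / length(truth)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> accuracy = %.2f%%  (micro recall/precision identical)\n",
    x$accuracy))
  cat(sprintf("  classifiable: %d / %d (%.1f%%)\n", x$n_classifiable,
              x$n_test, x$classifiability_pct))
  print(x$confusion_matrix)
  invisible(x)
}

#' Run the full two-stage experiment on a feature table
#'
#' Splits recordings by the per-grade rule, trains stage 1 and stage 2, and
#' evaluates grade predictions on the held-out test set.
#'
#' @param features Recording-level feature table
#'   ([recording_features()]) with `klass` and `grade` columns.
#' @param stage1_method,stage2_method Classifier methods (defaults SVM and
#'   decision tree, the best-performing pair).
#' @param spec A [split_spec()].
#' @param seed Seed for training.
#' @return List with `report` (an `eval_report`), `stage1`, `stage2`,
#'   `split`, `predictions`.
#' @export
run_two_stage <- function(features, stage1_method = "svm",
                          stage2_method = "dt", spec = split_spec(),
                          seed = 1) {
  sp <- split_train_test(features, spec)
  s1 <- train_stage1_class(sp$train, stage1_method, seed = seed)
  s2 <- train_stage2_grade(sp$train, stage2_method, seed = seed)
  pred <- predict_two_stage(s1, s2, sp$test)
  list(report = evaluate_predictions(pred, sp$test$grade),
       stage1 = s1, stage2 = s2, split = sp, predictions = pred)
}

#' Accuracy of uniform-random label assignment
#'
#' The chance level against which the classifiers are judged: assigning one
#' of `n_labels` labels uniformly at random is correct with probability
#' `1 / n_labels` (25% for the four laxity grades), irrespective of the
#' label distribution of the test set.
#'
#' @param n_labels Number of labels.
#' @param n_cases Simulated test-set size per replicate.
#' @param n_rep Replicates.
#' @param seed Seed (`NULL` to use the current RNG state).
#' @return List with `analytic_pct` and `simulated_pct`.
#' @export
chance_level <- function(n_labels = 4, n_cases = 100, n_rep = 100,
                         seed = 1) {
  sim <- function() {
    mean(vapply(seq_len(n_rep), function(i) {
      truth <- sample.int(n_labels, n_cases, replace = TRUE)
      guess <- sample.int(n_labels, n_cases, replace = TRUE)
      mean(guess == truth)
    }, numeric(1)))
  }
  simulated <- if (is.null(seed)) sim() else with_seed(seed, sim())
  list(analytic_pct = 100 / n_labels, simulated_pct = 100 * simulated)
}
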