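test_that("the per-grade split rule reproduces the 9-case test group", {
  d <- data.frame(id = 1:30, grade = rep(c(0, 1, 2, 3), c(10, 9, 9, 2)))
  sp <- split_train_test(d, split_spec(seed = 7))
  expect_equal(nrow(sp$test), 9)
  expect_equal(as.vector(table(sp$test$grade)), c(3, 3, 3))
  expect_equal(nrow(sp$train), 21)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  expect_setequal(c(sp$train$id, sp$test$id), d$id)
  # all four grades eligible -> 12 test cases
  d2 <- data.frame(id = 1:12, grade = rep(0:3, each = 3))
  expect_equal(nrow(split_train_test(d2, split_spec(seed = 1))$test), 12)
  # determinism
  sp2 <- split_train_test(d, split_spec(seed = 7))
  expect_identical(sp$test$id, sp2$test$id)
  sp3 <- split_train_test(d, split_spec(seed = 8))
  expect_false(identical(sp$test$id, sp3$test$id))
  expect_error(split_train_test(d[0, ], split_spec()), "empty")
})

test_that("all four classifier back ends separate an easy problem", {
  set.seed(41)
  x <- rbind(matrix(rnorm(60, 0), ncol = 2),
             matrix(rnorm(60, 6), ncol = 2),
             matrix(rnorm(60, 12), ncol = 2))
  y <- rep(c("a", "b", "c"), each = 30)
  xt <- rbind(matrix(rnorm(20, 0), ncol = 2),
              matrix(rnorm(20, 6), ncol = 2),
              matrix(rnorm(20, 12), ncol = 2))
  yt <- rep(c("a", "b", "c"), each = 10)
  for (method in c("lr", "svm", "dt", "rf")) {
    m <- fit_classifier(x, y, method, seed = 1)
    expect_gte(mean(predict_classifier(m, xt) == yt), 0.9)
  }
})

test_that("classifier training is reproducible under a fixed seed", {
  set.seed(42)
  x <- matrix(rnorm(120), ncol = 4)
  y <- sample(c("0", "1", "2"), 30, replace = TRUE)
  xt <- matrix(rnorm(40), ncol = 4)
  for (method in c("lr", "svm", "dt", "rf")) {
    a <- predict_classifier(fit_classifier(x, y, method, seed = 9), xt)
    b <- predict_classifier(fit_classifier(x, y, method, seed = 9), xt)
    expect_identical(a, b)
  }
})

test_that("single-label training collapses to a constant predictor", {
  m <- fit_classifier(matrix(rnorm(10), ncol = 2), rep("2", 5), "svm")
  expect_equal(m$method, "constant")
  expect_equal(predict_classifier(m, matrix(0, 3, 2)), rep("2", 3))
})

test_that("raw baseline: separable set hits 100%, shuffled labels hit chance", {
  co <- simulate_cohort(c("0" = 6, "3" = 6), seed = 43)
  recs <- co$session$recordings
  grades <- co$truth$grade
  m <- train_baseline_raw(recs, grades, "dt", seed = 1)
  expect_equal(mean(predict_baseline_raw(m, recs) == grades), 1)

  # permutation baseline: accuracy ~ chance = 1/2 over 100 resamples
  accs <- vapply(1:100, function(s) {
    set.seed(s)
    sh <- sample(grades)
    idx <- sample(length(recs), 8)
    mtr <- train_baseline_raw(recs[-idx], sh[-idx], "dt", seed = s)
    mean(predict_baseline_raw(mtr, recs[idx]) == sh[idx])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)

  # mixed lengths error without the resampling flag
  short <- simulate_recording(sim_params(n_maneuvers = 2, duration = 4,
                                         seed = 2,
                                         peak_times_cs = c(80, 220)),
                              "S900", "E1")
  expect_error(train_baseline_raw(c(recs, list(short)),
                                  c(grades, 0), "dt"), "mixed lengths")
  m2 <- train_baseline_raw(c(recs, list(short)), c(grades, 0), "dt",
                           resample_to = 500)
  expect_length(predict_baseline_raw(m2, list(short)), 1)
})

test_that("stage-2 routes unseen classes to 'unclassifiable'", {
  set.seed(44)
  tr <- data.frame(sd_nv = runif(10), max_ov = runif(10, 50, 100),
                   range_plus_mean_ov = runif(10, 60, 120),
                   mean_square_ov = runif(10, 1000, 4000),
                   klass = rep(c(1, 4), each = 5),
                   grade = rep(c(0, 3), each = 5))
  s1 <- train_stage1_class(tr, "dt")
  s2 <- train_stage2_grade(tr[tr$klass == 1, ], "dt")  # class 4 unseen
  te <- tr[tr$klass == 4, ]
  pred <- predict_two_stage(s1, s2, te)
  expect_true(all(pred == "unclassifiable"))
  expect_equal(attr(pred, "klass"), rep("4", 5))
  rep_ <- evaluate_predictions(pred, te$grade)
  expect_equal(rep_$classifiability_pct, 0)
})

test_that("evaluation metrics are micro-averaged and matrix-consistent", {
  rep1 <- evaluate_predictions(c("a", "a", "a", "b", "b", "b"),
                               c("a", "a", "b", "b", "b", "b"))
  expect_equal(unname(as.matrix(rep1$confusion_matrix)),
               rbind(c(2, 0), c(1, 3)))
  expect_equal(rep1$accuracy, 100 * 5 / 6, tolerance = 1e-12)
  expect_equal(rep1$recall, rep1$accuracy)
  expect_equal(rep1$precision, rep1$accuracy)
  expect_equal(rep1$f1, 5 / 6, tolerance = 1e-12)
  # metrics recomputable from the returned matrix
  cm <- rep1$confusion_matrix
  expect_equal(rep1$accuracy, 100 * sum(diag(cm)) / sum(cm))

  perfect <- evaluate_predictions(c(0, 1, 2), c(0, 1, 2))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$f1, 1)

  # 27 classifiable of 30 -> 90% classifiability
  pred <- c(rep("1", 27), rep("unclassifiable", 3))
  truth <- rep("1", 30)
  expect_equal(evaluate_predictions(pred, truth)$classifiability_pct, 90)
  expect_error(evaluate_predictions(1:3, 1:4), "length")
})

test_that("two-stage pipeline recovers grades and beats the raw baseline", {
  two_stage <- numeric(25); raw <- numeric(25)
  for (s in 1:25) {
    co <- study_shaped_cohort(seed = s)
    feats <- recording_features(session_features(co$session))
    res <- run_two_stage(feats, "svm", "dt",
                         spec = split_spec(seed = s), seed = s)
    two_stage[s] <- res$report$accuracy

    key <- function(d) paste(d$subject_id, d$evaluator_id, d$repeat_index)
    rk <- vapply(co$session$recordings, function(r)
      paste(r$subject_id, r$evaluator_id, r$repeat_index), character(1))
    tr <- co$session$recordings[match(key(res$split$train), rk)]
    te <- co$session$recordings[match(key(res$split$test), rk)]
    bm <- train_baseline_raw(tr, res$split$train$grade, "svm", seed = s)
    raw[s] <- 100 * mean(predict_baseline_raw(bm, te) ==
                           res$split$test$grade)
  }
  expect_gte(mean(two_stage), 90)         # parameter recovery
  expect_gt(mean(two_stage), mean(raw))   # preprocessing is necessary
})
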