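test_that("perfect agreement gives ICC 1 in every form", {
  m <- cbind(c(1, 5, 9, 2), c(1, 5, 9, 2))
  for (form in c("ICC(1)", "ICC(2,1)", "ICC(3,1)")) {
    expect_equal(icc(m, form)$estimate, 1)
  }
})

test_that("an additive rater shift is perfect consistency but not agreement", {
  m <- cbind(c(1, 3, 5), c(2, 4, 6))
  expect_equal(icc(m, "ICC(3,1)")$estimate, 1)
  r21 <- icc(m, "ICC(2,1)")
  expect_lt(r21$estimate, 1)
  expect_equal(r21$estimate, 8 / 9, tolerance = 1e-12)  # frozen from oracle
  expect_equal(oracle_icc(m, "ICC(2,1)"), 8 / 9, tolerance = 1e-12)
})

test_that("icc matches the aov-based brute-force oracle on random matrices", {
  set.seed(21)
  for (i in 1:500) {
    n <- sample(2:20, 1)
    k <- sample(2:6, 1)
    m <- matrix(rnorm(n * k, sd = runif(1, 0.5, 10)) +
                  rep(rnorm(n, sd = 3), k), n, k)
    for (form in c("ICC(1)", "ICC(2,1)", "ICC(3,1)")) {
      got <- icc(m, form)
      expect_equal(got$estimate_unclipped, oracle_icc(m, form),
                   tolerance = 1e-10)
    }
  }
})

test_that("icc is invariant under row (target) permutation", {
  set.seed(22)
  for (i in 1:25) {
    m <- matrix(rnorm(24) + rep(rnorm(6, sd = 2), 4), 6, 4)
    p <- m[sample(6), ]
    for (form in c("ICC(1)", "ICC(2,1)", "ICC(3,1)")) {
      expect_equal(icc(p, form)$estimate_unclipped,
                   icc(m, form)$estimate_unclipped, tolerance = 1e-12)
    }
  }
})

test_that("expected ICC degrades monotonically with rater noise", {
  noise_levels <- c(0.2, 1, 3, 8)
  mean_icc <- vapply(noise_levels, function(sd) {
    mean(vapply(1:50, function(s) {
      set.seed(s)
      truth <- rnorm(10, sd = 4)
      m <- sapply(1:3, function(j) truth + rnorm(10, sd = sd))
      icc(m, "ICC(2,1)")$estimate
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_icc) < 0))
})

test_that("icc rejects degenerate input", {
  expect_error(icc(matrix(1, 3, 2)), "zero total variance")
  expect_error(icc(matrix(1:4, 1, 4)), "at least 2")
  expect_error(icc(cbind(c(1, NA, 3), c(1, 2, 3))), "complete")
  expect_error(ratings_matrix(matrix(1:2, 2, 1)), "at least 2 raters")
})

test_that("landis_koch_label reproduces the published usage", {
  expect_equal(landis_koch_label(0.95), "almost perfect")
  expect_equal(landis_koch_label(0.71), "substantial")
  expect_equal(landis_koch_label(0), "poor")
  expect_equal(landis_koch_label(0.5), "moderate")
  expect_equal(landis_koch_label(0.3), "fair")
  expect_error(landis_koch_label(1.2), "\\[0, 1\\]")
})

test_that("identical repeats give intraobserver ICC 1 everywhere", {
  co <- simulate_cohort(c("0" = 3, "2" = 3), seed = 31)
  recs1 <- co$session$recordings
  recs2 <- lapply(recs1, function(r)
    gyro_recording(r$x, r$y, r$z, r$subject_id, r$evaluator_id, 2L,
                   sample_rate = r$sample_rate, duration = r$duration,
                   t = r$t))
  sess <- study_session(co$session$subjects, c(recs1, recs2), "E1")
  res <- intraobserver_analysis(sess)
  expect_equal(res$global_time, 1)
  expect_equal(res$global_amplitude, 1)
})

test_that("pure amplitude-gain repeats: time ICC 1 exceeds amplitude ICC", {
  for (seed in 1:20) {
    co <- simulate_cohort(c("0" = 2, "1" = 2, "2" = 2), seed = seed)
    recs1 <- co$session$recordings
    recs2 <- lapply(recs1, function(r) {
      out <- apply_rater_effect(r, rater_profile("E1", amplitude_gain = 1.3))
      out$repeat_index <- 2L
      out
    })
    sess <- study_session(co$session$subjects, c(recs1, recs2), "E1")
    res <- intraobserver_analysis(sess)
    expect_equal(res$global_time, 1)
    expect_lt(res$global_amplitude, 1)
  }
})

test_that("single-repeat evaluators are excluded with a warning", {
  co <- simulate_cohort(c("1" = 3),
                        raters = list(rater_profile("E1"),
                                      rater_profile("E2")),
                        repeats_per_subject = 1, seed = 33)
  # E1 gets a second repeat, E2 stays single
  extra <- lapply(co$session$recordings, function(r) {
    if (r$evaluator_id != "E1") return(NULL)
    r$repeat_index <- 2L
    r
  })
  extra <- Filter(Negate(is.null), extra)
  sess <- study_session(co$session$subjects,
                        c(co$session$recordings, extra), c("E1", "E2"))
  expect_warning(res <- intraobserver_analysis(sess), "single repeat")
  expect_named(res$per_evaluator, "E1")
})

test_that("interobserver analysis: copies agree, gain-differing raters do not", {
  sess <- copy_rater_session()
  res <- interobserver_analysis(sess)
  expect_equal(res$time$estimate, 1)
  expect_equal(res$amplitude$estimate, 1)

  co <- simulate_cohort(c("0" = 2, "1" = 2, "2" = 2), seed = 35)
  recs2 <- lapply(co$session$recordings, function(r)
    apply_rater_effect(r, rater_profile("E2", amplitude_gain = 1.4)))
  sess2 <- study_session(co$session$subjects,
                         c(co$session$recordings, recs2), c("E1", "E2"))
  res2 <- interobserver_analysis(sess2)
  expect_lt(res2$amplitude$estimate, res2$time$estimate)
})

test_that("disjoint subject coverage across evaluators errors", {
  a <- simulate_cohort(c("1" = 2), seed = 36)
  b <- simulate_cohort(c("2" = 2), seed = 37,
                       raters = list(rater_profile("E2")))
  # rename b's subjects so coverage is disjoint
  subs_b <- lapply(seq_along(b$session$subjects), function(i) {
    s <- b$session$subjects[[i]]; s$subject_id <- paste0("T", i); s
  })
  recs_b <- lapply(b$session$recordings, function(r) {
    r$subject_id <- paste0("T", match(r$subject_id, sapply(
      b$session$subjects, function(s) s$subject_id)))
    r
  })
  sess <- study_session(c(a$session$subjects, subs_b),
                        c(a$session$recordings, recs_b), c("E1", "E2"))
  expect_error(interobserver_analysis(sess), "disjoint|at least 2")
})
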