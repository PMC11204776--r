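test_that("a default simulated recording has the nominal 500 samples", {
  rec <- simulate_recording(sim_params(seed = 42))
  expect_length(rec$x, 500)
  expect_length(rec$y, 500)
  expect_equal(rec$t, 0:499)
})

test_that("simulation is bit-deterministic under a fixed seed", {
  a <- simulate_recording(sim_params(seed = 42))
  b <- simulate_recording(sim_params(seed = 42))
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_identical(a$z, b$z)
  c <- simulate_recording(sim_params(seed = 43))
  expect_false(identical(a$x, c$x))
})

test_that("explicit noise-free peaks are rendered exactly", {
  rec <- subject45_recording()
  # maxima exactly at the requested indices with the requested heights
  expect_equal(rec$x[c(111, 267, 448) + 1],
               c(137.54, 179.86, 156.83), tolerance = 1e-12)
  expect_equal(which.max(rec$x) - 1, 267)
  for (p in c(111, 267, 448)) {
    win <- rec$x[(p - 5):(p + 7)]  # 0-based peak p sits at window position 7
    expect_equal(which.max(win), 7)
  }
})

test_that("too-close peak times are rejected", {
  expect_error(sim_params(peak_times_cs = c(100, 130, 300)),
               "closer than the flexion width")
  expect_error(sim_params(peak_times_cs = c(100, 90, 300)),
               "strictly increasing")
  expect_error(sim_params(peak_times_cs = c(100, 200, 600)),
               "within")
})

test_that("class 0 pivot is plateau-shaped: lower sd_nv than sinusoidal classes", {
  # equal amplitudes and equal noise; only the pivot morphology differs
  for (seed in 1:100) {
    f0 <- preprocess_recording(simulate_recording(
      sim_params(peak_times_cs = c(80, 220, 360),
                 peak_amplitudes = c(120, 125, 122), klass = 0,
                 noise_sd = 2, seed = seed)))
    f2 <- preprocess_recording(simulate_recording(
      sim_params(peak_times_cs = c(80, 220, 360),
                 peak_amplitudes = c(120, 125, 122), klass = 2,
                 noise_sd = 2, seed = seed)))
    sd0 <- mean(vapply(f0$pivots, function(p) compute_features(p)$sd_nv, 0))
    sd2 <- mean(vapply(f2$pivots, function(p) compute_features(p)$sd_nv, 0))
    expect_lt(sd0, sd2)
  }
})

test_that("simulated pivot ground truth is recovered by segmentation", {
  rec <- subject45_recording()
  truth <- attr(rec, "sim_truth")
  mans <- segment_maneuvers(select_axis(rec, "x"), detect_peaks(rec$x))
  for (i in 1:2) {  # last maneuver's true pivot is truncated by the window
    tw <- truth$maneuvers[[i]]$pivot
    seg <- mans[[i]]$pivot
    true_idx <- tw[1]:(tw[2] - 1)
    det_idx <- seg$start_index:(seg$end_index - 1)
    overlap <- length(intersect(true_idx, det_idx)) / length(true_idx)
    expect_gte(overlap, 0.9)
  }
})

test_that("cohort sizes multiply out and KT-1000 values match the grade", {
  co <- simulate_cohort(c("0" = 1), raters = list(rater_profile("E1"),
                                                  rater_profile("E2")),
                        repeats_per_subject = 3, seed = 5)
  expect_length(co$session$recordings, 6)

  co2 <- study_shaped_cohort(seed = 2)
  expect_length(co2$session$recordings, 30)
  # truth grade always equals the CDP map applied to the simulated mm
  for (s in co2$session$subjects) {
    g <- cdp_grade(s$kt1000_left_mm, s$kt1000_right_mm)$grade
    expect_equal(g, co2$truth$grade[co2$truth$subject_id == s$subject_id][1])
  }
  # requested grade-2 subjects show a 4-5 mm side-to-side difference
  g2 <- co2$truth$subject_id[co2$truth$grade == 2]
  for (sid in unique(g2)) {
    s <- session_subject(co2$session, sid)
    expect_true(abs(s$kt1000_left_mm - s$kt1000_right_mm) %in% 4:5)
  }
  expect_error(simulate_cohort(c("0" = 0)), "empty cohort")
})

test_that("apply_rater_effect scales amplitudes and jitters peak times", {
  rec <- subject45_recording()
  ident <- apply_rater_effect(rec, rater_profile("E2", 1, 0))
  expect_identical(ident$x, rec$x)
  doubled <- apply_rater_effect(rec, rater_profile("E2", 2, 0))
  expect_equal(doubled$x, rec$x * 2, tolerance = 1e-15)

  # mean absolute time shift of N(0, 5) draws is 5 * sqrt(2/pi) ~ 3.99 cs
  prof <- rater_profile("E2", 1, time_jitter_sd = 5)
  shifts <- unlist(lapply(1:300, function(i) {
    out <- apply_rater_effect(rec, prof, seed = i)
    attr(out, "sim_truth")$peak_times - attr(rec, "sim_truth")$peak_times
  }))
  expect_equal(mean(abs(shifts)), 5 * sqrt(2 / pi), tolerance = 0.1)
  # rounding to integer cs and half-normal theory agree loosely, not exactly
})

test_that("rater jitter requires simulation provenance", {
  plain <- gyro_recording(sin(1:500), numeric(500), numeric(500), "S", "E")
  expect_error(apply_rater_effect(plain, rater_profile("E2", 1, 5)),
               "sim_truth")
})
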