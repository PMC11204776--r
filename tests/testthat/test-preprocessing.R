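test_that("select_axis projects and rejects unknown axes", {
  rec <- subject45_recording()
  expect_identical(as.numeric(select_axis(rec, "x")), rec$x)
  expect_error(select_axis(rec, "q"), "unknown axis")
  # Y axis carries only noise in the simulator (zero at noise_sd = 0)
  expect_true(all(select_axis(rec, "y") == 0))
  noisy <- simulate_recording(sim_params(seed = 1, noise_sd = 2))
  expect_lt(max(abs(noisy$y)), 0.1 * max(noisy$x))
})

test_that("normalize_unit_interval is the affine min-max map", {
  expect_equal(normalize_unit_interval(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize_unit_interval(c(0, 1)), c(0, 1))
  expect_error(normalize_unit_interval(c(5, 5, 5)), "degenerate")
  expect_error(normalize_unit_interval(3), "at least 2")
  # idempotence on already-normalized signals
  set.seed(4)
  for (i in 1:20) {
    s <- rnorm(50)
    ns <- normalize_unit_interval(s)
    expect_equal(normalize_unit_interval(ns), ns, tolerance = 1e-14)
  }
})

test_that("detect_peaks recovers the printed subject-45 peaks exactly", {
  rec <- subject45_recording()
  pk <- detect_peaks(select_axis(rec, "x"))
  expect_equal(pk$times, c(111, 267, 448))
  expect_equal(pk$amplitudes, c(137.54, 179.86, 156.83), tolerance = 1e-12)
  expect_s3_class(pk$cv, "characteristic_vector")
})

test_that("too few peaks raises a typed error carrying what was found", {
  sig <- numeric(500)
  sig[101:141] <- 50 * 0.5 * (1 + cos(pi * seq(-1, 1, length.out = 41)))
  err <- tryCatch(detect_peaks(sig), pivotshift_too_few_peaks = identity)
  expect_s3_class(err, "pivotshift_too_few_peaks")
  expect_length(err$peaks$times, 1)
  expect_equal(err$peaks$times, 120)
  expect_error(detect_peaks(numeric(100)), "constant")
})

test_that("of two close maxima only the higher is kept", {
  lobe <- function(center, h, w = 12) {
    i <- (center - w):(center + w)
    v <- h * 0.5 * (1 + cos(pi * (i - center) / w))
    list(i = i + 1, v = v)
  }
  sig <- numeric(500)
  for (p in list(lobe(100, 80), lobe(110, 90), lobe(250, 85),
                 lobe(400, 70))) {
    sig[p$i] <- pmax(sig[p$i], p$v)
  }
  pk <- detect_peaks(sig)
  expect_equal(pk$times, c(110, 250, 400))  # 100 lost to the higher 110
})

test_that("detect_peaks equals the exhaustive brute-force oracle", {
  set.seed(99)
  for (trial in 1:60) {
    n <- sample(80:200, 1)
    sig <- rep(0, n)
    n_lobes <- sample(2:6, 1)
    centers <- sort(sample(10:(n - 10), n_lobes))
    for (c0 in centers) {
      w <- sample(4:9, 1)
      h <- runif(1, 10, 100)
      i <- pmax(1, c0 - w):pmin(n, c0 + w)
      sig[i] <- sig[i] + h * 0.5 * (1 + cos(pi * (i - c0) / w))
    }
    sig <- sig + rnorm(n, 0, 0.5)
    cfg <- peak_config(min_separation_cs = 15, min_prominence_frac = 0.2,
                       expected_peaks = 3)
    got <- tryCatch(detect_peaks(sig, cfg),
                    pivotshift_too_few_peaks = function(e) e$peaks)
    want <- oracle_peaks(sig, k = 3, sep = 15, prom_frac = 0.2)
    expect_equal(got$times, want$times)
    expect_equal(got$amplitudes, want$amplitudes, tolerance = 1e-12)
  }
})

test_that("segmentation yields contiguous disjoint phase triplets", {
  rec <- subject45_recording()
  sig <- select_axis(rec, "x")
  mans <- segment_maneuvers(sig, detect_peaks(sig))
  expect_length(mans, 3)
  prev_end <- -1
  for (m in mans) {
    expect_identical(m$flexion$end_index, m$extension$start_index)
    expect_identical(m$extension$end_index, m$pivot$start_index)
    expect_gte(m$flexion$start_index, prev_end)  # maneuvers disjoint, ordered
    prev_end <- m$pivot$end_index
    expect_lte(m$pivot$end_index, length(sig))
  }
  # single peak -> single triplet
  one <- segment_maneuvers(sig, 111L)
  expect_length(one, 1)
  expect_equal(one[[1]]$flexion$peak_index, 111L)
})

test_that("a too-short pivot tail warns", {
  sig <- numeric(500)
  idx <- 456:496
  sig[idx + 1] <- 100 * 0.5 * (1 + cos(pi * (idx - 476) / 20))
  sig[498:500] <- c(-5, -10, -20)  # monotone fall to the window edge
  expect_warning(segment_maneuvers(sig, 476L), "shorter than 2 samples")
})

test_that("extract_pivot slices ov and nv on the same index range", {
  rec <- subject45_recording()
  sig <- select_axis(rec, "x")
  nv <- normalize_unit_interval(sig)
  mans <- segment_maneuvers(sig, detect_peaks(sig))
  seg <- mans[[1]]$pivot
  pv <- extract_pivot(sig, nv, seg)
  expect_length(pv$ov, seg$end_index - seg$start_index)
  expect_true(all(pv$nv >= 0 & pv$nv <= 1))
  expect_equal(pv$ov[1], sig[seg$start_index + 1])
  expect_error(extract_pivot(sig, nv, mans[[1]]$flexion),
               "pivot-phase segment")
})
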