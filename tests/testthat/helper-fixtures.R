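# Shared fixtures, built in code at test time.

# Noise-free fixture built from the printed subject-45 characteristic
# vector: three lobes at 111/267/448 cs with heights 137.54/179.86/156.83.
subject45_recording <- function(klass = 3, noise_sd = 0, seed = 7) {
  simulate_recording(
    sim_params(peak_times_cs = c(111, 267, 448),
               peak_amplitudes = c(137.54, 179.86, 156.83),
               klass = klass, noise_sd = noise_sd, seed = seed),
    subject_id = "S45", evaluator_id = "E1")
}

# Small graded cohort with defaults (grade counts as in the study's
# laxity table), one rater, one repeat.
study_shaped_cohort <- function(seed = 1, ...) {
  simulate_cohort(c("0" = 10, "1" = 9, "2" = 9, "3" = 2), seed = seed, ...)
}

# A session where a second evaluator's recordings are exact copies of the
# first's (perfect interobserver agreement by construction).
copy_rater_session <- function(n_subjects = 5, seed = 3) {
  co <- simulate_cohort(stats::setNames(c(n_subjects), "1"),
                        raters = list(rater_profile("E1")), seed = seed)
  recs2 <- lapply(co$session$recordings, function(r) {
    gyro_recording(r$x, r$y, r$z, r$subject_id, "E2", r$repeat_index,
                   sample_rate = r$sample_rate, duration = r$duration,
                   t = r$t)
  })
  study_session(co$session$subjects,
                c(co$session$recordings, recs2),
                evaluators = c("E1", "E2"),
                provenance = co$session$provenance)
}

# Independent brute-force peak oracle: own local-maximum and prominence
# loops, exhaustive subset enumeration (sizes 1..k), max summed amplitude,
# ties toward the earliest time set.
oracle_peaks <- function(signal, k = 3, sep = 50, prom_frac = 0.2) {
  n <- length(signal)
  cand <- c()
  for (i in 2:(n - 1)) {
    if (signal[i] > signal[i - 1] && signal[i] > signal[i + 1]) {
      cand <- c(cand, i)
    }
  }
  admissible <- c()
  for (i in cand) {
    h <- signal[i]
    lmin <- h; j <- i - 1
    while (j >= 1 && signal[j] <= h) { lmin <- min(lmin, signal[j]); j <- j - 1 }
    rmin <- h; j <- i + 1
    while (j <= n && signal[j] <= h) { rmin <- min(rmin, signal[j]); j <- j + 1 }
    if (h - max(lmin, rmin) >= prom_frac * max(signal)) admissible <- c(admissible, i)
  }
  if (length(admissible) == 0) return(list(times = numeric(0), amplitudes = numeric(0)))
  best_sum <- -Inf; best <- NULL
  for (m in seq_len(min(k, length(admissible)))) {
    subsets <- utils::combn(admissible, m, simplify = FALSE)
    for (s in subsets) {
      if (m >= 2 && min(diff(sort(s))) < sep) next
      tot <- sum(signal[s])
      # combn enumerates in time order, so the first subset reaching a sum
      # is the lexicographically earliest one; strict > keeps it on ties
      if (tot > best_sum + 1e-12) {
        best_sum <- tot; best <- sort(s)
      }
    }
  }
  list(times = best - 1, amplitudes = signal[best])  # 0-based times
}

# Independent ANOVA mean squares via stats::aov on the long format.
oracle_anova_ms <- function(m) {
  d <- data.frame(value = as.vector(m),
                  target = factor(rep(seq_len(nrow(m)), ncol(m))),
                  rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  two <- summary(stats::aov(value ~ target + rater, data = d))[[1]]
  one <- summary(stats::aov(value ~ target, data = d))[[1]]
  list(msr = two["target", "Mean Sq"], msc = two["rater", "Mean Sq"],
       mse = two["Residuals", "Mean Sq"], msw = one["Residuals", "Mean Sq"])
}

oracle_icc <- function(m, form) {
  ms <- oracle_anova_ms(m)
  n <- nrow(m); k <- ncol(m)
  switch(form,
    "ICC(1)" = (ms$msr - ms$msw) / (ms$msr + (k - 1) * ms$msw),
    "ICC(2,1)" = (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n),
    "ICC(3,1)" = (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse))
}
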