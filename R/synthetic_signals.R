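#' Synthetic pivot-shift signal generation
#'
#' The study's raw data are not public, so every downstream stage is
#' exercised against simulated recordings that reproduce the documented
#' signal structure: three consecutive maneuvers in a 5-s, 100-Hz capture,
#' each maneuver showing a positive flexion peak, an extension trough and a
#' joint-reduction ("pivot") region on the X axis. Classes 1-4 carry a
#' damped-sinusoid pivot morphology whose relative amplitude grows with
#' class; class 0 shows a flat-topped plateau. Y and Z axes carry noise only.
#'
#' @name synthetic_signals
NULL

# Evaluate an expression with a locally seeded RNG, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stable 31-adic string hash into [0, 2^31 - 2]; used to derive independent
# per-recording RNG streams from one root seed.
stable_hash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  h
}

# Combine a root seed with a stream label into a 32-bit-safe seed.
derive_seed <- function(root_seed, label) {
  (as.numeric(root_seed) %% 65521 * 32749 + stable_hash(label)) %% 2147483647
}

#' Simulation parameters for one recording
#'
#' @param n_maneuvers Number of maneuvers in the capture (default 3).
#' @param peak_times_cs Optional explicit flexion-peak locations in cs
#'   (0-based sample indices); strictly increasing, within `[0, n_samples)`.
#'   Drawn when `NULL`: first peak uniform in 60-80 cs, maneuver gaps
#'   uniform in 130-150 cs.
#' @param peak_amplitudes Optional explicit peak heights in rad/s. Drawn
#'   around the class's nominal amplitude when `NULL`.
#' @param klass Maneuver class 0-4 controlling the pivot morphology
#'   (plateau for 0, damped sinusoid for 1-4) and the default amplitude
#'   scale (30, 75, 125, 175, 225 rad/s).
#' @param noise_sd Standard deviation (rad/s) of additive i.i.d. Gaussian
#'   noise on all three axes (default 2).
#' @param flexion_width_cs Half-width of the raised-cosine flexion lobe
#'   (default 25 cs).
#' @param extension_width_cs Half-width of the extension trough lobe
#'   (default 20 cs); trough depth is 60% of the peak amplitude.
#' @param pivot_width_cs Length of the pivot region (default 50 cs).
#' @param pivot_rel_amp Pivot waveform amplitude relative to the flexion
#'   peak; defaults to 0.06 for class 0 (a low hysteresis shelf) and 0.35
#'   for classes 1-4 (oscillation amplitude). The contrast encodes the
#'   clinical reading that a flat, low pivot region means little residual
#'   joint movement while a pronounced oscillation means hypermobility.
#' @param pivot_cycles Sinusoid cycles across the pivot window (default 2).
#' @param sample_rate,duration Capture geometry (defaults 100 Hz, 5 s).
#' @param seed RNG seed for all draws (default 1).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_maneuvers = 3, peak_times_cs = NULL,
                       peak_amplitudes = NULL, klass = 2, noise_sd = 2,
                       flexion_width_cs = 25, extension_width_cs = 20,
                       pivot_width_cs = 50, pivot_rel_amp = NULL,
                       pivot_cycles = 2, sample_rate = 100, duration = 5,
                       seed = 1) {
  if (!klass %in% 0:4) stop("klass must be an integer in 0..4")
  n <- round(sample_rate * duration)
  if (!is.null(peak_times_cs)) {
    peak_times_cs <- round(peak_times_cs)
    if (any(diff(peak_times_cs) <= 0))
      stop("explicit peak_times_cs must be strictly increasing")
    if (any(peak_times_cs < 0 | peak_times_cs >= n))
      stop("peak_times_cs must lie within [0, ", n, ")")
    if (length(peak_times_cs) >= 2 &&
        min(diff(peak_times_cs)) < 2 * flexion_width_cs)
      stop("peak times closer than the flexion width (",
           2 * flexion_width_cs, " cs): flexion lobes would overlap")
  }
  if (is.null(pivot_rel_amp))
    pivot_rel_amp <- if (klass == 0) 0.06 else 0.35
  structure(list(
    n_maneuvers = as.integer(n_maneuvers), peak_times_cs = peak_times_cs,
    peak_amplitudes = peak_amplitudes, klass = as.integer(klass),
    noise_sd = noise_sd, flexion_width_cs = flexion_width_cs,
    extension_width_cs = extension_width_cs,
    pivot_width_cs = pivot_width_cs, pivot_rel_amp = pivot_rel_amp,
    pivot_cycles = pivot_cycles, sample_rate = sample_rate,
    duration = duration, seed = seed
  ), class = "sim_params")
}

#' Rater profile for inter-observer variability
#'
#' Emulates evaluator-specific execution: a multiplicative amplitude gain
#' (stronger or gentler maneuver) and Gaussian jitter on the peak timing.
#'
#' @param evaluator_id Identifier.
#' @param amplitude_gain Multiplicative amplitude factor, > 0 (default 1).
#' @param time_jitter_sd Peak-time jitter standard deviation in cs
#'   (default 0).
#' @param seed_offset Integer offset decorrelating this rater's RNG stream.
#' @return A list of class `rater_profile`.
#' @export
rater_profile <- function(evaluator_id, amplitude_gain = 1,
                          time_jitter_sd = 0, seed_offset = 0) {
  if (amplitude_gain <= 0) stop("amplitude_gain must be positive")
  structure(list(evaluator_id = as.character(evaluator_id),
                 amplitude_gain = amplitude_gain,
                 time_jitter_sd = time_jitter_sd,
                 seed_offset = as.integer(seed_offset)),
            class = "rater_profile")
}

# Nominal peak amplitude (rad/s) per class 0..4; the default class-bin edges
# (50, 100, 150, 200) place these means inside their own bin.
class_nominal_amplitude <- function(klass) c(30, 75, 125, 175, 225)[klass + 1]

# Mean multiplicative inflation of the *detected* peak speed over the
# subject's characteristic amplitude at the generator defaults: the
# within-recording amplitude jitter (max over three maneuvers) plus the
# upward bias of picking the raw maximum sample under 5% additive noise.
# Measured once on the default world; used to express class targets on the
# detected-speed scale the bins operate on.
amp_detect_gain <- 1.107

# Deterministic noiseless render of the X-axis waveform. Returns the signal
# plus per-maneuver ground truth (trough index, pivot window).
render_maneuvers <- function(n, peak_times, peak_amps, klass, fw, ew, pw,
                             rel, cycles) {
  x <- numeric(n)
  truth <- vector("list", length(peak_times))
  for (i in seq_along(peak_times)) {
    p <- peak_times[i]; A <- peak_amps[i]
    # flexion lobe: raised cosine, exact height A at sample p
    lo <- max(0L, p - fw); hi <- min(n - 1L, p + fw)
    idx <- lo:hi
    u <- (idx - p) / fw
    x[idx + 1L] <- x[idx + 1L] + A * 0.5 * (1 + cos(pi * u))
    # extension trough centered fw + ew after the peak, depth 0.6 A
    ce <- p + fw + ew
    lo <- max(0L, ce - ew); hi <- min(n - 1L, ce + ew)
    idx <- lo:hi
    u <- (idx - ce) / ew
    x[idx + 1L] <- x[idx + 1L] - 0.6 * A * 0.5 * (1 + cos(pi * u))
    # pivot region
    ps <- p + fw + 2L * ew
    pe <- min(n, ps + pw)
    if (pe - ps >= 2L) {
      idx <- ps:(pe - 1L)
      s <- (idx - ps) / pw
      wave <- if (klass == 0) {
        ramp <- pmin(1, pmin(s, 1 - s) / 0.15)
        rel * A * ramp^2 * (3 - 2 * ramp)   # smoothstep plateau
      } else {
        rel * A * sin(2 * pi * cycles * s) * exp(-2.5 * s)
      }
      x[idx + 1L] <- x[idx + 1L] + wave
    }
    truth[[i]] <- list(peak = p, trough = ce, pivot = c(ce, pe))
  }
  list(x = x, truth = truth)
}

#' Simulate one pivot-shift recording
#'
#' Renders `params$n_maneuvers` maneuvers into a tri-axial recording and
#' adds Gaussian noise. Identical parameters and seed give bit-identical
#' output. The realized peak times/amplitudes and the ground-truth pivot
#' windows are attached as attribute `"sim_truth"` for parameter-recovery
#' tests.
#'
#' @param params A [sim_params()].
#' @param subject_id,evaluator_id,repeat_index Recording identity.
#' @return A [gyro_recording()] with attribute `sim_truth`.
#' @examples
#' rec <- simulate_recording(sim_params(seed = 42), "S01", "E1")
#' length(rec$x)  # 500
#' @export
simulate_recording <- function(params = sim_params(), subject_id = "S01",
                               evaluator_id = "E1", repeat_index = 1) {
  stopifnot(inherits(params, "sim_params"))
  n <- round(params$sample_rate * params$duration)
  with_seed(params$seed, {
    pt <- params$peak_times_cs
    if (is.null(pt)) {
      start <- round(stats::runif(1, 60, 80))
      gaps <- round(stats::runif(params$n_maneuvers - 1, 130, 150))
      pt <- as.integer(start + cumsum(c(0, gaps)))
    }
    pa <- params$peak_amplitudes
    if (is.null(pa)) {
      A0 <- class_nominal_amplitude(params$klass)
      pa <- A0 * (1 + stats::rnorm(length(pt), 0, 0.05))
    }
    if (length(pa) != length(pt))
      stop("peak_amplitudes and peak_times_cs lengths differ")
    if (length(pt) >= 2 && min(diff(pt)) < 2 * params$flexion_width_cs)
      stop("peak times closer than the flexion width (",
           2 * params$flexion_width_cs, " cs): flexion lobes would overlap")
    rm_ <- render_maneuvers(n, as.integer(pt), pa, params$klass,
                            params$flexion_width_cs,
                            params$extension_width_cs,
                            params$pivot_width_cs, params$pivot_rel_amp,
                            params$pivot_cycles)
    x <- rm_$x
    if (params$noise_sd > 0) {
      x <- x + stats::rnorm(n, 0, params$noise_sd)
      y <- stats::rnorm(n, 0, params$noise_sd)
      z <- stats::rnorm(n, 0, params$noise_sd)
    } else {
      y <- numeric(n); z <- numeric(n)
    }
    rec <- gyro_recording(x, y, z, subject_id, evaluator_id, repeat_index,
                          sample_rate = params$sample_rate,
                          duration = params$duration)
    attr(rec, "sim_truth") <- list(peak_times = as.integer(pt),
                                   peak_amplitudes = pa,
                                   maneuvers = rm_$truth,
                                   klass = params$klass, params = params)
    rec
  })
}

#' Apply a rater's execution profile to a simulated recording
#'
#' Scales all three axes by the rater's amplitude gain. Non-zero time jitter
#' requires the simulation ground truth attached by [simulate_recording()]
#' (the recording is re-rendered with jittered peak times); it cannot be
#' applied to externally loaded recordings.
#'
#' @param recording A [gyro_recording()].
#' @param profile A [rater_profile()].
#' @param seed Seed for the jitter draws (default derived from the profile's
#'   `seed_offset`).
#' @return A new [gyro_recording()] attributed to `profile$evaluator_id`.
#' @export
apply_rater_effect <- function(recording, profile, seed = NULL) {
  stopifnot(inherits(profile, "rater_profile"))
  if (is.null(seed)) seed <- 1000 + profile$seed_offset
  if (profile$time_jitter_sd > 0) {
    truth <- attr(recording, "sim_truth")
    if (is.null(truth))
      stop("time jitter requires a simulated recording with sim_truth")
    p <- truth$params
    jit <- with_seed(seed,
      round(stats::rnorm(length(truth$peak_times), 0,
                         profile$time_jitter_sd)))
    p2 <- p
    p2$peak_times_cs <- truth$peak_times + jit
    p2$peak_amplitudes <- truth$peak_amplitudes * profile$amplitude_gain
    rec <- simulate_recording(p2, recording$subject_id,
                              profile$evaluator_id,
                              recording$repeat_index)
    return(rec)
  }
  out <- gyro_recording(recording$x * profile$amplitude_gain,
                        recording$y * profile$amplitude_gain,
                        recording$z * profile$amplitude_gain,
                        recording$subject_id, profile$evaluator_id,
                        recording$repeat_index,
                        sample_rate = recording$sample_rate,
                        duration = recording$duration, t = recording$t)
  tr <- attr(recording, "sim_truth")
  if (!is.null(tr)) {
    tr$peak_amplitudes <- tr$peak_amplitudes * profile$amplitude_gain
    attr(out, "sim_truth") <- tr
  }
  out
}

# KT-1000 side-to-side difference (integer mm) consistent with a CDP grade.
draw_kt_difference <- function(grade) {
  switch(as.character(grade),
         "0" = sample(0:2, 1), "1" = 3L, "2" = sample(4:5, 1),
         "3" = sample(6:10, 1),
         stop("grade must be in 0..3"))
}

#' Simulate a study cohort
#'
#' Generates one subject per requested laxity grade slot, KT-1000 values
#' whose side-to-side difference reproduces the requested grade, and
#' `length(raters) * repeats_per_subject` recordings per subject. Each
#' subject carries a characteristic peak amplitude (drawn around the grade's
#' nominal class amplitude) and a characteristic maneuver cadence, so that
#' between-subject variance exists for the reliability analysis; raters add
#' their gain and timing jitter on top, and every recording re-draws small
#' within-rater execution noise from its own hash-derived RNG stream.
#'
#' @param grade_counts Named vector/list mapping grade (`"0"`..`"3"`) to the
#'   number of subjects, e.g. `c("0" = 10, "1" = 9, "2" = 9, "3" = 2)`.
#' @param raters List of [rater_profile()] (default one neutral rater "E1").
#' @param repeats_per_subject Repeats each rater performs (default 1).
#' @param seed Root seed; per-recording streams are derived by stable
#'   hashing of (subject, evaluator, repeat).
#' @param amp_means Characteristic peak amplitude per grade 0-3 (rad/s);
#'   the defaults 68/113/158/203 are the bin centers 75/125/175/225
#'   deflated by the measured detection gain (about 1.107), so that the
#'   *detected* peak speed of each grade centers in speed class
#'   `grade + 1` under the default class bins.
#' @param amp_spread Half-width of the uniform band the subject's
#'   characteristic amplitude is drawn from (default 15 rad/s), leaving a
#'   clear detected-speed margin to the nearest bin edge so grade
#'   morphologies stay well separated and a subject's truth class is
#'   unambiguous.
#' @param noise_frac Additive noise SD as a fraction of the subject's
#'   characteristic amplitude (default 0.05).
#' @param amp_within_frac Within-rater multiplicative amplitude noise SD
#'   (default 0.03).
#' @param time_within_sd Within-rater maneuver-gap noise SD in cs
#'   (default 2).
#' @param pivot_rel_base,pivot_rel_step Pivot oscillation amplitude relative
#'   to the flexion peak: `base + step * grade` (defaults 0.12 and 0.10), so
#'   higher laxity grades show larger joint-reduction oscillation.
#' @param class_bins A [class_bins()] used for the truth class labels.
#' @return A list with `session` (a [study_session()]) and `truth`
#'   (data.frame: subject_id, evaluator_id, repeat_index, grade, klass).
#' @export
simulate_cohort <- function(grade_counts, raters = list(rater_profile("E1")),
                            repeats_per_subject = 1, seed = 1,
                            amp_means = c(68, 113, 158, 203),
                            amp_spread = 15,
                            noise_frac = 0.05, amp_within_frac = 0.03,
                            time_within_sd = 2,
                            pivot_rel_base = 0.12, pivot_rel_step = 0.10,
                            class_bins = default_class_bins()) {
  gc <- unlist(grade_counts)
  if (is.null(names(gc)) || !all(names(gc) %in% as.character(0:3)))
    stop("grade_counts must be named with grades 0..3")
  if (any(gc < 0)) stop("grade counts must be >= 0")
  if (sum(gc) == 0) stop("empty cohort requested")
  if (length(raters) < 1) stop("at least one rater is required")

  subjects <- list(); recs <- list(); truth <- list()
  sidx <- 0L
  for (gname in names(gc)) {
    g <- as.integer(gname)
    for (k in seq_len(gc[[gname]])) {
      sidx <- sidx + 1L
      sid <- sprintf("S%03d", sidx)
      sub_draw <- with_seed(derive_seed(seed, paste0("subject/", sid)), {
        d <- draw_kt_difference(g)
        base <- sample(4:10, 1)
        left_larger <- stats::runif(1) < 0.5
        list(kl = if (left_larger) base + d else base,
             kr = if (left_larger) base else base + d,
             A = stats::runif(1, amp_means[g + 1] - amp_spread,
                              amp_means[g + 1] + amp_spread),
             gap = stats::runif(1, 130, 150),
             age = sample(18:37, 1),
             gender = sample(c("F", "M"), 1),
             height = round(stats::rnorm(1, 170, 9)),
             weight = round(stats::rnorm(1, 70, 10)))
      })
      subjects[[sidx]] <- subject_record(
        sid, initials = sid, age = sub_draw$age, gender = sub_draw$gender,
        height = sub_draw$height, weight = sub_draw$weight,
        kt1000_left_mm = sub_draw$kl, kt1000_right_mm = sub_draw$kr)
      for (rp in raters) for (rep_i in seq_len(repeats_per_subject)) {
        lab <- paste(sid, rp$evaluator_id, rep_i, sep = "/")
        rseed <- derive_seed(seed, paste0("rec/", lab)) + rp$seed_offset
        rec <- with_seed(rseed, {
          start <- round(stats::runif(1, 60, 80))
          gaps <- round(sub_draw$gap +
                          stats::rnorm(2, 0, time_within_sd) +
                          stats::rnorm(2, 0, rp$time_jitter_sd))
          pt <- as.integer(start + cumsum(c(0, gaps)))
          amps <- sub_draw$A * rp$amplitude_gain *
            (1 + stats::rnorm(3, 0, amp_within_frac))
          params <- sim_params(
            peak_times_cs = pt, peak_amplitudes = amps,
            klass = max(1L, assign_class_speed(
              sub_draw$A * rp$amplitude_gain * amp_detect_gain,
              class_bins)),
            noise_sd = noise_frac * sub_draw$A,
            pivot_rel_amp = pivot_rel_base + pivot_rel_step * g,
            seed = derive_seed(rseed, "render"))
          simulate_recording(params, sid, rp$evaluator_id, rep_i)
        })
        recs[[length(recs) + 1L]] <- rec
        # truth class is a subject-level property: the bin of the expected
        # detected speed, unperturbed by per-recording execution noise
        truth[[length(truth) + 1L]] <- data.frame(
          subject_id = sid, evaluator_id = rp$evaluator_id,
          repeat_index = rep_i, grade = g,
          klass = assign_class_speed(
            sub_draw$A * rp$amplitude_gain * amp_detect_gain, class_bins),
          stringsAsFactors = FALSE)
      }
    }
  }
  session <- study_session(
    subjects, recs,
    evaluators = vapply(raters, function(r) r$evaluator_id, character(1)),
    provenance = list(simulated = TRUE, seed = seed,
                      generator = "pivotshift::simulate_cohort"))
  list(session = session, truth = do.call(rbind, truth))
}
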