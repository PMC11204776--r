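#' Core domain types for pivot-shift gyroscope analysis
#'
#' Constructors and validators for the in-memory objects shared by the whole
#' toolkit. Time is measured in centiseconds (cs) throughout: at the nominal
#' 100 Hz sampling rate one sample corresponds to one centisecond, so sample
#' index (0-based) and time coincide. Seconds appear only at I/O boundaries.
#' All sample-index intervals are half-open `[start, end)` and 0-based.
#'
#' @name signal_model
NULL

#' Construct a gyroscope recording
#'
#' A single capture of tri-axial angular velocity (rad/s) during the
#' pivot-shift maneuver, nominally 5 s at 100 Hz (500 samples).
#'
#' @param x,y,z Numeric vectors of angular velocity in rad/s, one per axis.
#'   The X axis is the analysis axis (it tracks the leg's rotation given the
#'   phone placement on the anteromedial tibia).
#' @param subject_id,evaluator_id Opaque identifiers (coerced to character).
#' @param repeat_index Integer >= 1, which repeat of the exam this is.
#' @param sample_rate Samples per second (default 100).
#' @param duration Nominal duration in seconds (default 5).
#' @param t Sample times in centiseconds, strictly increasing. Defaults to
#'   `0:(n-1)` scaled so that at 100 Hz the time equals the sample index.
#' @return An object of class `gyro_recording`: a list with fields
#'   `subject_id`, `evaluator_id`, `repeat_index`, `sample_rate`, `duration`,
#'   `t`, `x`, `y`, `z`.
#' @examples
#' rec <- gyro_recording(x = sin(seq(0, 10, length.out = 500)),
#'                       y = numeric(500), z = numeric(500),
#'                       subject_id = "S01", evaluator_id = "E1")
#' length(rec$x)
#' @export
gyro_recording <- function(x, y, z, subject_id, evaluator_id,
                           repeat_index = 1L, sample_rate = 100,
                           duration = 5, t = NULL) {
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("x, y and z must have equal length (got ", n, ", ", length(y),
         ", ", length(z), ")")
  if (is.null(t)) t <- (seq_len(n) - 1) * (100 / sample_rate)
  if (length(t) != n)
    stop("t must have the same length as the axis vectors")
  if (n >= 2 && any(diff(t) <= 0))
    stop("t must be strictly increasing")
  if (repeat_index < 1) stop("repeat_index must be >= 1")
  rec <- structure(list(
    subject_id   = as.character(subject_id),
    evaluator_id = as.character(evaluator_id),
    repeat_index = as.integer(repeat_index),
    sample_rate  = sample_rate,
    duration     = duration,
    t = as.numeric(t), x = as.numeric(x),
    y = as.numeric(y), z = as.numeric(z)
  ), class = "gyro_recording")
  rec
}

#' @export
print.gyro_recording <- function(x, ...) {
  cat(sprintf(
    "<gyro_recording> subject=%s evaluator=%s repeat=%d  %d samples @ %g Hz\n",
    x$subject_id, x$evaluator_id, x$repeat_index, length(x$x), x$sample_rate))
  cat(sprintf("  X range [%.3f, %.3f] rad/s\n", min(x$x), max(x$x)))
  invisible(x)
}

#' Number of samples expected for a nominal recording
#' @param recording A `gyro_recording`.
#' @return Integer, `sample_rate * duration`.
#' @export
nominal_samples <- function(recording) {
  as.integer(round(recording$sample_rate * recording$duration))
}

#' Construct a subject record
#'
#' Demographics plus per-leg KT-1000 anteroposterior displacement (mm), as
#' recorded in the study manifest. KT-1000 values may be `NA` when the
#' arthrometer was not used for that subject.
#'
#' @param subject_id Opaque identifier.
#' @param initials,gender,ikdc_label,notes Character (optional but `initials`
#'   is conventionally filled).
#' @param age Years. @param height cm. @param weight kg.
#' @param kt1000_left_mm,kt1000_right_mm KT-1000 displacement per leg, mm,
#'   finite and non-negative when present.
#' @return A list of class `subject_record`.
#' @export
subject_record <- function(subject_id, initials = "", age = NA_real_,
                           gender = NA_character_, height = NA_real_,
                           weight = NA_real_, kt1000_left_mm = NA_real_,
                           kt1000_right_mm = NA_real_,
                           ikdc_label = NA_character_, notes = NA_character_) {
  for (v in c(kt1000_left_mm, kt1000_right_mm)) {
    if (!is.na(v) && (!is.finite(v) || v < 0))
      stop("KT-1000 values must be finite and non-negative")
  }
  structure(list(
    subject_id = as.character(subject_id), initials = initials,
    age = age, gender = gender, height = height, weight = weight,
    kt1000_left_mm = kt1000_left_mm, kt1000_right_mm = kt1000_right_mm,
    ikdc_label = ikdc_label, notes = notes
  ), class = "subject_record")
}

#' Construct a characteristic vector
#'
#' The per-recording triple of positive-peak amplitudes (rad/s) and peak
#' times (centiseconds), ordered by time. This is the quantity entering the
#' reliability (ICC) analysis.
#'
#' @param amplitudes Three peak heights in rad/s, all positive.
#' @param times Three peak locations in centiseconds. If supplied out of
#'   time order, both vectors are re-sorted jointly by time.
#' @return A list of class `characteristic_vector` with `amplitudes`, `times`.
#' @examples
#' cv <- characteristic_vector(c(137.54, 179.86, 156.83), c(111, 267, 448))
#' cv$times
#' @export
characteristic_vector <- function(amplitudes, times) {
  if (length(amplitudes) != 3 || length(times) != 3)
    stop("a characteristic vector requires exactly 3 peaks, got ",
         length(times))
  ord <- order(times)
  amplitudes <- as.numeric(amplitudes[ord])
  times <- as.numeric(times[ord])
  if (any(diff(times) <= 0)) stop("peak times must be strictly increasing")
  if (any(amplitudes <= 0)) stop("peak amplitudes must be positive")
  structure(list(amplitudes = amplitudes, times = times),
            class = "characteristic_vector")
}

#' @export
print.characteristic_vector <- function(x, ...) {
  cat("<characteristic_vector>\n")
  cat("  amplitudes (rad/s):", paste(sprintf("%.2f", x$amplitudes),
                                     collapse = ", "), "\n")
  cat("  times (cs):       ", paste(sprintf("%.2f", x$times),
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Construct a maneuver segment
#'
#' A half-open, 0-based sample-index interval `[start_index, end_index)` into
#' the X-axis signal, labelled with the maneuver phase it covers.
#'
#' @param start_index,end_index Integers, `0 <= start < end <= n`.
#' @param phase One of `"flexion"`, `"extension"`, `"pivot"`.
#' @param peak_index Sample index of the owning maneuver's flexion peak.
#' @param n_signal Length of the underlying signal (for bounds checking),
#'   or `NULL` to skip the upper-bound check.
#' @return A list of class `maneuver_segment`.
#' @export
maneuver_segment <- function(start_index, end_index, phase, peak_index,
                             n_signal = NULL) {
  phase <- match.arg(phase, c("flexion", "extension", "pivot"))
  if (start_index < 0 || start_index >= end_index)
    stop("require 0 <= start_index < end_index")
  if (!is.null(n_signal) && end_index > n_signal)
    stop("end_index exceeds signal length")
  structure(list(start_index = as.integer(start_index),
                 end_index = as.integer(end_index),
                 phase = phase, peak_index = as.integer(peak_index)),
            class = "maneuver_segment")
}

#' Construct a pivot segment
#'
#' The isolated joint-reduction portion of the X-axis signal, carried both in
#' original values (OV, rad/s) and normalized values (NV, unit interval).
#'
#' @param ov Numeric, original values in rad/s.
#' @param nv Numeric, the same samples after min-max normalization of the
#'   recording; every entry must lie in `[0, 1]`.
#' @param source Optional list identifying the parent recording and maneuver
#'   index.
#' @return A list of class `pivot_segment`.
#' @export
pivot_segment <- function(ov, nv, source = NULL) {
  if (length(ov) != length(nv)) stop("ov and nv must be aligned")
  if (length(ov) < 2) stop("a pivot segment needs at least 2 samples")
  eps <- 1e-9
  if (any(nv < -eps | nv > 1 + eps))
    stop("normalized values must lie in [0, 1]")
  structure(list(ov = as.numeric(ov),
                 nv = pmin(1, pmax(0, as.numeric(nv))),
                 source = source),
            class = "pivot_segment")
}

#' Construct a study session
#'
#' Cohort container tying subjects, evaluators and recordings together.
#' Every recording's subject and evaluator identifiers must resolve within
#' the session.
#'
#' @param subjects List of [subject_record()] objects.
#' @param recordings List of [gyro_recording()] objects.
#' @param evaluators Character vector of evaluator identifiers.
#' @param provenance Free-form list (e.g. the seed used when simulated).
#' @return A list of class `study_session`.
#' @export
study_session <- function(subjects, recordings, evaluators,
                          provenance = list()) {
  sub_ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(sub_ids)) stop("duplicate subject_id in session")
  for (rec in recordings) {
    if (!rec$subject_id %in% sub_ids)
      stop("recording references unknown subject_id: ", rec$subject_id)
    if (!rec$evaluator_id %in% evaluators)
      stop("recording references unknown evaluator_id: ", rec$evaluator_id)
  }
  structure(list(subjects = subjects, recordings = recordings,
                 evaluators = as.character(evaluators),
                 provenance = provenance),
            class = "study_session")
}

#' @export
print.study_session <- function(x, ...) {
  cat(sprintf("<study_session> %d subjects, %d evaluators, %d recordings\n",
              length(x$subjects), length(x$evaluators), length(x$recordings)))
  invisible(x)
}

#' Look up a session's subject by id
#' @param session A `study_session`. @param subject_id Identifier.
#' @return The matching `subject_record`, or error if absent.
#' @export
session_subject <- function(session, subject_id) {
  for (s in session$subjects) if (s$subject_id == subject_id) return(s)
  stop("no such subject in session: ", subject_id)
}
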