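#' Peak-detection configuration
#'
#' The study reports three positive flexion peaks (PI-III) per 5-s capture,
#' one per maneuver, but does not state a detection algorithm. The detector
#' used here keeps local maxima whose topographic prominence is at least
#' `min_prominence_frac` of the global maximum and which are pairwise at
#' least `min_separation_cs` apart, then selects the admissible subset of at
#' most `expected_peaks` peaks maximizing summed amplitude (ties broken
#' toward earlier times).
#'
#' @param min_separation_cs Minimum peak-to-peak distance in centiseconds
#'   (default 50; three maneuvers in 5 s leave >100 cs between peaks).
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   global maximum, in `(0, 1]` (default 0.2).
#' @param expected_peaks Number of peaks a nominal capture contains
#'   (default 3).
#' @return A list of class `peak_config`.
#' @export
peak_config <- function(min_separation_cs = 50, min_prominence_frac = 0.2,
                        expected_peaks = 3) {
  if (min_separation_cs < 1) stop("min_separation_cs must be >= 1")
  if (min_prominence_frac <= 0 || min_prominence_frac > 1)
    stop("min_prominence_frac must be in (0, 1]")
  structure(list(min_separation_cs = min_separation_cs,
                 min_prominence_frac = min_prominence_frac,
                 expected_peaks = as.integer(expected_peaks)),
            class = "peak_config")
}

#' Select one axis of a recording
#'
#' The X axis is the analysis axis: with the phone strapped to the
#' anteromedial tibia it tracks the rotation of the leg during the maneuver.
#'
#' @param recording A [gyro_recording()].
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @return Numeric vector of angular velocities with the time base attached
#'   as attribute `t_cs`.
#' @export
select_axis <- function(recording, axis = "x") {
  if (!axis %in% c("x", "y", "z"))
    stop("unknown axis: ", axis, " (must be one of x, y, z)")
  sig <- recording[[axis]]
  attr(sig, "t_cs") <- recording$t
  sig
}

#' Min-max normalize a signal to the unit interval
#'
#' Affine rescaling so the minimum maps to 0 and the maximum to 1; first
#' processing step before morphological analysis. Idempotent on signals
#' already spanning `[0, 1]`.
#'
#' @param signal Numeric vector, length >= 2, non-constant.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' normalize_unit_interval(c(2, 4, 6))  # 0.0 0.5 1.0
#' @export
normalize_unit_interval <- function(signal) {
  if (length(signal) < 2) stop("signal must have at least 2 samples")
  lo <- min(signal); hi <- max(signal)
  if (hi == lo)
    stop("degenerate signal: constant value ", lo, " cannot be normalized")
  (signal - lo) / (hi - lo)
}

# Indices (0-based) of strict local maxima; plateaus contribute their first
# sample. Endpoints are not peaks.
local_maxima0 <- function(signal) {
  n <- length(signal)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (signal[i] > signal[i - 1L]) {
      j <- i
      while (j < n && signal[j + 1L] == signal[j]) j <- j + 1L
      if (j < n && signal[j + 1L] < signal[j]) out <- c(out, i - 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Topographic prominence of a candidate peak at 0-based index p: height minus
# the higher of the two key saddles (minimum between the peak and the nearest
# strictly higher ground on each side, or the window edge).
peak_prominence0 <- function(signal, p) {
  h <- signal[p + 1L]
  n <- length(signal)
  i <- p
  left_min <- h
  while (i >= 1L) {
    v <- signal[i]
    if (v > h) break
    if (v < left_min) left_min <- v
    i <- i - 1L
  }
  i <- p + 2L
  right_min <- h
  while (i <= n) {
    v <- signal[i]
    if (v > h) break
    if (v < right_min) right_min <- v
    i <- i + 1L
  }
  h - max(left_min, right_min)
}

# Choose <= k candidates, pairwise >= sep apart, maximizing summed amplitude;
# among equal sums prefer the lexicographically earliest time set. Dynamic
# program over candidates sorted by time.
select_peak_subset <- function(times, amps, k, sep) {
  m <- length(times)
  if (m == 0) return(integer(0))
  # best[[i]][[c]]: list(sum, set) for prefix ending with candidate i using c peaks
  best_sum <- matrix(-Inf, nrow = m, ncol = k)
  best_set <- vector("list", m * k)
  idx <- function(i, c) (i - 1L) * k + c
  for (i in seq_len(m)) {
    best_sum[i, 1] <- amps[i]
    best_set[[idx(i, 1L)]] <- i
    if (k >= 2) for (c in 2:k) {
      for (j in seq_len(i - 1L)) {
        if (times[i] - times[j] >= sep && is.finite(best_sum[j, c - 1])) {
          s <- best_sum[j, c - 1] + amps[i]
          if (s > best_sum[i, c] + 1e-12 ||
              (abs(s - best_sum[i, c]) <= 1e-12 && !is.null(best_set[[idx(i, c)]]) &&
               earlier_set(c(best_set[[idx(j, c - 1L)]], i), best_set[[idx(i, c)]], times))) {
            best_sum[i, c] <- s
            best_set[[idx(i, c)]] <- c(best_set[[idx(j, c - 1L)]], i)
          }
        }
      }
    }
  }
  # overall best over all i, preferring more peaks only through larger sums
  sel <- integer(0); sel_sum <- -Inf
  for (i in seq_len(m)) for (c in seq_len(k)) {
    if (is.finite(best_sum[i, c])) {
      s <- best_sum[i, c]
      st <- best_set[[idx(i, c)]]
      if (s > sel_sum + 1e-12 ||
          (abs(s - sel_sum) <= 1e-12 && earlier_set(st, sel, times))) {
        sel_sum <- s; sel <- st
      }
    }
  }
  sort(sel)
}

earlier_set <- function(a, b, times) {
  if (length(b) == 0) return(TRUE)
  ta <- sort(times[a]); tb <- sort(times[b])
  L <- min(length(ta), length(tb))
  for (i in seq_len(L)) {
    if (ta[i] < tb[i]) return(TRUE)
    if (ta[i] > tb[i]) return(FALSE)
  }
  length(ta) < length(tb)
}

#' Detect the positive maneuver peaks of an X-axis signal
#'
#' Finds the flexion peaks PI-III: local maxima with topographic prominence
#' at least `config$min_prominence_frac` of the global maximum, thinned to
#' the admissible subset of at most `config$expected_peaks` peaks with
#' pairwise separation `config$min_separation_cs` that maximizes summed
#' amplitude (an exact dynamic program, equivalent to exhaustive search).
#'
#' @param signal Numeric X-axis signal (rad/s); sample index = time in cs at
#'   100 Hz.
#' @param config A [peak_config()].
#' @return A list of class `detected_peaks` with `times` (cs, 0-based sample
#'   indices), `amplitudes` (rad/s), and `cv` (a [characteristic_vector()]
#'   when exactly 3 peaks are requested and found).
#' @details If fewer than `expected_peaks` admissible peaks exist, an error
#'   of class `pivotshift_too_few_peaks` is thrown; its `peaks` field carries
#'   the peaks that were found so callers may relax the configuration.
#' @export
detect_peaks <- function(signal, config = peak_config()) {
  if (max(signal) == min(signal)) stop("signal is constant; no peaks")
  cand <- local_maxima0(signal)
  if (length(cand) > 0) {
    prom <- vapply(cand, function(p) peak_prominence0(signal, p), numeric(1))
    keep <- prom >= config$min_prominence_frac * max(signal)
    cand <- cand[keep]
  }
  amps <- signal[cand + 1L]
  sel <- select_peak_subset(as.numeric(cand), amps, config$expected_peaks,
                            config$min_separation_cs)
  times <- as.numeric(cand[sel])
  amplitudes <- signal[cand[sel] + 1L]
  if (length(sel) < config$expected_peaks) {
    cond <- structure(
      class = c("pivotshift_too_few_peaks", "error", "condition"),
      list(message = sprintf(
        "found %d peak(s) but %d expected; relax peak_config to proceed",
        length(sel), config$expected_peaks),
        call = sys.call(-1),
        peaks = list(times = times, amplitudes = amplitudes)))
    stop(cond)
  }
  cv <- if (length(times) == 3)
    characteristic_vector(amplitudes, times) else NULL
  structure(list(times = times, amplitudes = amplitudes, cv = cv),
            class = "detected_peaks")
}

# 0-based index of the last sample strictly before peak where the signal sits
# at or below frac * peak height; onset of the flexion rise.
rise_start0 <- function(signal, peak0, frac = 0.1, floor0 = 0L) {
  thr <- frac * signal[peak0 + 1L]
  i <- peak0 - 1L
  while (i >= floor0) {
    if (signal[i + 1L] <= thr) return(i)
    i <- i - 1L
  }
  floor0
}

#' Segment a signal into flexion / extension / pivot phases
#'
#' Each detected flexion peak anchors one maneuver. Within a maneuver:
#' flexion runs from the rise onset (last sample at or below 10% of the peak
#' height) to the peak; extension from the peak to the trough (the global
#' minimum between this peak and the next, or within a 100-cs horizon after
#' the last peak); the pivot phase runs from the trough to the next
#' maneuver's rise onset, or to the window end for the last maneuver.
#'
#' @param signal Numeric X-axis signal.
#' @param peaks A `detected_peaks` object from [detect_peaks()], or a numeric
#'   vector of 0-based peak indices.
#' @return A list of maneuvers; each maneuver is a named list of three
#'   [maneuver_segment()]s (`flexion`, `extension`, `pivot`).
#' @export
segment_maneuvers <- function(signal, peaks) {
  pk <- if (inherits(peaks, "detected_peaks")) as.integer(peaks$times)
        else as.integer(peaks)
  if (length(pk) < 1) stop("need at least one detected peak")
  pk <- sort(pk)
  n <- length(signal)
  k <- length(pk)
  rises <- integer(k)
  prev_end <- 0L
  for (i in seq_len(k)) {
    rises[i] <- rise_start0(signal, pk[i], floor0 = prev_end)
    prev_end <- pk[i]
  }
  out <- vector("list", k)
  for (i in seq_len(k)) {
    p <- pk[i]
    if (i < k) {
      span <- (p + 1L):(pk[i + 1L] - 1L)
    } else {
      span <- (p + 1L):(min(n - 1L, p + 100L))
    }
    trough <- span[which.min(signal[span + 1L])]
    pivot_end <- if (i < k) rises[i + 1L] else n
    if (pivot_end - trough < 2L) {
      warning("pivot window after peak ", p,
              " is shorter than 2 samples; truncated maneuver dropped")
      pivot_end <- min(n, trough + 2L)
    }
    out[[i]] <- list(
      flexion   = maneuver_segment(rises[i], p, "flexion", p, n),
      extension = maneuver_segment(p, trough, "extension", p, n),
      pivot     = maneuver_segment(trough, pivot_end, "pivot", p, n))
  }
  out
}

#' Extract the pivot segment in original and normalized values
#'
#' Slices the joint-reduction region out of the raw signal (OV, rad/s) and
#' out of the recording-wide min-max normalized signal (NV), aligned on the
#' same half-open index range.
#'
#' @param signal Raw X-axis signal.
#' @param normalized The same signal after [normalize_unit_interval()];
#'   computed on demand when `NULL`.
#' @param segment A [maneuver_segment()] with `phase == "pivot"`.
#' @param source Optional provenance list stored on the result.
#' @return A [pivot_segment()].
#' @export
extract_pivot <- function(signal, normalized = NULL, segment, source = NULL) {
  if (segment$phase != "pivot")
    stop("extract_pivot requires a pivot-phase segment, got ", segment$phase)
  if (is.null(normalized)) normalized <- normalize_unit_interval(signal)
  idx <- (segment$start_index + 1L):segment$end_index
  if (length(idx) < 2) stop("pivot segment shorter than 2 samples")
  pivot_segment(signal[idx], normalized[idx], source = source)
}

#' Full preprocessing of one recording
#'
#' Convenience wrapper: select the X axis, detect peaks, segment maneuvers
#' and extract every pivot segment.
#'
#' @param recording A [gyro_recording()].
#' @param config A [peak_config()].
#' @return List with `peaks` (`detected_peaks`), `maneuvers` (segment
#'   triplets) and `pivots` (list of [pivot_segment()], one per maneuver).
#' @export
preprocess_recording <- function(recording, config = peak_config()) {
  sig <- select_axis(recording, "x")
  peaks <- detect_peaks(sig, config)
  mans <- segment_maneuvers(sig, peaks)
  nv <- normalize_unit_interval(sig)
  pivots <- lapply(seq_along(mans), function(i)
    extract_pivot(sig, nv, mans[[i]]$pivot,
                  source = list(subject_id = recording$subject_id,
                                evaluator_id = recording$evaluator_id,
                                repeat_index = recording$repeat_index,
                                maneuver = i)))
  list(peaks = peaks, maneuvers = mans, pivots = pivots)
}
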