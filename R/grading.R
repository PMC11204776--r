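#' KT-1000-based laxity grading ("Del Parque" classification)
#'
#' The CDP scale maps the side-to-side difference in anteroposterior tibial
#' displacement, measured in mm with the KT-1000 arthrometer, to a laxity
#' grade: 0 (difference 0-2 mm, almost null laxity), 1 (3 mm, low),
#' 2 (4-5 mm, considerable), 3 (6 mm and above, high). The published scale
#' leaves non-integer differences between 5 and 6 mm unmapped; the
#' difference is therefore rounded to the nearest integer millimetre first,
#' and every rounded value of 6 mm or more maps to grade 3, making the map
#' total and monotone.
#'
#' @param left_mm,right_mm KT-1000 displacement of each leg, mm, >= 0.
#' @return A list of class `cdp_grade` with `grade` (integer 0-3) and
#'   `mm_difference` (the rounded absolute difference).
#' @examples
#' cdp_grade(9, 6)$grade   # 1
#' cdp_grade(10, 6)$grade  # 2
#' @export
cdp_grade <- function(left_mm, right_mm) {
  if (missing(left_mm) || missing(right_mm) ||
      is.na(left_mm) || is.na(right_mm))
    stop("both KT-1000 measurements are required")
  if (!is.finite(left_mm) || !is.finite(right_mm) ||
      left_mm < 0 || right_mm < 0)
    stop("KT-1000 measurements must be finite and non-negative")
  d <- round(abs(left_mm - right_mm))
  grade <- if (d <= 2) 0L else if (d == 3) 1L else if (d <= 5) 2L else 3L
  structure(list(grade = grade, mm_difference = d), class = "cdp_grade")
}

#' Speed-class bin edges
#'
#' Maneuver recordings are grouped into classes 0-4 by the maximum angular
#' velocity reached. The study publishes no boundary values; the defaults
#' (50, 100, 150, 200 rad/s) spread the simulator's class amplitudes and are
#' overridable in every entry point.
#'
#' @param edges Four strictly increasing rad/s thresholds; class k covers
#'   `[edges[k], edges[k+1])` with class 0 below the first edge and class 4
#'   at or above the last.
#' @return Numeric vector of class `class_bins`.
#' @export
class_bins <- function(edges = c(50, 100, 150, 200)) {
  if (length(edges) != 4) stop("exactly 4 edges define 5 classes")
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  structure(as.numeric(edges), class = "class_bins")
}

#' @rdname class_bins
#' @export
default_class_bins <- function() class_bins()

# Bin a peak speed (rad/s) into 0..4.
assign_class_speed <- function(speed, bins = default_class_bins()) {
  sum(speed >= unclass(bins))
}

#' Assign a speed-based maneuver class
#'
#' The class is the bin index of the maximum positive-peak amplitude of the
#' recording (its "speed of the maneuver reached").
#'
#' @param peaks A `detected_peaks` object from [detect_peaks()], a
#'   [characteristic_vector()], or a numeric vector of peak amplitudes.
#' @param bins A [class_bins()].
#' @return A list of class `maneuver_class` with `klass` (integer 0-4) and
#'   `peak_speed` (rad/s).
#' @export
assign_class <- function(peaks, bins = default_class_bins()) {
  amps <- if (inherits(peaks, "detected_peaks")) peaks$amplitudes
          else if (inherits(peaks, "characteristic_vector")) peaks$amplitudes
          else as.numeric(peaks)
  if (length(amps) < 1) stop("at least one detected peak is required")
  speed <- max(amps)
  structure(list(klass = as.integer(assign_class_speed(speed, bins)),
                 peak_speed = speed),
            class = "maneuver_class")
}
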