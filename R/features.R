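#' Morphological features of the pivot segment
#'
#' The four scalar descriptors computed from the isolated joint-reduction
#' region and fed to the classifiers:
#' \describe{
#'   \item{`sd_nv`}{population (divide-by-N) standard deviation of the
#'     normalized values; dimensionless, bounded by 0.5. Large values mean
#'     pronounced oscillation after joint reduction.}
#'   \item{`max_ov`}{maximum of the original values, rad/s.}
#'   \item{`range_plus_mean_ov`}{`(max(ov) - min(ov)) + mean(ov)`, rad/s.}
#'   \item{`mean_square_ov`}{`sum(ov^2) / N` over the segment's own N,
#'     (rad/s)^2.}
#' }
#'
#' @param pivot A [pivot_segment()].
#' @return A named list of class `feature_vector` with the four features.
#' @examples
#' pv <- pivot_segment(ov = c(1, 2, 3), nv = c(0, 0.5, 1))
#' unlist(compute_features(pv))
#' @export
compute_features <- function(pivot) {
  stopifnot(inherits(pivot, "pivot_segment"))
  ov <- pivot$ov; nv <- pivot$nv
  n <- length(ov)
  if (n < 2) stop("pivot segment shorter than 2 samples")
  mu_nv <- mean(nv)
  structure(list(
    sd_nv = sqrt(sum((nv - mu_nv)^2) / n),
    max_ov = max(ov),
    range_plus_mean_ov = (max(ov) - min(ov)) + mean(ov),
    mean_square_ov = sum(ov^2) / n
  ), class = "feature_vector")
}

#' Feature table for a whole session
#'
#' Runs [preprocess_recording()] on every recording and computes the four
#' pivot features plus the characteristic vector per maneuver.
#'
#' @param session A [study_session()].
#' @param config A [peak_config()].
#' @param class_bins A [class_bins()] used to derive each recording's
#'   speed class.
#' @return A data.frame with one row per (recording, maneuver): identifier
#'   columns, the four features, the three peak amplitudes and times, the
#'   recording-level `klass`, and the subject's CDP `grade` (NA when KT-1000
#'   values are absent). Rows are sorted by (subject, evaluator, repeat,
#'   maneuver) so exports are stable.
#' @export
session_features <- function(session, config = peak_config(),
                             class_bins = default_class_bins()) {
  rows <- list()
  for (rec in session$recordings) {
    pp <- preprocess_recording(rec, config)
    subj <- session_subject(session, rec$subject_id)
    grade <- if (!is.na(subj$kt1000_left_mm) && !is.na(subj$kt1000_right_mm))
      cdp_grade(subj$kt1000_left_mm, subj$kt1000_right_mm)$grade else NA_integer_
    klass <- assign_class(pp$peaks, class_bins)$klass
    cv <- pp$peaks$cv
    for (m in seq_along(pp$pivots)) {
      fv <- compute_features(pp$pivots[[m]])
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = rec$subject_id, evaluator_id = rec$evaluator_id,
        repeat_index = rec$repeat_index, maneuver = m,
        sd_nv = fv$sd_nv, max_ov = fv$max_ov,
        range_plus_mean_ov = fv$range_plus_mean_ov,
        mean_square_ov = fv$mean_square_ov,
        amp1 = cv$amplitudes[1], amp2 = cv$amplitudes[2],
        amp3 = cv$amplitudes[3],
        time1_cs = cv$times[1], time2_cs = cv$times[2],
        time3_cs = cv$times[3],
        klass = klass, grade = grade,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(subject_id = character(), evaluator_id = character(),
                      repeat_index = integer(), maneuver = integer(),
                      sd_nv = numeric(), max_ov = numeric(),
                      range_plus_mean_ov = numeric(),
                      mean_square_ov = numeric(),
                      amp1 = numeric(), amp2 = numeric(), amp3 = numeric(),
                      time1_cs = numeric(), time2_cs = numeric(),
                      time3_cs = numeric(), klass = integer(),
                      grade = integer(), stringsAsFactors = FALSE))
  }
  tab <- do.call(rbind, rows)
  tab[order(tab$subject_id, tab$evaluator_id, tab$repeat_index,
            tab$maneuver), , drop = FALSE]
}

#' Recording-level feature aggregation
#'
#' Classification in this toolkit operates per recording (one exam capture);
#' maneuver-level pivot features are averaged across the recording's
#' maneuvers, which damps per-maneuver execution noise.
#'
#' @param feature_table Output of [session_features()].
#' @return One row per recording with averaged features; `klass` and `grade`
#'   are constant within a recording and carried through.
#' @export
recording_features <- function(feature_table) {
  key <- interaction(feature_table$subject_id, feature_table$evaluator_id,
                     feature_table$repeat_index, drop = TRUE)
  parts <- split(feature_table, key)
  rows <- lapply(parts, function(d) {
    data.frame(subject_id = d$subject_id[1], evaluator_id = d$evaluator_id[1],
               repeat_index = d$repeat_index[1],
               sd_nv = mean(d$sd_nv), max_ov = mean(d$max_ov),
               range_plus_mean_ov = mean(d$range_plus_mean_ov),
               mean_square_ov = mean(d$mean_square_ov),
               klass = d$klass[1], grade = d$grade[1],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab[order(tab$subject_id, tab$evaluator_id, tab$repeat_index), ,
      drop = FALSE]
}

#' Names of the four classifier feature columns
#' @return Character vector.
#' @export
feature_columns <- function() {
  c("sd_nv", "max_ov", "range_plus_mean_ov", "mean_square_ov")
}
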