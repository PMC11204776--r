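#' Intraclass correlation from ANOVA mean squares
#'
#' Reliability of the characteristic-vector measures (peak timing and peak
#' amplitude) across repeats of one evaluator (intraobserver) and across
#' evaluators (interobserver). Estimates follow the classical Shrout-Fleiss
#' single-rating forms computed from the two-way ANOVA decomposition of an
#' n-targets x k-raters matrix:
#' \deqn{ICC(1)   = (MSB - MSW) / (MSB + (k-1) MSW)}
#' \deqn{ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)}
#' \deqn{ICC(3,1) = (MSR - MSE) / (MSR + (k-1) MSE)}
#' where MSB/MSW are the one-way between/within-target mean squares and
#' MSR/MSC/MSE the two-way target, rater and residual mean squares.
#'
#' @name reliability
NULL

#' Ratings matrix
#'
#' @param values Numeric matrix, rows = targets (subjects), columns =
#'   raters (evaluators or repeats). Complete cases only.
#' @param measure Label of what is rated: `"peak_time_cs"`,
#'   `"peak_amplitude_rad_s"` or `"inter_peak_interval_cs"`.
#' @return The matrix with class `ratings_matrix`.
#' @export
ratings_matrix <- function(values,
                           measure = c("inter_peak_interval_cs",
                                       "peak_amplitude_rad_s",
                                       "peak_time_cs")) {
  measure <- match.arg(measure)
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("need at least 2 targets")
  if (ncol(values) < 2) stop("need at least 2 raters")
  if (anyNA(values)) stop("ratings matrix must be complete (no NA)")
  structure(values, measure = measure, class = c("ratings_matrix", "matrix"))
}

# Two-way ANOVA mean squares of an n x k matrix.
anova_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  ri <- rowMeans(m); cj <- colMeans(m)
  ssr <- k * sum((ri - g)^2)
  ssc <- n * sum((cj - g)^2)
  sst <- sum((m - g)^2)
  sse <- sst - ssr - ssc
  ssw <- sum((m - ri)^2)  # within-target (one-way residual)
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), msw = ssw / (n * (k - 1)),
       sst = sst, n = n, k = k)
}

#' Intraclass correlation coefficient
#'
#' @param matrix A [ratings_matrix()] (or plain matrix, targets x raters).
#' @param form One of `"ICC(1)"`, `"ICC(2,1)"`, `"ICC(3,1)"`.
#' @return A list of class `icc_result`: `estimate` (clipped to `[0, 1]`
#'   for reporting, as the scale is described as running from 0 to 1),
#'   `estimate_unclipped`, `form`, `n_targets`, `k_raters` and the mean
#'   squares (`msr`, `msc`, `mse`, `msw`).
#' @examples
#' m <- cbind(r1 = c(1, 3, 5), r2 = c(2, 4, 6))
#' icc(m, "ICC(3,1)")$estimate  # 1: perfect consistency
#' @export
icc <- function(matrix, form = c("ICC(2,1)", "ICC(1)", "ICC(3,1)")) {
  form <- match.arg(form)
  m <- unclass(as.matrix(matrix))
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("ICC requires at least 2 targets and 2 raters")
  if (anyNA(m)) stop("ratings matrix must be complete (no NA)")
  ms <- anova_mean_squares(m)
  if (ms$sst <= 0) stop("zero total variance: ICC undefined")
  n <- ms$n; k <- ms$k
  est <- switch(form,
    "ICC(1)"   = (ms$msr - ms$msw) / (ms$msr + (k - 1) * ms$msw),
    "ICC(2,1)" = (ms$msr - ms$mse) /
                 (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n),
    "ICC(3,1)" = (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse))
  if (!is.finite(est)) stop("ICC undefined for this matrix (degenerate ANOVA)")
  structure(list(estimate = min(1, max(0, est)), estimate_unclipped = est,
                 form = form, n_targets = n, k_raters = k,
                 msr = ms$msr, msc = ms$msc, mse = ms$mse, msw = ms$msw),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> %s = %.4f  (n=%d targets, k=%d raters) [%s]\n",
              x$form, x$estimate, x$n_targets, x$k_raters,
              landis_koch_label(x$estimate)))
  invisible(x)
}

#' Landis-Koch agreement label
#'
#' Interpretation bands for a reliability coefficient in `[0, 1]`:
#' below 0.2 "poor", 0.2-0.4 "fair", 0.4-0.6 "moderate", 0.6-0.8
#' "substantial", 0.8 and above "almost perfect".
#'
#' @param estimate Numeric in `[0, 1]`.
#' @return Character label.
#' @examples
#' landis_koch_label(0.95)  # "almost perfect"
#' landis_koch_label(0.71)  # "substantial"
#' @export
landis_koch_label <- function(estimate) {
  if (!is.finite(estimate) || estimate < 0 || estimate > 1)
    stop("estimate must lie in [0, 1]")
  if (estimate < 0.2) "poor"
  else if (estimate < 0.4) "fair"
  else if (estimate < 0.6) "moderate"
  else if (estimate < 0.8) "substantial"
  else "almost perfect"
}

#' Characteristic-vector summary table for a session
#'
#' Detects the three peaks of every recording and summarizes each recording
#' by its mean inter-peak interval (cs) and mean peak amplitude (rad/s);
#' intervals rather than absolute peak times are used because absolute times
#' depend on when the capture started, while the cadence between maneuvers
#' is the evaluator-reproducible quantity.
#'
#' @param session A [study_session()].
#' @param config A [peak_config()].
#' @param use_intervals Use the two inter-peak intervals (default) instead
#'   of the three absolute peak times for the timing measure.
#' @return data.frame with one row per recording: identifiers,
#'   `time_measure_cs`, `amplitude_measure`.
#' @export
session_cv_table <- function(session, config = peak_config(),
                             use_intervals = TRUE) {
  rows <- lapply(session$recordings, function(rec) {
    pk <- detect_peaks(select_axis(rec, "x"), config)
    tm <- if (use_intervals) mean(diff(pk$times)) else mean(pk$times)
    data.frame(subject_id = rec$subject_id, evaluator_id = rec$evaluator_id,
               repeat_index = rec$repeat_index,
               time_measure_cs = tm, amplitude_measure = mean(pk$amplitudes),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab[order(tab$subject_id, tab$evaluator_id, tab$repeat_index), ,
      drop = FALSE]
}

# Build a subjects x columns matrix of one measure, given a keyed cv table.
build_matrix <- function(tab, col_key, measure_col) {
  subs <- sort(unique(tab$subject_id))
  cols <- sort(unique(tab[[col_key]]))
  m <- matrix(NA_real_, length(subs), length(cols),
              dimnames = list(subs, as.character(cols)))
  for (i in seq_len(nrow(tab)))
    m[tab$subject_id[i], as.character(tab[[col_key]][i])] <-
      tab[[measure_col]][i]
  m
}

#' Intraobserver reliability analysis
#'
#' For each evaluator separately, an ICC with targets = subjects and raters
#' = that evaluator's repeats, for the timing measure and the amplitude
#' measure. Evaluators with fewer than 2 repeats on the common subjects are
#' excluded with a warning. The global average is the unweighted mean of the
#' per-evaluator estimates.
#'
#' @param session A [study_session()].
#' @param cv_table Optional precomputed [session_cv_table()].
#' @param form ICC form (default `"ICC(1)"`: repeats of one evaluator are
#'   interchangeable ratings).
#' @param config A [peak_config()].
#' @return List of class `intraobserver_result`: `per_evaluator` (named list
#'   with `time` and `amplitude` [icc()] results), `global_time`,
#'   `global_amplitude` (means of clipped estimates), and labels.
#' @export
intraobserver_analysis <- function(session, cv_table = NULL,
                                   form = "ICC(1)",
                                   config = peak_config()) {
  if (is.null(cv_table)) cv_table <- session_cv_table(session, config)
  per <- list()
  for (ev in session$evaluators) {
    tab <- cv_table[cv_table$evaluator_id == ev, , drop = FALSE]
    if (nrow(tab) == 0) next
    if (max(tab$repeat_index) < 2) {
      warning("evaluator ", ev,
              " has a single repeat; excluded from intraobserver analysis")
      next
    }
    mt <- build_matrix(tab, "repeat_index", "time_measure_cs")
    ma <- build_matrix(tab, "repeat_index", "amplitude_measure")
    keep <- stats::complete.cases(mt) & stats::complete.cases(ma)
    mt <- mt[keep, , drop = FALSE]; ma <- ma[keep, , drop = FALSE]
    per[[ev]] <- list(time = icc(mt, form), amplitude = icc(ma, form))
  }
  if (length(per) == 0)
    stop("no evaluator has >= 2 repeats: intraobserver ICC impossible")
  gt <- mean(vapply(per, function(p) p$time$estimate, numeric(1)))
  ga <- mean(vapply(per, function(p) p$amplitude$estimate, numeric(1)))
  structure(list(per_evaluator = per, global_time = gt,
                 global_amplitude = ga,
                 global_time_label = landis_koch_label(gt),
                 global_amplitude_label = landis_koch_label(ga),
                 form = form),
            class = "intraobserver_result")
}

#' Interobserver reliability analysis
#'
#' One ICC per measure with targets = subjects and raters = evaluators.
#' When evaluators repeated the exam, either the first repeat or the
#' per-evaluator mean enters the matrix.
#'
#' @param session A [study_session()].
#' @param cv_table Optional precomputed [session_cv_table()].
#' @param form ICC form (default `"ICC(2,1)"`: evaluators are a random
#'   sample of orthopedists and absolute agreement is of interest).
#' @param aggregate `"first"` (default) or `"mean"` across repeats.
#' @param config A [peak_config()].
#' @return List of class `interobserver_result` with `time` and `amplitude`
#'   [icc()] results and their labels.
#' @export
interobserver_analysis <- function(session, cv_table = NULL,
                                   form = "ICC(2,1)",
                                   aggregate = c("first", "mean"),
                                   config = peak_config()) {
  aggregate <- match.arg(aggregate)
  if (is.null(cv_table)) cv_table <- session_cv_table(session, config)
  tab <- if (aggregate == "first")
    cv_table[cv_table$repeat_index == min(cv_table$repeat_index), ,
             drop = FALSE]
  else {
    key <- interaction(cv_table$subject_id, cv_table$evaluator_id,
                       drop = TRUE)
    agg <- lapply(split(cv_table, key), function(d)
      data.frame(subject_id = d$subject_id[1],
                 evaluator_id = d$evaluator_id[1], repeat_index = 1L,
                 time_measure_cs = mean(d$time_measure_cs),
                 amplitude_measure = mean(d$amplitude_measure),
                 stringsAsFactors = FALSE))
    do.call(rbind, agg)
  }
  if (length(unique(tab$evaluator_id)) < 2)
    stop("interobserver ICC requires at least 2 evaluators")
  mt <- build_matrix(tab, "evaluator_id", "time_measure_cs")
  ma <- build_matrix(tab, "evaluator_id", "amplitude_measure")
  keep <- stats::complete.cases(mt) & stats::complete.cases(ma)
  if (sum(keep) < 2)
    stop("fewer than 2 subjects rated by all evaluators: ",
         "disjoint subject coverage")
  mt <- mt[keep, , drop = FALSE]; ma <- ma[keep, , drop = FALSE]
  t_res <- icc(mt, form); a_res <- icc(ma, form)
  structure(list(time = t_res, amplitude = a_res,
                 time_label = landis_koch_label(t_res$estimate),
                 amplitude_label = landis_koch_label(a_res$estimate),
                 n_subjects = sum(keep), form = form),
            class = "interobserver_result")
}
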