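#' Plain-text persistence
#'
#' Recordings travel as UTF-8 comma-separated files with the mandatory
#' header `t_cs,gx_rad_s,gy_rad_s,gz_rad_s` ('.' decimal separator); a
#' session is a directory holding one `session.json` manifest plus one CSV
#' per recording. All writers are deterministic: stable row ordering and
#' fixed numeric formatting (`%.17g`, which round-trips doubles exactly).
#'
#' @name io_store
NULL

fmt_num <- function(v) sprintf("%.17g", v)

#' Write / read one recording as CSV
#'
#' @param recording A [gyro_recording()].
#' @param path File path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a [gyro_recording()].
#' @export
write_recording <- function(recording, path) {
  lines <- c("t_cs,gx_rad_s,gy_rad_s,gz_rad_s",
             paste(fmt_num(round(recording$t)), fmt_num(recording$x),
                   fmt_num(recording$y), fmt_num(recording$z), sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @param subject_id,evaluator_id,repeat_index Identity to attach (the CSV
#'   itself carries only samples).
#' @param sample_rate,duration Declared capture geometry; a row count
#'   within 2% of `sample_rate * duration` warns, a larger deviation
#'   errors.
#' @export
read_recording <- function(path, subject_id = "unknown",
                           evaluator_id = "unknown", repeat_index = 1,
                           sample_rate = 100, duration = 5) {
  if (!file.exists(path)) stop("no such recording file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) stop("empty recording file: ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  need <- c("t_cs", "gx_rad_s", "gy_rad_s", "gz_rad_s")
  miss <- setdiff(need, header)
  if (length(miss) > 0)
    stop("recording file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  body <- lines[-1]
  body <- body[nzchar(body)]
  cells <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(cells)
  bad <- which(nf != length(header))
  if (length(bad) > 0)
    stop("ragged row in ", path, ": data row ", bad[1], " has ", nf[bad[1]],
         " fields, expected ", length(header))
  m <- matrix(as.numeric(unlist(cells)), ncol = length(header), byrow = TRUE)
  colnames(m) <- header
  t_cs <- m[, "t_cs"]
  if (length(t_cs) >= 2) {
    nonmono <- which(diff(t_cs) <= 0)
    if (length(nonmono) > 0)
      stop("time not strictly increasing in ", path, " at data row ",
           nonmono[1] + 1L)
  }
  nominal <- round(sample_rate * duration)
  dev <- abs(nrow(m) - nominal) / nominal
  if (dev > 0.02)
    stop("recording ", path, " has ", nrow(m), " rows; more than 2% off ",
         "the declared ", nominal)
  if (nrow(m) != nominal)
    warning("recording ", path, " has ", nrow(m), " rows, nominal ",
            nominal, " (within 2% tolerance)")
  gyro_recording(m[, "gx_rad_s"], m[, "gy_rad_s"], m[, "gz_rad_s"],
                 subject_id, evaluator_id, repeat_index,
                 sample_rate = sample_rate, duration = duration, t = t_cs)
}

recording_filename <- function(rec) {
  sprintf("rec_%s_%s_%02d.csv", rec$subject_id, rec$evaluator_id,
          rec$repeat_index)
}

#' Write / read a study session
#'
#' A session directory holds `session.json` (schema-versioned manifest:
#' subjects with KT-1000 and IKDC fields, evaluators, recording file
#' references) and the referenced recording CSVs. Unknown top-level
#' manifest keys are accepted and preserved across a round trip.
#'
#' @param session A [study_session()].
#' @param dir Directory (created if needed).
#' @return `write_session` returns `dir` invisibly; `read_session` a
#'   [study_session()].
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- session$recordings
  ord <- order(vapply(recs, function(r)
    paste(r$subject_id, r$evaluator_id, sprintf("%05d", r$repeat_index)),
    character(1)))
  recs <- recs[ord]
  rec_entries <- lapply(recs, function(r) {
    f <- recording_filename(r)
    write_recording(r, file.path(dir, f))
    list(file = f, subject_id = r$subject_id, evaluator_id = r$evaluator_id,
         repeat_index = r$repeat_index, sample_rate = r$sample_rate,
         duration = r$duration)
  })
  manifest <- c(list(
    schema_version = "1",
    subjects = lapply(session$subjects, function(s) unclass(s)),
    evaluators = as.list(session$evaluators),
    recordings = rec_entries,
    provenance = session$provenance),
    attr(session, "manifest_extras"))
  jsonlite::write_json(manifest, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  mpath <- file.path(dir, "session.json")
  if (!file.exists(mpath)) stop("no session.json in ", dir)
  man <- jsonlite::read_json(mpath)
  known <- c("schema_version", "subjects", "evaluators", "recordings",
             "provenance")
  files <- vapply(man$recordings, function(r) r$file, character(1))
  missing <- files[!file.exists(file.path(dir, files))]
  if (length(missing) > 0)
    stop("manifest references missing file(s): ",
         paste(missing, collapse = ", "))
  subjects <- lapply(man$subjects, function(s) {
    num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
    chr <- function(v) if (is.null(v)) NA_character_ else as.character(v)
    subject_record(s$subject_id, initials = chr(s$initials),
                   age = num(s$age), gender = chr(s$gender),
                   height = num(s$height), weight = num(s$weight),
                   kt1000_left_mm = num(s$kt1000_left_mm),
                   kt1000_right_mm = num(s$kt1000_right_mm),
                   ikdc_label = chr(s$ikdc_label), notes = chr(s$notes))
  })
  recordings <- lapply(man$recordings, function(r)
    read_recording(file.path(dir, r$file), r$subject_id, r$evaluator_id,
                   r$repeat_index,
                   sample_rate = if (is.null(r$sample_rate)) 100
                                 else r$sample_rate,
                   duration = if (is.null(r$duration)) 5 else r$duration))
  session <- study_session(subjects, recordings,
                           evaluators = unlist(man$evaluators),
                           provenance = man$provenance)
  extras <- man[setdiff(names(man), known)]
  if (length(extras) > 0) attr(session, "manifest_extras") <- extras
  session
}

#' Export a feature table as CSV
#'
#' One row per (recording, maneuver), stably ordered; re-exporting the same
#' table yields a byte-identical file.
#'
#' @param feature_table Output of [session_features()].
#' @param path File path.
#' @return `path` invisibly.
#' @export
export_feature_table <- function(feature_table, path) {
  tab <- feature_table
  num_cols <- vapply(tab, is.numeric, logical(1))
  for (j in which(num_cols)) tab[[j]] <- fmt_num(tab[[j]])
  utils::write.table(tab, path, sep = ",", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table CSV
#' @param path File path.
#' @return data.frame.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

icc_entry <- function(res, label) {
  list(estimate = res$estimate, estimate_unclipped = res$estimate_unclipped,
       form = res$form, n_targets = res$n_targets, k_raters = res$k_raters,
       mean_squares = list(msr = res$msr, msc = res$msc, mse = res$mse,
                           msw = res$msw),
       landis_koch = label)
}

#' Write an ICC report as JSON
#'
#' @param intra An `intraobserver_result` (or `NULL`).
#' @param inter An `interobserver_result` (or `NULL`).
#' @param path Output path (`icc-report.json`).
#' @return `path` invisibly.
#' @export
write_icc_report <- function(intra = NULL, inter = NULL, path) {
  out <- list(schema_version = "1")
  if (!is.null(intra)) {
    out$intraobserver <- list(
      form = intra$form,
      global = list(time = intra$global_time,
                    amplitude = intra$global_amplitude,
                    time_label = intra$global_time_label,
                    amplitude_label = intra$global_amplitude_label),
      per_evaluator = lapply(intra$per_evaluator, function(p)
        list(time = icc_entry(p$time, landis_koch_label(p$time$estimate)),
             amplitude = icc_entry(p$amplitude,
                                   landis_koch_label(p$amplitude$estimate)))))
  }
  if (!is.null(inter)) {
    out$interobserver <- list(
      form = inter$form, n_subjects = inter$n_subjects,
      time = icc_entry(inter$time, inter$time_label),
      amplitude = icc_entry(inter$amplitude, inter$amplitude_label))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' @param report An `eval_report` from [evaluate_predictions()].
#' @param path Output path (`eval-report.json`).
#' @param extra Optional named list merged into the JSON (e.g. methods,
#'   seed).
#' @return `path` invisibly.
#' @export
write_eval_report <- function(report, path, extra = list()) {
  cm <- report$confusion_matrix
  out <- c(list(schema_version = "1",
                accuracy_pct = report$accuracy,
                recall_pct = report$recall,
                precision_pct = report$precision,
                f1 = report$f1,
                n_test = report$n_test,
                n_classifiable = report$n_classifiable,
                classifiability_pct = report$classifiability_pct,
                confusion_matrix = list(labels = rownames(cm),
                                        counts = unclass(unname(cm)))),
           extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
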