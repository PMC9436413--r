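# CSV dialects. Traces and logs are written as plain CSV with a small block
# of "# key=value" comment lines carrying metadata (sample rate, stimulus
# time, schedule fields) so that every file round-trips through the package's
# own readers.

write_meta <- function(path, meta, df) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    v <- meta[[k]]
    if (!is.null(v) && length(v)) {
      writeLines(sprintf("# %s=%s", k, paste(v, collapse = ";")), con)
    }
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

read_meta <- function(path) {
  lines <- readLines(path, n = 64)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^# ", "", ln)
    k <- sub("=.*$", "", kv)
    meta[[k]] <- sub("^[^=]*=", "", kv)
  }
  meta
}

read_body <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

check_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_param(path, ": missing column(s) ", paste(miss, collapse = ", "))
  }
}

check_monotone_time <- function(time_s, path, strict = TRUE) {
  d <- diff(time_s)
  bad <- if (strict) which(d <= 0) else which(d < 0)
  if (length(bad)) {
    stop_param(path, ": time_s not ", if (strict) "strictly increasing"
               else "nondecreasing", " at data row ", bad[1] + 1)
  }
}

#' Write / read a photometry trace as CSV
#'
#' Columns `time_s, f465, f560, mask` (mask as 0/1; off samples keep their
#' row with empty fluorescence fields), with the sampling rate in a comment
#' header.
#'
#' @param trace a [photometry_trace()].
#' @param path file path.
#' @return `write_photometry_csv` returns `path` invisibly;
#'   `read_photometry_csv` returns a [photometry_trace()].
#' @export
write_photometry_csv <- function(trace, path) {
  df <- data.frame(time_s = trace$time_s, f465 = trace$f465,
                   f560 = trace$f560, mask = as.integer(trace$mask))
  write_meta(path, list(dialect = "photometry_trace",
                        sample_rate_hz = trace$sample_rate_hz), df)
  invisible(path)
}

#' @rdname write_photometry_csv
#' @export
read_photometry_csv <- function(path) {
  meta <- read_meta(path)
  df <- read_body(path)
  check_columns(df, c("time_s", "f465", "f560", "mask"), path)
  check_monotone_time(df$time_s, path)
  fs <- as.numeric(meta$sample_rate_hz %||% NA)
  if (!is.finite(fs)) fs <- 1 / stats::median(diff(df$time_s))
  photometry_trace(df$time_s, df$f465, df$f560, df$mask == 1, fs)
}

#' Write / read an FSCV trace as CSV
#'
#' Columns `time_s, value, units`; sampling rate and stimulus time travel in
#' the comment header. The units column must be constant within a file.
#'
#' @param trace an [fscv_trace()].
#' @param path file path.
#' @return `write_fscv_csv` returns `path` invisibly; `read_fscv_csv`
#'   returns an [fscv_trace()].
#' @export
write_fscv_csv <- function(trace, path) {
  df <- data.frame(time_s = trace$time_s, value = trace$value,
                   units = trace$units)
  write_meta(path, list(dialect = "fscv_trace",
                        sample_rate_hz = trace$sample_rate_hz,
                        stim_time_s = trace$stim_time_s), df)
  invisible(path)
}

#' @rdname write_fscv_csv
#' @export
read_fscv_csv <- function(path) {
  meta <- read_meta(path)
  df <- read_body(path)
  check_columns(df, c("time_s", "value", "units"), path)
  check_monotone_time(df$time_s, path)
  units <- unique(df$units)
  if (length(units) != 1 || !units %in% c("CONC_UM", "CURRENT_NA")) {
    stop_param(path, ": units column must be constant, CONC_UM or CURRENT_NA")
  }
  fs <- as.numeric(meta$sample_rate_hz %||% NA)
  if (!is.finite(fs)) fs <- 1 / stats::median(diff(df$time_s))
  fscv_trace(df$time_s, df$value, units = units, sample_rate_hz = fs,
             stim_time_s = as.numeric(meta$stim_time_s %||% NA))
}

#' Write / read an operant event log as CSV
#'
#' Columns `time_s, event, dose_mg_kg, trial_id`; the schedule parameters
#' travel in the comment header so a read-back log carries a full
#' [schedule_spec()].
#'
#' @param log an [operant_log()].
#' @param path file path.
#' @return `write_event_log` returns `path` invisibly; `read_event_log`
#'   returns an [operant_log()].
#' @export
write_event_log <- function(log, path) {
  s <- log_schedule(log)
  meta <- list(dialect = "operant_log", kind = s$kind,
               unit_dose_mg_kg = s$unit_dose_mg_kg,
               dose_sequence = s$dose_sequence, trial_s = s$trial_s,
               session_s = s$session_s, timeout_s = s$timeout_s,
               cue_s = s$cue_s, cap = s$cap, intertrial_s = s$intertrial_s,
               pr_a = s$pr_a, pr_b = s$pr_b,
               session_end_s = log_session_end(log))
  write_meta(path, meta, as.data.frame(log))
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  meta <- read_meta(path)
  df <- read_body(path)
  check_columns(df, c("time_s", "event", "dose_mg_kg", "trial_id"), path)
  check_monotone_time(df$time_s, path, strict = FALSE)
  num <- function(x) if (is.null(x)) NULL else as.numeric(strsplit(x, ";")[[1]])
  kind <- meta$kind %||% "FR1"
  sched <- schedule_spec(
    kind = kind,
    unit_dose_mg_kg = num(meta$unit_dose_mg_kg) %||% 0.5,
    dose_sequence = if (kind == "MULTIDOSE") num(meta$dose_sequence) else NULL,
    trial_s = num(meta$trial_s) %||% 1800,
    session_s = num(meta$session_s) %||% 10800,
    timeout_s = num(meta$timeout_s) %||% 10,
    cue_s = num(meta$cue_s) %||% 5,
    cap = num(meta$cap) %||% 64,
    intertrial_s = num(meta$intertrial_s) %||% 60,
    pr_a = num(meta$pr_a) %||% 5,
    pr_b = num(meta$pr_b) %||% 0.18)
  operant_log(df, sched,
              session_end_s = num(meta$session_end_s) %||% sched$session_s)
}

#' Write analysis results as JSON
#'
#' @param x a list of results (coerced with `auto_unbox`).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
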