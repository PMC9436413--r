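#' Progressive-ratio response requirement
#'
#' The number of active responses required for the n-th reinforcer under the
#' progressive-ratio schedule, \eqn{N = a (e^{b n} - 1)} rounded half away
#' from zero and floored at 1. With the defaults a = 5, b = 0.18 this yields
#' the requirement series 1, 2, 4, 5, 7, 10, 13, 16, 20, 25, 31, 38, 47, 57,
#' 69, 84, 102, ...
#'
#' Published listings of this series often begin with a duplicated "1, 1";
#' the formula itself produces a single 1 at n = 1 (5*(e^0.18 - 1) = 0.986
#' rounds to 1). This implementation follows the formula; if the first
#' reinforcer is treated as a free/priming reinforcer, prepend a 1 to
#' [pr_series()].
#'
#' @param n reinforcer index (vectorized), n >= 1.
#' @param a,b schedule constants (defaults 5 and 0.18).
#' @return integer vector of required responses.
#' @export
#' @examples
#' pr_requirement(1:18)
pr_requirement <- function(n, a = 5, b = 0.18) {
  if (any(n < 1)) stop_param("reinforcer index `n` must be >= 1")
  out <- pmax(1, round_half_away(a * (exp(b * n) - 1)))
  if (max(out) < .Machine$integer.max) as.integer(out) else out
}

#' Progressive-ratio requirement series
#'
#' @param length number of reinforcers to tabulate.
#' @inheritParams pr_requirement
#' @return integer vector `pr_requirement(1:length)`; always nondecreasing.
#' @export
pr_series <- function(length, a = 5, b = 0.18) {
  if (length < 1) stop_param("`length` must be >= 1")
  pr_requirement(seq_len(length), a = a, b = b)
}

#' Infusion duration for a unit dose
#'
#' Infusion durations scale in proportion to the unit dose, anchored at
#' 7.07 s for 1.0 mg/kg, and are reported to 2 decimals (half away from
#' zero). This reproduces the multiple-dose durations 7.07, 1.77, 0.88,
#' 0.44, 0.22 and 0 s for 1.0, 0.25, 0.125, 0.0625, 0.03125 and 0 mg/kg.
#'
#' @param dose_mg_kg unit dose, mg/kg (vectorized, >= 0).
#' @param anchor_dose_mg_kg,anchor_s anchor point of the proportional scale.
#' @return infusion duration(s) in seconds.
#' @export
#' @examples
#' infusion_duration(c(1.0, 0.25, 0.125, 0.0625, 0.03125, 0))
infusion_duration <- function(dose_mg_kg, anchor_dose_mg_kg = 1.0,
                              anchor_s = 7.07) {
  if (any(dose_mg_kg < 0)) stop_param("dose must be >= 0")
  round_half_away(anchor_s * dose_mg_kg / anchor_dose_mg_kg, 2)
}

#' Progressive-ratio breakpoint
#'
#' The breakpoint is the response requirement completed for the last
#' reinforcer obtained before the first period of at least `gap_s` (1 hr)
#' with no infusions. If no such infusion-free period occurs (including a
#' terminal gap shorter than `gap_s`), the requirement of the last infusion
#' of the session stands; with no infusions at all the breakpoint is 0.
#'
#' @param log an [operant_log()] from a PR session.
#' @param gap_s infusion-free period defining lapse of responding, seconds
#'   (default 3600).
#' @return integer breakpoint (completed response requirement).
#' @export
pr_breakpoint <- function(log, gap_s = 3600) {
  sched <- log_schedule(log)
  if (is.null(sched) || sched$kind != "PR") {
    stop_param("breakpoint is defined for PR session logs only")
  }
  inf <- log$time_s[log$event == "INFUSION_START"]
  m <- length(inf)
  if (m == 0) return(0L)
  gaps <- diff(inf)
  k <- which(gaps >= gap_s)
  idx <- if (length(k)) k[1] else m
  pr_requirement(idx, a = sched$pr_a, b = sched$pr_b)
}

#' Summarize an operant session
#'
#' Tabulates the panel quantities of a self-administration session: active
#' and inactive nose pokes (timeout responses included — they are counted
#' but have no consequence), infusions, total drug intake (sum of infusions
#' times unit dose), a per-dose breakdown, and for PR sessions the
#' breakpoint.
#'
#' @param log an [operant_log()].
#' @return list of class `session_summary`: `active_pokes`, `inactive_pokes`,
#'   `infusions`, `intake_mg_kg`, `per_dose` (data.frame dose/infusions/
#'   intake), `breakpoint` (PR only, else `NA`).
#' @export
summarize_session <- function(log) {
  sched <- log_schedule(log)
  bad <- !is.finite(log$time_s)
  if (any(bad)) {
    stop_param("malformed event time at row ", which(bad)[1])
  }
  inf <- log[log$event == "INFUSION_START", , drop = FALSE]
  per_dose <- if (nrow(inf)) {
    agg <- stats::aggregate(list(infusions = inf$time_s),
                            by = list(dose_mg_kg = inf$dose_mg_kg), FUN = length)
    agg$intake_mg_kg <- agg$infusions * agg$dose_mg_kg
    agg
  } else {
    data.frame(dose_mg_kg = numeric(0), infusions = integer(0),
               intake_mg_kg = numeric(0))
  }
  bp <- if (!is.null(sched) && sched$kind == "PR") pr_breakpoint(log)
        else NA_integer_
  structure(
    list(active_pokes = sum(log$event == "ACTIVE_POKE"),
         inactive_pokes = sum(log$event == "INACTIVE_POKE"),
         infusions = nrow(inf),
         intake_mg_kg = sum(per_dose$intake_mg_kg),
         per_dose = per_dose,
         breakpoint = bp),
    class = "session_summary")
}

#' Acquisition criteria for self-administration training
#'
#' Cocaine: at least 25 infusions and an active/inactive response ratio above
#' 2:1 for 3 consecutive days, with less than 20% variability in daily
#' infusions across two consecutive sessions; animals not reaching criteria
#' within 10 sessions are excluded. Sucrose variant: at least 30 rewards and
#' the same ratio for 4 consecutive days *including the last day*.
#'
#' @param preset `"cocaine"` or `"sucrose"`, or override fields directly.
#' @param min_infusions minimum daily reinforcers.
#' @param ratio_threshold active/inactive ratio that must be exceeded.
#' @param consecutive_days length of the qualifying run.
#' @param variability_threshold max relative difference in infusions across
#'   the final two sessions of the run (|a-b| / mean(a,b)).
#' @param require_last_day if `TRUE`, the qualifying run must end on the
#'   final session (sucrose rule).
#' @param max_sessions training sessions allowed before exclusion.
#' @return list of class `acquisition_criteria`.
#' @export
acquisition_criteria <- function(preset = c("cocaine", "sucrose"),
                                 min_infusions = NULL,
                                 ratio_threshold = 2.0,
                                 consecutive_days = NULL,
                                 variability_threshold = 0.20,
                                 require_last_day = NULL,
                                 max_sessions = 10) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    cocaine = list(min_infusions = 25, consecutive_days = 3,
                   require_last_day = FALSE),
    sucrose = list(min_infusions = 30, consecutive_days = 4,
                   require_last_day = TRUE))
  structure(
    list(preset = preset,
         min_infusions = min_infusions %||% defaults$min_infusions,
         ratio_threshold = ratio_threshold,
         consecutive_days = consecutive_days %||% defaults$consecutive_days,
         variability_threshold = variability_threshold,
         require_last_day = require_last_day %||% defaults$require_last_day,
         max_sessions = max_sessions),
    class = "acquisition_criteria")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Relative variability between two counts: |a-b| / mean(a,b).
rel_variability <- function(a, b) {
  m <- (a + b) / 2
  if (m == 0) return(NA_real_)
  abs(a - b) / m
}

#' Apply acquisition criteria to a training history
#'
#' @param daily data.frame with one row per training session, columns
#'   `infusions`, `active_pokes`, `inactive_pokes`, in session order.
#' @param criteria an [acquisition_criteria()] object.
#' @return list: `acquired` (flag), `acquisition_day` (first qualifying day,
#'   or `NA`), `exclusion_reason` (`NA` when acquired). A zero inactive count
#'   with positive active count is treated as an infinite ratio (passes).
#' @export
acquisition_filter <- function(daily, criteria = acquisition_criteria()) {
  req <- c("infusions", "active_pokes", "inactive_pokes")
  if (!all(req %in% names(daily))) {
    stop_param("daily summaries need columns: ", paste(req, collapse = ", "))
  }
  n_days <- nrow(daily)
  if (n_days < 1) stop_param("need at least one daily summary")
  k <- criteria$consecutive_days
  ratio <- ifelse(daily$inactive_pokes == 0,
                  ifelse(daily$active_pokes > 0, Inf, 0),
                  daily$active_pokes / daily$inactive_pokes)
  day_ok <- daily$infusions >= criteria$min_infusions &
    ratio > criteria$ratio_threshold

  last_considered <- min(n_days, criteria$max_sessions)
  candidates <- if (criteria$require_last_day) last_considered else
    seq_len(last_considered)
  reason <- "min_infusions_or_ratio"
  for (d in candidates) {
    if (d < k) next
    run <- (d - k + 1):d
    if (!all(day_ok[run])) next
    v <- rel_variability(daily$infusions[d - 1], daily$infusions[d])
    if (is.na(v) || v > criteria$variability_threshold) {
      reason <- "variability"
      next
    }
    return(list(acquired = TRUE, acquisition_day = d, exclusion_reason = NA))
  }
  list(acquired = FALSE, acquisition_day = NA_integer_,
       exclusion_reason = reason)
}

#' Dose-response curve from a multiple-dose session
#'
#' Per-trial infusion counts and intake keyed by unit dose, and the dose
#' maintaining maximal responding (the argmax of the typically inverted-U
#' curve; flagged undefined when no infusions occurred at any dose).
#'
#' @param log an [operant_log()] from a MULTIDOSE session.
#' @return list of class `dose_response`: `curve` (data.frame trial_id /
#'   dose_mg_kg / infusions / intake_mg_kg), `max_dose_mg_kg`,
#'   `max_defined`, `total_intake_mg_kg`.
#' @export
dose_response <- function(log) {
  sched <- log_schedule(log)
  if (is.null(sched) || sched$kind != "MULTIDOSE") {
    stop_param("dose_response is defined for MULTIDOSE logs")
  }
  trials <- log[log$event == "TRIAL_START", c("trial_id", "dose_mg_kg")]
  if (!nrow(trials)) stop_param("log has no TRIAL_START markers")
  inf <- log[log$event == "INFUSION_START", , drop = FALSE]
  counts <- vapply(trials$trial_id,
                   function(tr) sum(inf$trial_id == tr), integer(1))
  curve <- data.frame(trial_id = trials$trial_id,
                      dose_mg_kg = trials$dose_mg_kg,
                      infusions = counts,
                      intake_mg_kg = counts * trials$dose_mg_kg)
  max_defined <- any(curve$infusions > 0)
  max_dose <- if (max_defined) {
    curve$dose_mg_kg[which.max(curve$infusions)]
  } else NA_real_
  structure(list(curve = curve, max_dose_mg_kg = max_dose,
                 max_defined = max_defined,
                 total_intake_mg_kg = sum(curve$intake_mg_kg)),
            class = "dose_response")
}

#' Multiple-dose stability rule
#'
#' Responding is stable across two consecutive multiple-dose sessions when
#' (1) total infusions vary by less than 20% (|a-b| / mean) and (2) the dose
#' maintaining maximal responding drifts by no more than half a log10 unit.
#'
#' @param dr1,dr2 [dose_response()] results for the two sessions.
#' @param infusion_variation_threshold default 0.20.
#' @param max_dose_drift_log10 default 0.5.
#' @return list: `stable`, `infusion_variation`, `dose_drift_log10`,
#'   `defined` (`FALSE` when either session had no infusions).
#' @export
multidose_stable <- function(dr1, dr2,
                             infusion_variation_threshold = 0.20,
                             max_dose_drift_log10 = 0.5) {
  n1 <- sum(dr1$curve$infusions)
  n2 <- sum(dr2$curve$infusions)
  if (!dr1$max_defined || !dr2$max_defined) {
    return(list(stable = NA, infusion_variation = NA_real_,
                dose_drift_log10 = NA_real_, defined = FALSE))
  }
  v <- rel_variability(n1, n2)
  drift <- abs(log10(dr1$max_dose_mg_kg) - log10(dr2$max_dose_mg_kg))
  list(stable = v <= infusion_variation_threshold &&
         drift <= max_dose_drift_log10,
       infusion_variation = v, dose_drift_log10 = drift, defined = TRUE)
}

#' Inter-infusion interval statistics
#'
#' Quantifies the temporal pattern of drug taking (regularly spaced versus
#' sporadic intake with long gaps): intervals between consecutive infusion
#' onsets, their mean and coefficient of variation, and the list of gaps
#' above a threshold.
#'
#' @param log an [operant_log()].
#' @param gap_threshold_s intervals above this are reported as gaps
#'   (default 600 s).
#' @return list: `intervals_s`, `mean_s`, `cv`, `gaps_s`, `defined`
#'   (`FALSE` with fewer than 2 infusions).
#' @export
interval_stats <- function(log, gap_threshold_s = 600) {
  inf <- log$time_s[log$event == "INFUSION_START"]
  if (length(inf) < 2) {
    return(list(intervals_s = numeric(0), mean_s = NA_real_, cv = NA_real_,
                gaps_s = numeric(0), defined = FALSE))
  }
  iv <- diff(inf)
  list(intervals_s = iv, mean_s = mean(iv),
       cv = stats::sd(iv) / mean(iv),
       gaps_s = iv[iv > gap_threshold_s], defined = TRUE)
}
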