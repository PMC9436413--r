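#' Operant schedule specification
#'
#' Encodes the reinforcement schedules used in intravenous cocaine and oral
#' sucrose self-administration: fixed-ratio 1 (`FR1`), the descending
#' multiple-dose paradigm (`MULTIDOSE`, one 30-min trial per dose separated by
#' 1-min intertrial timeouts), and progressive ratio (`PR`, requirement
#' N = a*(exp(b*n) - 1) rounded half away from zero). Every reinforced
#' response triggers a cue light (5 s) and a timeout (10 s) during which
#' responses are counted but have no consequence; sessions end early once the
#' reinforcer cap (64) is reached.
#'
#' @param kind one of `"FR1"`, `"MULTIDOSE"`, `"PR"`.
#' @param unit_dose_mg_kg unit dose per infusion (FR1/PR), mg/kg.
#' @param dose_sequence ordered unit doses for MULTIDOSE trials, mg/kg.
#'   Default is the training dose 0.5 followed by the descending series
#'   1.0, 0.25, 0.125, 0.0625, 0.03125, 0.
#' @param trial_s per-trial duration for MULTIDOSE, seconds (default 1800).
#' @param session_s session duration, seconds (default 10800 = 3 h).
#' @param timeout_s post-reinforcement timeout, seconds (default 10).
#' @param cue_s cue-light duration, seconds (default 5).
#' @param cap maximum reinforcers before the session ends early (default 64,
#'   the overdose guard); in MULTIDOSE sessions the cap applies within each
#'   dose trial (the remainder of the trial is locked out, the session
#'   continues).
#' @param intertrial_s intertrial timeout for MULTIDOSE, seconds (default 60).
#' @param pr_a,pr_b progressive-ratio requirement constants (defaults 5, 0.18).
#' @return list of class `schedule_spec`.
#' @export
schedule_spec <- function(kind = c("FR1", "MULTIDOSE", "PR"),
                          unit_dose_mg_kg = 0.5,
                          dose_sequence = NULL,
                          trial_s = 1800,
                          session_s = 10800,
                          timeout_s = 10,
                          cue_s = 5,
                          cap = 64,
                          intertrial_s = 60,
                          pr_a = 5,
                          pr_b = 0.18) {
  kind <- match.arg(kind)
  check_scalar_num(session_s, "session_s", min = 0, strict_min = TRUE)
  check_scalar_num(timeout_s, "timeout_s", min = 0)
  check_scalar_num(cue_s, "cue_s", min = 0)
  check_scalar_num(cap, "cap", min = 1)
  check_scalar_num(intertrial_s, "intertrial_s", min = 0)
  if (kind == "MULTIDOSE") {
    if (is.null(dose_sequence)) {
      dose_sequence <- c(0.5, 1.0, 0.25, 0.125, 0.0625, 0.03125, 0)
    }
    if (length(dose_sequence) < 1 || any(dose_sequence < 0)) {
      stop_param("`dose_sequence` must be a nonempty vector of doses >= 0")
    }
    trial_s <- rep_len(trial_s, length(dose_sequence))
  } else {
    check_scalar_num(unit_dose_mg_kg, "unit_dose_mg_kg", min = 0)
  }
  structure(
    list(kind = kind, unit_dose_mg_kg = unit_dose_mg_kg,
         dose_sequence = dose_sequence, trial_s = trial_s,
         session_s = session_s, timeout_s = timeout_s, cue_s = cue_s,
         cap = as.integer(cap), intertrial_s = intertrial_s,
         pr_a = pr_a, pr_b = pr_b),
    class = "schedule_spec")
}

#' Behavioral agent parameters for session simulation
#'
#' A deliberately simple stochastic responder used to exercise schedule
#' analytics: active-port responses arrive as a Poisson process (or at exact
#' regular intervals when `deterministic = TRUE`), inactive-port responses as
#' an independent Poisson process, each infusion imposes a satiety pause
#' proportional to the unit dose, and under PR the agent abandons responding
#' before each new requirement N with probability 1 - (1 - h)^N where h is
#' the per-required-poke quit hazard.
#'
#' @param base_rate_hz active-port response rate, pokes/s.
#' @param inactive_rate_hz inactive-port response rate, pokes/s.
#' @param post_infusion_pause_s pause per mg/kg of delivered dose, s/(mg/kg).
#' @param quit_hazard_per_required_poke PR persistence parameter in [0, 1).
#' @param deterministic if `TRUE`, active pokes occur exactly every
#'   `1/base_rate_hz` seconds.
#' @param seed integer seed.
#' @return list of class `agent_params`.
#' @export
agent_params <- function(base_rate_hz = 0.1,
                         inactive_rate_hz = 0.01,
                         post_infusion_pause_s = 40,
                         quit_hazard_per_required_poke = 0,
                         deterministic = FALSE,
                         seed = 1L) {
  check_scalar_num(base_rate_hz, "base_rate_hz", min = 0)
  check_scalar_num(inactive_rate_hz, "inactive_rate_hz", min = 0)
  check_scalar_num(post_infusion_pause_s, "post_infusion_pause_s", min = 0)
  check_scalar_num(quit_hazard_per_required_poke,
                   "quit_hazard_per_required_poke", min = 0, max = 1,
                   strict_max = TRUE)
  structure(
    list(base_rate_hz = base_rate_hz, inactive_rate_hz = inactive_rate_hz,
         post_infusion_pause_s = post_infusion_pause_s,
         quit_hazard_per_required_poke = quit_hazard_per_required_poke,
         deterministic = isTRUE(deterministic), seed = as.integer(seed)),
    class = "agent_params")
}

EVENT_LEVELS <- c("TRIAL_START", "ACTIVE_POKE", "INACTIVE_POKE",
                  "INFUSION_START", "CUE_ON", "TIMEOUT_START",
                  "INFUSION_END", "CUE_OFF", "TIMEOUT_END")

#' Construct an operant event log
#'
#' @param events data.frame with columns `time_s`, `event`, `dose_mg_kg`,
#'   `trial_id`.
#' @param schedule the [schedule_spec()] the log was recorded under.
#' @param session_end_s effective session end (cap truncation respected).
#' @return data.frame of class `operant_log` with the schedule attached as an
#'   attribute.
#' @export
operant_log <- function(events, schedule, session_end_s = schedule$session_s) {
  required <- c("time_s", "event", "dose_mg_kg", "trial_id")
  miss <- setdiff(required, names(events))
  if (length(miss)) {
    stop_param("event log is missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- !events$event %in% EVENT_LEVELS
  if (any(bad)) {
    stop_param("unknown event type(s) at row(s) ",
               paste(utils::head(which(bad), 5), collapse = ", "))
  }
  if (nrow(events) > 1 && any(diff(events$time_s) < 0)) {
    stop_param("event times must be nondecreasing (first offending row ",
               which(diff(events$time_s) < 0)[1] + 1, ")")
  }
  no_dose <- events$event == "INFUSION_START" & !is.finite(events$dose_mg_kg)
  if (any(no_dose)) {
    stop_param("INFUSION_START without a dose at row(s) ",
               paste(utils::head(which(no_dose), 5), collapse = ", "))
  }
  structure(events, schedule = schedule, session_end_s = session_end_s,
            class = c("operant_log", "data.frame"))
}

log_schedule <- function(log) attr(log, "schedule")
log_session_end <- function(log) attr(log, "session_end_s")

#' Validate schedule legality of an event log
#'
#' Checks the invariants any log recorded under these schedules must obey:
#' no two infusions closer than the timeout, and the reinforcer count never
#' exceeding the session cap.
#'
#' @param log an [operant_log()].
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_log <- function(log) {
  sched <- log_schedule(log)
  inf <- log$time_s[log$event == "INFUSION_START"]
  if (sched$kind == "MULTIDOSE") {
    # the overdose cap applies within each dose trial
    per_trial <- table(log$trial_id[log$event == "INFUSION_START"])
    if (any(per_trial > sched$cap)) {
      stop_param("a dose trial has more infusions than the cap of ", sched$cap)
    }
  } else if (length(inf) > sched$cap) {
    stop_param("log has ", length(inf), " infusions, above the cap of ",
               sched$cap)
  }
  if (length(inf) > 1 && any(diff(inf) < sched$timeout_s - 1e-9)) {
    stop_param("two infusions are closer than the ", sched$timeout_s,
               " s timeout")
  }
  invisible(TRUE)
}
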