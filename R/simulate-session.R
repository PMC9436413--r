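# Growable event recorder used by the session simulator.
new_recorder <- function(init = 1024L) {
  env <- new.env(parent = emptyenv())
  env$time <- numeric(init); env$event <- character(init)
  env$dose <- numeric(init); env$trial <- integer(init)
  env$n <- 0L
  env
}

rec_add <- function(env, time, event, dose = NA_real_, trial = NA_integer_) {
  n <- env$n + 1L
  if (n > length(env$time)) {
    grow <- length(env$time) * 2L
    length(env$time) <- grow; length(env$event) <- grow
    length(env$dose) <- grow; length(env$trial) <- grow
  }
  env$time[n] <- time; env$event[n] <- event
  env$dose[n] <- dose; env$trial[n] <- trial
  env$n <- n
  invisible(env)
}

rec_collect <- function(env) {
  i <- seq_len(env$n)
  data.frame(time_s = env$time[i], event = env$event[i],
             dose_mg_kg = env$dose[i], trial_id = env$trial[i],
             stringsAsFactors = FALSE)
}

#' Simulate an operant self-administration session
#'
#' Replays an [agent_params()] responder through a [schedule_spec()] with the
#' full schedule semantics: FR1 reinforcement of every active poke outside a
#' timeout, the 5 s cue and 10 s timeout both starting at the reinforced poke
#' (a single 10 s lockout), dose-proportional infusion durations, the 64-
#' reinforcer session cap with early termination, MULTIDOSE trial structure
#' with intertrial timeouts (pokes during an intertrial period are counted
#' but never reinforced), and PR requirement escalation with quit hazard.
#'
#' @param agent an [agent_params()] object.
#' @param schedule a [schedule_spec()] object.
#' @return an [operant_log()]; the schedule and effective session end are
#'   attached as attributes.
#' @export
gen_session <- function(agent, schedule) {
  if (!inherits(agent, "agent_params")) {
    stop_param("`agent` must come from agent_params()")
  }
  if (!inherits(schedule, "schedule_spec")) {
    stop_param("`schedule` must come from schedule_spec()")
  }
  s <- schedule
  with_seed(agent$seed, {
    if (s$kind == "MULTIDOSE") {
      k <- length(s$dose_sequence)
      starts <- cumsum(c(0, utils::head(s$trial_s, -1) + s$intertrial_s))
      trials <- data.frame(trial_id = seq_len(k), dose = s$dose_sequence,
                           start = starts, end = starts + s$trial_s)
      session_s <- max(trials$end)
    } else {
      trials <- data.frame(trial_id = 1L, dose = s$unit_dose_mg_kg,
                           start = 0, end = s$session_s)
      session_s <- s$session_s
    }

    rec <- new_recorder()
    for (i in seq_len(nrow(trials))) {
      rec_add(rec, trials$start[i], "TRIAL_START", trials$dose[i],
              trials$trial_id[i])
    }

    t <- 0
    timeout_until <- -Inf
    pause_until <- 0
    n_inf <- 0L
    trial_inf <- integer(nrow(trials))
    pr_n <- 1L
    pr_prog <- 0L
    pr_req <- pr_requirement(1L, s$pr_a, s$pr_b)
    quit <- FALSE
    capped_at <- NA_real_

    if (agent$base_rate_hz > 0) {
      repeat {
        dt <- if (agent$deterministic) 1 / agent$base_rate_hz else
          stats::rexp(1, agent$base_rate_hz)
        t <- max(t, pause_until) + dt
        if (t > session_s || quit) break
        tr <- which(trials$start <= t & t < trials$end)
        in_trial <- length(tr) == 1L
        trial_id <- if (in_trial) trials$trial_id[tr] else NA_integer_
        dose <- if (in_trial) trials$dose[tr] else NA_real_
        rec_add(rec, t, "ACTIVE_POKE", dose, trial_id)
        if (!in_trial) next             # intertrial: counted, no consequence
        if (t < timeout_until) next     # timeout: counted, no consequence
        if (s$kind == "MULTIDOSE" && trial_inf[tr] >= s$cap) next
        if (s$kind == "PR") {
          pr_prog <- pr_prog + 1L
          if (pr_prog < pr_req) next
          pr_prog <- 0L
        }
        # reinforcement
        n_inf <- n_inf + 1L
        trial_inf[tr] <- trial_inf[tr] + 1L
        dur <- infusion_duration(dose)
        rec_add(rec, t, "INFUSION_START", dose, trial_id)
        rec_add(rec, t + dur, "INFUSION_END", dose, trial_id)
        rec_add(rec, t, "CUE_ON", dose, trial_id)
        rec_add(rec, t + s$cue_s, "CUE_OFF", dose, trial_id)
        rec_add(rec, t, "TIMEOUT_START", dose, trial_id)
        rec_add(rec, t + s$timeout_s, "TIMEOUT_END", dose, trial_id)
        timeout_until <- t + s$timeout_s
        pause_until <- t + agent$post_infusion_pause_s * dose
        if (s$kind == "PR") {
          pr_n <- pr_n + 1L
          pr_req <- pr_requirement(pr_n, s$pr_a, s$pr_b)
          h <- agent$quit_hazard_per_required_poke
          if (h > 0 && stats::runif(1) < 1 - (1 - h)^pr_req) quit <- TRUE
        }
        # overdose cap: ends FR1/PR sessions early; in MULTIDOSE it locks out
        # the remainder of the current dose trial only
        if (s$kind != "MULTIDOSE" && n_inf >= s$cap) { capped_at <- t; break }
      }
    }

    session_end <- if (is.na(capped_at)) session_s else
      capped_at + s$timeout_s
    if (agent$inactive_rate_hz > 0) {
      ti <- 0
      repeat {
        ti <- ti + stats::rexp(1, agent$inactive_rate_hz)
        if (ti > session_end) break
        rec_add(rec, ti, "INACTIVE_POKE")
      }
    }

    ev <- rec_collect(rec)
    ev <- ev[ev$time_s <= session_end + max(s$timeout_s, s$cue_s), ]
    prio <- match(ev$event, EVENT_LEVELS)
    ev <- ev[order(ev$time_s, prio), ]
    rownames(ev) <- NULL
    operant_log(ev, s, session_end_s = session_end)
  })
}
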