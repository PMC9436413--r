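# Independent oracles and small constructors shared across test files.

# Naive O(n*w) re-implementation of the rolling-window onset rule: for every
# sample, recompute the trailing-window mean/sd with mean()/sd() directly.
naive_detect_onsets <- function(ztrace, window_s = 0.5, k = 3,
                                refractory_s = 0.5) {
  fs <- ztrace$sample_rate_hz
  w <- as.integer(round(window_s * fs))
  onsets <- numeric(0)
  last <- -Inf
  for (b in sort(unique(ztrace$block[!is.na(ztrace$block)]))) {
    idx <- which(ztrace$block == b)
    zb <- ztrace$z[idx]
    tb <- ztrace$time_s[idx]
    nb <- length(zb)
    if (nb <= w) next
    for (i in (w + 1):nb) {
      win <- zb[(i - w):(i - 1)]
      if (zb[i] > mean(win) + k * sd(win)) {
        if (tb[i] - last < refractory_s) next
        onsets <- c(onsets, tb[i])
        last <- tb[i]
      }
    }
  }
  onsets
}

make_z_trace <- function(z, fs = 120, block = rep(1L, length(z))) {
  structure(list(time_s = (seq_along(z) - 1) / fs, z = z,
                 mask = rep(TRUE, length(z)), block = block,
                 sample_rate_hz = fs),
            class = "z_trace")
}

make_dff_trace <- function(dff, fs = 120, block = rep(1L, length(dff))) {
  structure(list(time_s = (seq_along(dff) - 1) / fs, dff = dff,
                 mask = rep(TRUE, length(dff)), block = block,
                 fits = NULL, sample_rate_hz = fs),
            class = "dff_trace")
}

# Brute-force breakpoint: scan every infusion-free interval (between
# consecutive infusions and the terminal interval to session end) for the
# first one of at least gap_s, independently of pr_breakpoint's logic.
brute_breakpoint <- function(inf_times, session_s, gap_s = 3600,
                             a = 5, b = 0.18) {
  m <- length(inf_times)
  if (m == 0) return(0L)
  ends <- c(inf_times[-1], session_s)
  for (kk in seq_len(m)) {
    if (ends[kk] - inf_times[kk] >= gap_s) return(pr_requirement(kk, a, b))
  }
  pr_requirement(m, a, b)
}

# Wrap bare infusion times into a minimal PR operant log.
pr_log_from_times <- function(inf_times, session_s = 14400) {
  sched <- schedule_spec("PR", session_s = session_s)
  ev <- data.frame(time_s = inf_times,
                   event = rep("INFUSION_START", length(inf_times)),
                   dose_mg_kg = rep(0.5, length(inf_times)),
                   trial_id = rep(1L, length(inf_times)))
  operant_log(ev, sched, session_end_s = session_s)
}

# Replay a PR log and recover the completed response requirement for each
# infusion: active pokes outside timeouts accumulated between infusions.
replay_pr_requirements <- function(log) {
  s <- attr(log, "schedule")
  timeout_until <- -Inf
  prog <- 0L
  reqs <- integer(0)
  for (r in seq_len(nrow(log))) {
    ev <- log$event[r]
    if (ev == "ACTIVE_POKE") {
      if (log$time_s[r] < timeout_until) next
      prog <- prog + 1L
    } else if (ev == "INFUSION_START") {
      reqs <- c(reqs, prog)
      prog <- 0L
      timeout_until <- log$time_s[r] + s$timeout_s
    }
  }
  reqs
}
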