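#' Parameters for the evoked-release FSCV simulator
#'
#' Emulates the concentration-vs-time readout of fast-scan cyclic voltammetry
#' at a carbon-fiber microelectrode: one scan every 100 ms (10 Hz), a
#' stimulus-evoked dopamine transient that rises linearly over `rise_time_s`
#' to a known peak and then decays exponentially with time constant
#' `decay_tau_s` (the reuptake proxy tau), optionally as a 5-pulse 100 Hz
#' train whose per-pulse kernels superpose.
#'
#' @param duration_s trace length, seconds.
#' @param sample_rate_hz scan repetition rate (default 10, one scan / 100 ms).
#' @param stim_time_s stimulus time, seconds; must lie inside the recording.
#' @param peak_um evoked peak amplitude above baseline, micromolar.
#' @param decay_tau_s exponential decay time constant, seconds.
#' @param rise_time_s linear rise time from stimulus to peak, seconds.
#' @param baseline_um baseline dopamine concentration, micromolar.
#' @param noise_sd_um white measurement noise SD, micromolar.
#' @param n_pulses 1 (single pulse) or 5 (100 Hz train).
#' @param pulse_interval_s inter-pulse interval for trains (0.01 s = 100 Hz).
#' @param seed integer seed.
#' @return list of class `fscv_sim_params`.
#' @export
fscv_sim_params <- function(duration_s = 30,
                            sample_rate_hz = 10,
                            stim_time_s = 5,
                            peak_um = 1.0,
                            decay_tau_s = 0.6,
                            rise_time_s = 0.3,
                            baseline_um = 0,
                            noise_sd_um = 0.02,
                            n_pulses = 1,
                            pulse_interval_s = 0.01,
                            seed = 1L) {
  check_scalar_num(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_scalar_num(sample_rate_hz, "sample_rate_hz", min = 0, strict_min = TRUE)
  check_scalar_num(stim_time_s, "stim_time_s")
  if (stim_time_s < 0 || stim_time_s >= duration_s) {
    stop_param("`stim_time_s` must lie within the recording")
  }
  check_scalar_num(peak_um, "peak_um", min = 0)
  check_scalar_num(decay_tau_s, "decay_tau_s", min = 0, strict_min = TRUE)
  check_scalar_num(rise_time_s, "rise_time_s", min = 0, strict_min = TRUE)
  check_scalar_num(baseline_um, "baseline_um", min = 0)
  check_scalar_num(noise_sd_um, "noise_sd_um", min = 0)
  if (!n_pulses %in% c(1, 5)) stop_param("`n_pulses` must be 1 or 5")
  check_scalar_num(pulse_interval_s, "pulse_interval_s", min = 0, strict_min = TRUE)
  structure(
    list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
         stim_time_s = stim_time_s, peak_um = peak_um,
         decay_tau_s = decay_tau_s, rise_time_s = rise_time_s,
         baseline_um = baseline_um, noise_sd_um = noise_sd_um,
         n_pulses = as.integer(n_pulses), pulse_interval_s = pulse_interval_s,
         seed = as.integer(seed)),
    class = "fscv_sim_params")
}

#' Construct an FSCV time series
#'
#' @param time_s strictly increasing sample times, seconds.
#' @param value oxidation current (nA) or dopamine concentration (uM).
#' @param units `"CURRENT_NA"` or `"CONC_UM"`.
#' @param sample_rate_hz scan repetition rate.
#' @param stim_time_s stimulus time (may be `NA` for spontaneous traces).
#' @return list of class `fscv_trace`.
#' @export
fscv_trace <- function(time_s, value, units = c("CONC_UM", "CURRENT_NA"),
                       sample_rate_hz, stim_time_s = NA_real_) {
  units <- match.arg(units)
  if (length(time_s) != length(value)) {
    stop_param("time_s and value must have equal length")
  }
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    stop_param("time_s must be strictly increasing")
  }
  structure(list(time_s = as.numeric(time_s), value = as.numeric(value),
                 units = units, sample_rate_hz = sample_rate_hz,
                 stim_time_s = stim_time_s),
            class = "fscv_trace")
}

#' @export
print.fscv_trace <- function(x, ...) {
  cat(sprintf("<fscv_trace> %d samples @ %g Hz [%s], stim at %s s\n",
              length(x$time_s), x$sample_rate_hz, x$units,
              format(x$stim_time_s)))
  invisible(x)
}

# Single-pulse evoked kernel: linear rise over rise_time to `peak`, then
# exponential decay with constant tau. Zero before the pulse.
fscv_kernel <- function(dt, peak, tau, rise_time) {
  out <- numeric(length(dt))
  rising <- dt >= 0 & dt < rise_time
  falling <- dt >= rise_time
  out[rising] <- peak * dt[rising] / rise_time
  out[falling] <- peak * exp(-(dt[falling] - rise_time) / tau)
  out
}

#' Simulate an evoked FSCV dopamine transient
#'
#' @param params an [fscv_sim_params()] object.
#' @return list with `trace` (an [fscv_trace()] in uM) and `ground_truth`
#'   (planted peak, tau, pulse times, parameter echo, seed).
#' @export
gen_fscv <- function(params) {
  if (!inherits(params, "fscv_sim_params")) {
    stop_param("`params` must come from fscv_sim_params()")
  }
  p <- params
  with_seed(p$seed, {
    n <- floor(p$duration_s * p$sample_rate_hz)
    time_s <- (seq_len(n) - 1) / p$sample_rate_hz
    pulse_times <- p$stim_time_s + (seq_len(p$n_pulses) - 1) * p$pulse_interval_s
    value <- rep(p$baseline_um, n)
    for (tp in pulse_times) {
      value <- value + fscv_kernel(time_s - tp, p$peak_um,
                                   p$decay_tau_s, p$rise_time_s)
    }
    if (p$noise_sd_um > 0) {
      value <- value + stats::rnorm(n, 0, p$noise_sd_um)
    }
    trace <- fscv_trace(time_s, value, units = "CONC_UM",
                        sample_rate_hz = p$sample_rate_hz,
                        stim_time_s = p$stim_time_s)
    gt <- list(peak_um = p$peak_um, decay_tau_s = p$decay_tau_s,
               t_peak_s = p$stim_time_s + p$rise_time_s,
               pulse_times_s = pulse_times, params_echo = p, seed = p$seed)
    list(trace = trace, ground_truth = gt)
  })
}
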