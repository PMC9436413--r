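#' Parameters for the photometry simulator
#'
#' Describes a two-channel (sensor 465 nm, control 560 nm) fiber-photometry
#' recording: a shared photobleaching decay and shared smoothed motion
#' artifact, Poisson-timed dopamine transients added to the sensor channel
#' only, independent measurement noise per channel, and the acquisition duty
#' cycle (recording light cycled 5 min on / 1 min off to limit bleaching).
#'
#' The default sampling rate of 120 Hz corresponds to 12.0 ksps acquisition
#' decimated by a factor of 100, and channels are low-pass filtered at 6 Hz by
#' default (zero-phase Butterworth) to emulate the demodulated acquisition
#' output; set `lowpass_hz = NA` for unfiltered traces.
#'
#' Transient amplitude and kinetics for the dopamine sensor in vivo are not
#' well constrained; the defaults (5% dF/F peak, 0.1 s rise, 1 s decay time
#' constants) are placeholders of realistic order and are echoed in the
#' ground truth of every simulated trace.
#'
#' @param duration_s recording length, seconds.
#' @param sample_rate_hz samples per second (default 120).
#' @param baseline_f baseline fluorescence, arbitrary units.
#' @param bleach_tau_s photobleaching exponential time constant, seconds.
#' @param bleach_frac fraction of baseline fluorescence lost as t -> Inf, in [0, 1).
#' @param motion_sd standard deviation of the shared motion artifact,
#'   fluorescence units.
#' @param motion_smooth_s smoothing window for the motion artifact, seconds.
#' @param noise_sd_465,noise_sd_560 per-channel white measurement noise SD,
#'   fluorescence units (applied before the acquisition low-pass).
#' @param transient_rate_hz Poisson rate of dopamine transients per second of
#'   recorded (mask-on) time.
#' @param transient_amp transient peak amplitude in dF/F units.
#' @param rise_tau_s,decay_tau_s transient kernel rise and decay time
#'   constants, seconds; rise must be faster than decay.
#' @param control_gain scaling of the shared components (bleached baseline,
#'   motion) into the control channel.
#' @param duty_on_s,duty_off_s duty cycle: recording on / off durations,
#'   seconds (defaults 300/60, i.e. the 83% duty cycle).
#' @param lowpass_hz acquisition low-pass corner frequency, Hz; `NA` disables.
#' @param seed integer seed; identical seed gives bit-identical output.
#' @return a list of class `photometry_sim_params`.
#' @export
photometry_sim_params <- function(duration_s = 1200,
                                  sample_rate_hz = 120,
                                  baseline_f = 100,
                                  bleach_tau_s = 1800,
                                  bleach_frac = 0.3,
                                  motion_sd = 1.0,
                                  motion_smooth_s = 0.25,
                                  noise_sd_465 = 0.3,
                                  noise_sd_560 = 0.3,
                                  transient_rate_hz = 0.05,
                                  transient_amp = 0.05,
                                  rise_tau_s = 0.1,
                                  decay_tau_s = 1.0,
                                  control_gain = 0.5,
                                  duty_on_s = 300,
                                  duty_off_s = 60,
                                  lowpass_hz = 6,
                                  seed = 1L) {
  check_scalar_num(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_scalar_num(sample_rate_hz, "sample_rate_hz", min = 0, strict_min = TRUE)
  check_scalar_num(baseline_f, "baseline_f", min = 0, strict_min = TRUE)
  check_scalar_num(bleach_tau_s, "bleach_tau_s", min = 0, strict_min = TRUE)
  check_scalar_num(bleach_frac, "bleach_frac", min = 0, max = 1, strict_max = TRUE)
  check_scalar_num(motion_sd, "motion_sd", min = 0)
  check_scalar_num(noise_sd_465, "noise_sd_465", min = 0)
  check_scalar_num(noise_sd_560, "noise_sd_560", min = 0)
  check_scalar_num(transient_rate_hz, "transient_rate_hz", min = 0)
  check_scalar_num(transient_amp, "transient_amp", min = 0)
  check_scalar_num(rise_tau_s, "rise_tau_s", min = 0, strict_min = TRUE)
  check_scalar_num(decay_tau_s, "decay_tau_s", min = 0, strict_min = TRUE)
  if (rise_tau_s >= decay_tau_s) {
    stop_param("`rise_tau_s` must be smaller than `decay_tau_s`")
  }
  check_scalar_num(control_gain, "control_gain", min = 0, strict_min = TRUE)
  check_scalar_num(duty_on_s, "duty_on_s", min = 0, strict_min = TRUE)
  check_scalar_num(duty_off_s, "duty_off_s", min = 0)
  if (!is.na(lowpass_hz)) {
    check_scalar_num(lowpass_hz, "lowpass_hz", min = 0, strict_min = TRUE)
    if (lowpass_hz >= sample_rate_hz / 2) {
      stop_param("`lowpass_hz` must be below the Nyquist frequency")
    }
  }
  structure(
    list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
         baseline_f = baseline_f, bleach_tau_s = bleach_tau_s,
         bleach_frac = bleach_frac, motion_sd = motion_sd,
         motion_smooth_s = motion_smooth_s,
         noise_sd_465 = noise_sd_465, noise_sd_560 = noise_sd_560,
         transient_rate_hz = transient_rate_hz, transient_amp = transient_amp,
         rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
         control_gain = control_gain,
         duty_on_s = duty_on_s, duty_off_s = duty_off_s,
         lowpass_hz = lowpass_hz, seed = as.integer(seed)),
    class = "photometry_sim_params")
}

#' Construct a two-channel photometry trace
#'
#' @param time_s strictly increasing sample times, seconds.
#' @param f465 sensor-channel fluorescence (NA where the mask is off).
#' @param f560 control-channel fluorescence (NA where the mask is off).
#' @param mask logical recording indicator per sample.
#' @param sample_rate_hz nominal sampling rate.
#' @return list of class `photometry_trace`.
#' @export
photometry_trace <- function(time_s, f465, f560, mask, sample_rate_hz) {
  n <- length(time_s)
  if (length(f465) != n || length(f560) != n || length(mask) != n) {
    stop_param("time_s, f465, f560 and mask must have equal length")
  }
  if (n > 1 && any(diff(time_s) <= 0)) {
    stop_param("time_s must be strictly increasing")
  }
  structure(list(time_s = as.numeric(time_s), f465 = as.numeric(f465),
                 f560 = as.numeric(f560), mask = as.logical(mask),
                 sample_rate_hz = sample_rate_hz),
            class = "photometry_trace")
}

#' @export
print.photometry_trace <- function(x, ...) {
  cat(sprintf("<photometry_trace> %d samples @ %g Hz, %.1f s, %.1f%% mask-on\n",
              length(x$time_s), x$sample_rate_hz,
              diff(range(x$time_s)), 100 * mean(x$mask)))
  invisible(x)
}

# Unit-peak transient kernel: difference of exponentials normalised so that a
# planted amplitude equals the kernel's actual peak dF/F.
transient_kernel <- function(dt, rise_tau, decay_tau) {
  k <- (1 - exp(-dt / rise_tau)) * exp(-dt / decay_tau)
  t_star <- rise_tau * log(1 + decay_tau / rise_tau)
  k_peak <- (1 - exp(-t_star / rise_tau)) * exp(-t_star / decay_tau)
  k / k_peak
}

duty_mask <- function(time_s, on_s, off_s) {
  if (off_s <= 0) return(rep(TRUE, length(time_s)))
  (time_s %% (on_s + off_s)) < on_s
}

#' Simulate a dual-channel fiber-photometry recording
#'
#' Generates sensor (465 nm) and control (560 nm) channels that share an
#' exponential photobleaching trend and a smoothed motion artifact; dopamine
#' transients (unit-peak difference-of-exponential kernels, planted at
#' Poisson times during mask-on periods, scaled by the local bleached
#' baseline so the planted amplitude is in dF/F units) enter the sensor
#' channel only. Samples during duty-cycle off periods are retained on the
#' time grid with `NA` fluorescence and `mask = FALSE`.
#'
#' @param params a [photometry_sim_params()] object.
#' @return list with elements `trace` (a [photometry_trace()]) and
#'   `ground_truth` (event times/amplitudes, parameter echo, seed).
#' @export
gen_photometry <- function(params) {
  if (!inherits(params, "photometry_sim_params")) {
    stop_param("`params` must come from photometry_sim_params()")
  }
  p <- params
  with_seed(p$seed, {
    fs <- p$sample_rate_hz
    n <- floor(p$duration_s * fs)
    time_s <- (seq_len(n) - 1) / fs
    mask <- duty_mask(time_s, p$duty_on_s, p$duty_off_s)

    bleach <- (1 - p$bleach_frac) + p$bleach_frac * exp(-time_s / p$bleach_tau_s)
    shared <- p$baseline_f * bleach

    motion <- numeric(n)
    if (p$motion_sd > 0) {
      w <- max(1L, as.integer(round(p$motion_smooth_s * fs)))
      raw <- stats::rnorm(n)
      sm <- as.numeric(stats::filter(raw, rep(1 / w, w), sides = 2,
                                     circular = TRUE))
      motion <- sm / stats::sd(sm) * p$motion_sd
    }

    # Poisson transients over mask-on time only
    on_runs <- rle_runs(mask)
    on_runs <- on_runs[on_runs$value, , drop = FALSE]
    event_times <- numeric(0)
    if (p$transient_rate_hz > 0 && nrow(on_runs) > 0) {
      seg_start <- time_s[on_runs$start]
      seg_len <- (on_runs$end - on_runs$start + 1) / fs
      total_on <- sum(seg_len)
      n_ev <- stats::rpois(1, p$transient_rate_hz * total_on)
      if (n_ev > 0) {
        u <- sort(stats::runif(n_ev, 0, total_on))
        cum <- cumsum(seg_len)
        seg_of <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
        offset <- u - c(0, cum)[seg_of]
        event_times <- seg_start[seg_of] + offset
      }
    }
    event_amps <- rep(p$transient_amp, length(event_times))

    transients <- numeric(n)
    if (length(event_times) > 0) {
      horizon <- 8 * p$decay_tau_s
      for (j in seq_along(event_times)) {
        i0 <- ceiling(event_times[j] * fs) + 1
        i1 <- min(n, floor((event_times[j] + horizon) * fs) + 1)
        if (i0 > n || i1 < i0) next
        dt <- time_s[i0:i1] - event_times[j]
        transients[i0:i1] <- transients[i0:i1] +
          event_amps[j] * transient_kernel(dt, p$rise_tau_s, p$decay_tau_s)
      }
    }

    f465 <- shared * (1 + transients) + motion +
      stats::rnorm(n, 0, p$noise_sd_465)
    f560 <- p$control_gain * (shared + motion) +
      stats::rnorm(n, 0, p$noise_sd_560)

    if (!is.na(p$lowpass_hz)) {
      bf <- signal::butter(2, p$lowpass_hz / (fs / 2), type = "low")
      f465 <- signal::filtfilt(bf, f465)
      f560 <- signal::filtfilt(bf, f560)
    }

    f465[!mask] <- NA_real_
    f560[!mask] <- NA_real_

    trace <- photometry_trace(time_s, f465, f560, mask, fs)
    gt <- list(event_times_s = event_times, event_amps = event_amps,
               params_echo = p, seed = p$seed)
    list(trace = trace, ground_truth = gt)
  })
}

# Run-length encode a logical vector into (value, start, end) rows.
rle_runs <- function(x) {
  r <- rle(x)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1
  data.frame(value = r$values, start = start, end = end)
}
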