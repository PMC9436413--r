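#' Calibrate an FSCV electrode against dopamine standards
#'
#' Least-squares line through (concentration, current) standards recorded
#' after the experiment (electrodes are calibrated in the 0.1–2 uM dopamine
#' range). The fitted slope is the electrode sensitivity in nA/uM; a
#' non-positive slope indicates an electrode fault and is an error.
#'
#' @param standards data.frame with columns `concentration_um` and
#'   `current_na`; at least two distinct concentrations.
#' @return list of class `fscv_calibration`: `slope_na_per_um`,
#'   `intercept_na`, `r2`, `range_um`.
#' @export
calibrate_electrode <- function(standards) {
  req <- c("concentration_um", "current_na")
  if (!all(req %in% names(standards))) {
    stop_param("standards need columns concentration_um, current_na")
  }
  conc <- standards$concentration_um
  cur <- standards$current_na
  if (length(unique(conc)) < 2) {
    stop_param("calibration needs >= 2 distinct concentrations")
  }
  fit <- ols_fit(conc, cur)
  if (!is.finite(fit$slope) || fit$slope <= 0) {
    stop_param("fitted calibration slope is not positive (electrode fault?)")
  }
  structure(list(slope_na_per_um = fit$slope, intercept_na = fit$intercept,
                 r2 = fit$r2, range_um = range(conc)),
            class = "fscv_calibration")
}

#' @export
print.fscv_calibration <- function(x, ...) {
  cat(sprintf("<fscv_calibration> %.4g nA/uM, intercept %.4g nA, r2 %.4f, range %g-%g uM\n",
              x$slope_na_per_um, x$intercept_na, x$r2,
              x$range_um[1], x$range_um[2]))
  invisible(x)
}

#' Convert an FSCV current trace to dopamine concentration
#'
#' Inverts the calibration line per sample:
#' concentration = (current - intercept) / slope. Samples outside the
#' calibration range are flagged (attribute `out_of_range`), never clipped.
#'
#' @param trace an [fscv_trace()] in `CURRENT_NA` units.
#' @param cal an [calibrate_electrode()] result.
#' @return an [fscv_trace()] in `CONC_UM` units.
#' @export
to_concentration <- function(trace, cal) {
  if (!inherits(trace, "fscv_trace")) stop_param("`trace` must be an fscv_trace")
  if (trace$units != "CURRENT_NA") {
    stop_param("trace is in ", trace$units, "; expected CURRENT_NA")
  }
  conc <- (trace$value - cal$intercept_na) / cal$slope_na_per_um
  out <- fscv_trace(trace$time_s, conc, units = "CONC_UM",
                    sample_rate_hz = trace$sample_rate_hz,
                    stim_time_s = trace$stim_time_s)
  attr(out, "out_of_range") <- conc < cal$range_um[1] | conc > cal$range_um[2]
  out
}

#' Evoked peak amplitude above pre-stimulus baseline
#'
#' The baseline is the mean concentration over the 1 s preceding the
#' stimulus; the peak is the maximum concentration in the post-stimulus
#' search window, reported as amplitude above baseline together with its
#' time.
#'
#' @param trace an [fscv_trace()] in `CONC_UM` units.
#' @param stim_time_s stimulus time; defaults to the trace's own.
#' @param search_window_s length of the post-stimulus search window, seconds.
#' @param baseline_window_s pre-stimulus baseline window, seconds (default 1).
#' @return list: `peak_um` (above baseline), `t_peak_s`, `baseline_um`.
#' @export
peak_amplitude <- function(trace, stim_time_s = trace$stim_time_s,
                           search_window_s = 5, baseline_window_s = 1) {
  if (!inherits(trace, "fscv_trace")) stop_param("`trace` must be an fscv_trace")
  if (trace$units != "CONC_UM") {
    stop_param("trace is in ", trace$units, "; expected CONC_UM")
  }
  if (!is.finite(stim_time_s)) stop_param("stimulus time is not set")
  pre <- trace$value[trace$time_s >= stim_time_s - baseline_window_s &
                       trace$time_s < stim_time_s]
  if (!length(pre)) stop_param("no samples in the pre-stimulus baseline window")
  win <- which(trace$time_s > stim_time_s &
                 trace$time_s <= stim_time_s + search_window_s)
  if (!length(win)) stop_param("post-stimulus search window is empty")
  baseline <- mean(pre)
  j <- win[which.max(trace$value[win])]
  list(peak_um = trace$value[j] - baseline, t_peak_s = trace$time_s[j],
       baseline_um = baseline)
}

#' Fit the exponential decay constant tau of evoked dopamine
#'
#' Nonlinear least squares of the single-exponential reuptake model
#' \deqn{C(t) = baseline + A e^{-(t - t_{peak})/\tau}}
#' over the window from the peak to the first sample at or below
#' baseline + `fit_fraction` * A (default 10% of amplitude) or the trace end.
#' Start values: A from the observed peak, tau from the time to half-peak
#' divided by ln 2, baseline from the pre-stimulus mean. The decay constant
#' tau is the standard proxy for dopamine reuptake rate.
#'
#' @param trace an [fscv_trace()] in `CONC_UM` units.
#' @param t_peak_s peak time; defaults to the [peak_amplitude()] estimate.
#' @param fit_fraction fraction of amplitude at which the fit window stops
#'   (default 0.1).
#' @param baseline_window_s pre-stimulus baseline window, seconds.
#' @param mask_stim_artifact drop the samples within one scan of the
#'   stimulus before fitting (default `FALSE`).
#' @return list of class `decay_fit`: `tau_s`, `amplitude_um`, `baseline_um`,
#'   `t_peak_s`, `fit_window`, `r2`, `n`.
#' @export
fit_decay <- function(trace, t_peak_s = NULL, fit_fraction = 0.1,
                      baseline_window_s = 1, mask_stim_artifact = FALSE) {
  if (!inherits(trace, "fscv_trace")) stop_param("`trace` must be an fscv_trace")
  if (trace$units != "CONC_UM") {
    stop_param("trace is in ", trace$units, "; expected CONC_UM")
  }
  time_s <- trace$time_s
  value <- trace$value
  if (mask_stim_artifact && is.finite(trace$stim_time_s)) {
    keep <- abs(time_s - trace$stim_time_s) > 1 / trace$sample_rate_hz
    time_s <- time_s[keep]; value <- value[keep]
  }

  pk <- peak_amplitude(trace, baseline_window_s = baseline_window_s)
  if (is.null(t_peak_s)) t_peak_s <- pk$t_peak_s
  b0 <- pk$baseline_um
  a0 <- pk$peak_um

  pre <- value[time_s >= trace$stim_time_s - baseline_window_s &
                 time_s < trace$stim_time_s]
  noise_floor <- if (length(pre) > 1) 3 * stats::sd(pre) else 0
  if (a0 <= noise_floor || a0 <= 0) {
    stop_param("amplitude (", signif(a0, 3),
               " uM) is at or below the noise floor; degenerate fit")
  }

  after <- which(time_s >= t_peak_s)
  stop_level <- b0 + fit_fraction * a0
  below <- after[value[after] <= stop_level]
  end_i <- if (length(below)) below[1] else after[length(after)]
  win <- after[after <= end_i]
  if (length(win) < 5) stop_param("fit window has fewer than 5 samples")

  tw <- time_s[win]; vw <- value[win]
  half <- b0 + a0 / 2
  t_half <- tw[which(vw <= half)[1]]
  tau0 <- if (is.na(t_half) || t_half <= t_peak_s) {
    (tw[length(tw)] - t_peak_s) / 2
  } else {
    (t_half - t_peak_s) / log(2)
  }
  tau0 <- max(tau0, 1 / trace$sample_rate_hz)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      vw ~ b + A * exp(-(tw - t_peak_s) / tau),
      start = list(A = a0, tau = tau0, b = b0),
      lower = c(A = 0, tau = 1e-6, b = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop_param("decay fit did not converge: ",
                                   conditionMessage(e)))
  est <- stats::coef(fit)
  resid <- stats::resid(fit)
  ss_tot <- sum((vw - mean(vw))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  structure(list(tau_s = unname(est["tau"]), amplitude_um = unname(est["A"]),
                 baseline_um = unname(est["b"]), t_peak_s = t_peak_s,
                 fit_window = c(tw[1], tw[length(tw)]), r2 = r2,
                 n = length(win)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> tau %.4g s, amplitude %.4g uM, baseline %.4g uM, r2 %.4f (%d pts)\n",
              x$tau_s, x$amplitude_um, x$baseline_um, x$r2, x$n))
  invisible(x)
}
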