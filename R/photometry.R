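#' Split a photometry trace into contiguous recorded blocks
#'
#' The recording light is duty-cycled (5 min on / 1 min off by default), so a
#' session consists of disjoint recorded blocks. Blocks are maximal runs of
#' mask-on samples; a gap in the time grid larger than 1.5 sample intervals
#' also splits a block, so traces stored without their off samples are
#' segmented correctly.
#'
#' @param trace a [photometry_trace()].
#' @return data.frame with one row per block: `block_id`, `start`, `end`
#'   (sample indices into the trace), `n`, `t_start_s`, `t_end_s`.
#' @export
split_blocks <- function(trace) {
  if (!inherits(trace, "photometry_trace")) {
    stop_param("`trace` must be a photometry_trace")
  }
  if (!any(trace$mask)) stop_param("trace has no mask-on samples")
  runs <- rle_runs(trace$mask)
  runs <- runs[runs$value, , drop = FALSE]
  dt_med <- stats::median(diff(trace$time_s))
  out <- list()
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start[i]:runs$end[i]
    gaps <- which(diff(trace$time_s[idx]) > 1.5 * dt_med)
    cut <- c(0, gaps, length(idx))
    for (j in seq_len(length(cut) - 1)) {
      sub <- idx[(cut[j] + 1):cut[j + 1]]
      out[[length(out) + 1]] <- data.frame(
        start = sub[1], end = sub[length(sub)], n = length(sub))
    }
  }
  blocks <- do.call(rbind, out)
  blocks$block_id <- seq_len(nrow(blocks))
  blocks$t_start_s <- trace$time_s[blocks$start]
  blocks$t_end_s <- trace$time_s[blocks$end]
  blocks[, c("block_id", "start", "end", "n", "t_start_s", "t_end_s")]
}

# OLS of y on x in closed form; returns slope/intercept/r2.
ols_fit <- function(x, y) {
  vx <- stats::var(x)
  slope <- stats::cov(x, y) / vx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(slope = slope, intercept = intercept, r2 = r2)
}

#' Fit the control channel to the sensor channel over one block
#'
#' Ordinary least squares predicting the 465 nm sensor signal from the 560 nm
#' control signal; the fitted control is what gets subtracted from (and
#' divides) the sensor channel in [compute_dff()]. The "alignment" of the two
#' channels is this affine fit itself; no time-lag alignment is attempted.
#'
#' @param f465,f560 sensor and control samples over one block (>= 10 samples).
#' @param block_id block index, carried through for reporting.
#' @return data.frame row: `block_id`, `slope`, `intercept`, `r2`, `n`.
#' @export
fit_control <- function(f465, f560, block_id = 1L) {
  ok <- is.finite(f465) & is.finite(f560)
  f465 <- f465[ok]; f560 <- f560[ok]
  if (length(f465) < 10) {
    stop_param("block ", block_id, ": control fit needs >= 10 samples")
  }
  if (stats::var(f560) == 0) {
    stop_param("block ", block_id, ": control channel has zero variance")
  }
  fit <- ols_fit(f560, f465)
  data.frame(block_id = block_id, slope = fit$slope,
             intercept = fit$intercept, r2 = fit$r2, n = length(f465))
}

#' Compute dF/F from a two-channel trace
#'
#' For each recorded block (or once globally), the control channel is fitted
#' to the sensor channel by ordinary least squares, the fitted control is
#' subtracted from the sensor signal, and the difference is divided by the
#' fitted control:
#' \deqn{\Delta F/F = (F_{465} - \hat F_{560}) / \hat F_{560}.}
#' Per-block fitting is the default because photobleaching leaves each
#' duty-cycle block with its own baseline.
#'
#' @param trace a [photometry_trace()].
#' @param per_block fit each duty-cycle block independently (default `TRUE`)
#'   or once over the whole masked trace.
#' @return list of class `dff_trace`: `time_s`, `dff` (NA where mask off),
#'   `mask`, `block` (block id per sample), `fits` (one [fit_control()] row
#'   per block), `sample_rate_hz`.
#' @export
compute_dff <- function(trace, per_block = TRUE) {
  blocks <- split_blocks(trace)
  n <- length(trace$time_s)
  dff <- rep(NA_real_, n)
  block_of <- rep(NA_integer_, n)
  fits <- list()

  if (!per_block) {
    on_idx <- unlist(lapply(seq_len(nrow(blocks)),
                            function(i) blocks$start[i]:blocks$end[i]))
    gfit <- fit_control(trace$f465[on_idx], trace$f560[on_idx], block_id = 0L)
  }

  for (i in seq_len(nrow(blocks))) {
    idx <- blocks$start[i]:blocks$end[i]
    fit <- if (per_block) {
      fit_control(trace$f465[idx], trace$f560[idx], block_id = i)
    } else {
      transform(gfit, block_id = i)
    }
    fitted <- fit$intercept + fit$slope * trace$f560[idx]
    bad <- which(is.finite(fitted) & fitted <= 0)
    if (length(bad)) {
      stop_param("fitted control is non-positive at sample ", idx[bad[1]])
    }
    dff[idx] <- (trace$f465[idx] - fitted) / fitted
    block_of[idx] <- i
    fits[[i]] <- fit
  }
  structure(list(time_s = trace$time_s, dff = dff, mask = trace$mask,
                 block = block_of, fits = do.call(rbind, fits),
                 sample_rate_hz = trace$sample_rate_hz),
            class = "dff_trace")
}

#' Z-score a dF/F trace
#'
#' Standardizes dF/F against its own mean and standard deviation, computed
#' either per duty-cycle block (default; each block is its own reference
#' population) or globally over all masked samples.
#'
#' @param dff a `dff_trace` from [compute_dff()].
#' @param reference `"PER_BLOCK"` or `"GLOBAL"`.
#' @return list of class `z_trace` with elements `time_s`, `z`, `mask`,
#'   `block`, `sample_rate_hz`.
#' @export
zscore_dff <- function(dff, reference = c("PER_BLOCK", "GLOBAL")) {
  reference <- match.arg(reference)
  if (!inherits(dff, "dff_trace")) stop_param("`dff` must be a dff_trace")
  z <- rep(NA_real_, length(dff$dff))
  if (reference == "GLOBAL") {
    v <- dff$dff[dff$mask & is.finite(dff$dff)]
    if (length(v) < 2) stop_param("need >= 2 samples in the reference population")
    s <- stats::sd(v)
    if (s == 0) stop_param("dF/F has zero standard deviation")
    z <- (dff$dff - mean(v)) / s
  } else {
    for (b in unique(dff$block[!is.na(dff$block)])) {
      idx <- which(dff$block == b)
      v <- dff$dff[idx]
      if (length(v) < 2) stop_param("block ", b, ": need >= 2 samples")
      s <- stats::sd(v)
      if (s == 0) stop_param("block ", b, ": dF/F has zero standard deviation")
      z[idx] <- (v - mean(v)) / s
    }
  }
  structure(list(time_s = dff$time_s, z = z, mask = dff$mask,
                 block = dff$block, sample_rate_hz = dff$sample_rate_hz),
            class = "z_trace")
}

#' Transient detection parameters
#'
#' @param window_s length of the trailing reference window, seconds
#'   (default 0.5).
#' @param k threshold multiplier on the windowed SD (default 3).
#' @param refractory_s minimum spacing between detected onsets, seconds
#'   (default 0.5).
#' @return list of class `detection_params`.
#' @export
detection_params <- function(window_s = 0.5, k = 3, refractory_s = 0.5) {
  check_scalar_num(window_s, "window_s", min = 0, strict_min = TRUE)
  check_scalar_num(k, "k", min = 0, strict_min = TRUE)
  check_scalar_num(refractory_s, "refractory_s", min = 0)
  structure(list(window_s = window_s, k = k, refractory_s = refractory_s),
            class = "detection_params")
}

#' Detect dopamine transients with a rolling z-score threshold
#'
#' A sample is an event onset when its z value exceeds the mean plus `k`
#' times the standard deviation of the z scores over the immediately
#' preceding `window_s` seconds (default: mean + 3 SD over the prior 0.5 s).
#' The reference window must lie entirely within the same recorded block, so
#' no onset is ever emitted within `window_s` of a block start. After an
#' onset, the event peak is the z maximum from the onset until z first
#' returns below the reference-window mean (or the block ends), and no new
#' onset is emitted within `refractory_s` of the previous one.
#'
#' @param ztrace a `z_trace` from [zscore_dff()].
#' @param params a [detection_params()] object.
#' @return data.frame of class `transient_events`: `onset_time_s`,
#'   `peak_time_s`, `peak_z`, `block_id`, sorted by onset.
#' @export
detect_transients <- function(ztrace, params = detection_params()) {
  if (!inherits(ztrace, "z_trace")) stop_param("`ztrace` must be a z_trace")
  fs <- ztrace$sample_rate_hz
  w <- as.integer(round(params$window_s * fs))
  if (w < 2) stop_param("window_s * sample_rate must cover >= 2 samples")

  blocks <- sort(unique(ztrace$block[!is.na(ztrace$block)]))
  usable <- FALSE
  events <- list()
  last_onset <- -Inf
  for (b in blocks) {
    idx <- which(ztrace$block == b)
    zb <- ztrace$z[idx]
    tb <- ztrace$time_s[idx]
    nb <- length(zb)
    if (nb <= w) next
    usable <- TRUE

    # rolling mean/SD of the trailing w samples, centered for stability
    mu0 <- mean(zb)
    zc <- zb - mu0
    c1 <- cumsum(zc)
    c2 <- cumsum(zc * zc)
    i <- (w + 1):nb
    s1 <- c1[i - 1] - ifelse(i - w - 1 >= 1, c1[pmax(i - w - 1, 1)], 0)
    s2 <- c2[i - 1] - ifelse(i - w - 1 >= 1, c2[pmax(i - w - 1, 1)], 0)
    m <- s1 / w
    v <- pmax((s2 - s1^2 / w) / (w - 1), 0)
    thr <- m + params$k * sqrt(v)
    cand <- i[zc[i] > thr]

    for (ci in cand) {
      if (tb[ci] - last_onset < params$refractory_s) next
      win_mean <- mean(zb[(ci - w):(ci - 1)])
      # peak: max z until first return below the reference-window mean
      j <- ci
      while (j < nb && zb[j] >= win_mean) j <- j + 1
      span <- ci:j
      pk <- span[which.max(zb[span])]
      events[[length(events) + 1]] <- data.frame(
        onset_time_s = tb[ci], peak_time_s = tb[pk], peak_z = zb[pk],
        block_id = b)
      last_onset <- tb[ci]
    }
  }
  if (!usable) {
    stop_param("detection window (", params$window_s,
               " s) is longer than every recorded block")
  }
  out <- if (length(events)) do.call(rbind, events) else
    data.frame(onset_time_s = numeric(0), peak_time_s = numeric(0),
               peak_z = numeric(0), block_id = integer(0))
  out <- out[order(out$onset_time_s), ]
  rownames(out) <- NULL
  class(out) <- c("transient_events", "data.frame")
  out
}

#' Epoch specification
#'
#' @param start_s,end_s epoch bounds in seconds, `start_s < end_s`.
#' @param label epoch name.
#' @return list of class `epoch_spec`.
#' @export
epoch_spec <- function(start_s, end_s, label = "") {
  check_scalar_num(start_s, "start_s")
  check_scalar_num(end_s, "end_s")
  if (start_s >= end_s) stop_param("`start_s` must be before `end_s`")
  structure(list(start_s = start_s, end_s = end_s, label = label),
            class = "epoch_spec")
}

masked_minutes <- function(trace_like, epoch) {
  sel <- trace_like$mask & trace_like$time_s >= epoch$start_s &
    trace_like$time_s < epoch$end_s
  sum(sel) / trace_like$sample_rate_hz / 60
}

#' Transient frequency within an epoch
#'
#' Events per minute of *recorded* time: the denominator counts only
#' mask-on time within the epoch, so duty-cycle off periods never dilute the
#' rate.
#'
#' @param events a `transient_events` data.frame.
#' @param epoch an [epoch_spec()].
#' @param trace any trace-like object carrying `time_s`, `mask` and
#'   `sample_rate_hz` (the original trace, dff or z trace).
#' @return rate in events/min.
#' @export
transient_frequency <- function(events, epoch, trace) {
  mins <- masked_minutes(trace, epoch)
  if (mins <= 0) stop_param("epoch '", epoch$label,
                            "' contains no recorded time")
  n <- sum(events$onset_time_s >= epoch$start_s &
             events$onset_time_s < epoch$end_s)
  n / mins
}

#' Compare transient frequency between two epochs
#'
#' Typical use: a pre-injection baseline epoch against a post-injection
#' epoch. Returns both rates and their ratio; a zero baseline rate yields a
#' flagged undefined ratio rather than infinity.
#'
#' @param events a `transient_events` data.frame.
#' @param pre,post non-overlapping [epoch_spec()]s.
#' @param trace trace-like object used for the recorded-time denominators.
#' @return list: `rate_pre`, `rate_post` (events/min), `ratio`,
#'   `ratio_defined`.
#' @export
epoch_compare <- function(events, pre, post, trace) {
  if (pre$start_s < post$end_s && post$start_s < pre$end_s) {
    stop_param("pre and post epochs overlap")
  }
  rate_pre <- transient_frequency(events, pre, trace)
  rate_post <- transient_frequency(events, post, trace)
  if (rate_pre == 0) {
    list(rate_pre = rate_pre, rate_post = rate_post,
         ratio = NA_real_, ratio_defined = FALSE)
  } else {
    list(rate_pre = rate_pre, rate_post = rate_post,
         ratio = rate_post / rate_pre, ratio_defined = TRUE)
  }
}

#' Optional zero-phase low-pass filter for raw traces
#'
#' Acquisition systems typically low-pass the demodulated signal (6 Hz here);
#' this helper applies the same zero-phase Butterworth filter to a trace that
#' was stored unfiltered. It is not part of the default pipeline.
#'
#' @param trace a [photometry_trace()].
#' @param cutoff_hz corner frequency, Hz.
#' @return a filtered [photometry_trace()].
#' @export
lowpass_trace <- function(trace, cutoff_hz = 6) {
  bf <- signal::butter(2, cutoff_hz / (trace$sample_rate_hz / 2), type = "low")
  blocks <- split_blocks(trace)
  f465 <- trace$f465; f560 <- trace$f560
  for (i in seq_len(nrow(blocks))) {
    idx <- blocks$start[i]:blocks$end[i]
    f465[idx] <- signal::filtfilt(bf, trace$f465[idx])
    f560[idx] <- signal::filtfilt(bf, trace$f560[idx])
  }
  photometry_trace(trace$time_s, f465, f560, trace$mask, trace$sample_rate_hz)
}

#' Match detected events to ground-truth events
#'
#' Greedy one-to-one matching of detected onsets to planted event times
#' within a tolerance; used to score recall/precision of the detector against
#' simulator ground truth.
#'
#' @param detected_s detected onset times, seconds.
#' @param truth_s planted event times, seconds.
#' @param tol_s matching tolerance, seconds (default 0.5).
#' @return list: `n_matched`, `recall`, `precision`.
#' @export
match_events <- function(detected_s, truth_s, tol_s = 0.5) {
  used <- rep(FALSE, length(detected_s))
  n_matched <- 0L
  for (tt in truth_s) {
    d <- abs(detected_s - tt)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_s) {
      used[j] <- TRUE
      n_matched <- n_matched + 1L
    }
  }
  list(n_matched = n_matched,
       recall = if (length(truth_s)) n_matched / length(truth_s) else NA_real_,
       precision = if (length(detected_s)) n_matched / length(detected_s)
       else NA_real_)
}
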