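make_trace <- function(f465, f560, fs = 120, mask = rep(TRUE, length(f465))) {
  photometry_trace((seq_along(f465) - 1) / fs, f465, f560, mask, fs)
}

test_that("split_blocks partitions masked-on samples", {
  tr <- make_trace(rnorm(100) + 50, rnorm(100) + 25)
  b <- split_blocks(tr)
  expect_equal(nrow(b), 1)
  expect_equal(b$n, 100)

  mask <- rep(c(TRUE, FALSE), each = 50)
  tr2 <- make_trace(rnorm(100) + 50, rnorm(100) + 25, mask = mask)
  b2 <- split_blocks(tr2)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$end, 50)

  tr3 <- make_trace(rnorm(20), rnorm(20), mask = rep(FALSE, 20))
  expect_error(split_blocks(tr3), "no mask-on")
})

test_that("fit_control recovers an exact linear relation", {
  f560 <- seq(10, 20, length.out = 50)
  fit <- fit_control(2 * f560 + 1, f560)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_error(fit_control(rnorm(50), rep(5, 50)), "zero variance")
  expect_error(fit_control(rnorm(5), rnorm(5)), ">= 10 samples")
})

test_that("control-fit residual SD is bounded by the generator noise", {
  p <- photometry_sim_params(duration_s = 300, duty_off_s = 0,
                             transient_rate_hz = 0, control_gain = 1,
                             lowpass_hz = NA, seed = 11)
  sim <- gen_photometry(p)
  dff <- compute_dff(sim$trace)
  fit <- dff$fits[1, ]
  fitted <- fit$intercept + fit$slope * sim$trace$f560
  resid_sd <- sd(sim$trace$f465 - fitted)
  combined <- sqrt(p$noise_sd_465^2 + fit$slope^2 * p$noise_sd_560^2)
  expect_lte(resid_sd, 1.1 * combined)
})

test_that("exact affine channel relation nulls dF/F everywhere", {
  f560 <- 25 + 3 * sin(seq(0, 8 * pi, length.out = 2000)) +
    seq(0, 1, length.out = 2000)
  tr <- make_trace(2 * f560 + 1, f560)
  dff <- compute_dff(tr)
  expect_true(all(abs(dff$dff) < 1e-9))
  # shuffling the control channel destroys the nulling
  tr_shuf <- make_trace(2 * f560 + 1, sample(f560))
  dff_shuf <- compute_dff(tr_shuf)
  expect_gt(max(abs(dff_shuf$dff)), 1e-3)
  expect_lt(dff_shuf$fits$r2[1], dff$fits$r2[1])
})

test_that("a planted kernel's dF/F amplitude is recovered", {
  p <- photometry_sim_params(duration_s = 60, duty_off_s = 0,
                             transient_rate_hz = 0, noise_sd_465 = 0,
                             noise_sd_560 = 0, motion_sd = 0,
                             bleach_frac = 0.1, lowpass_hz = NA, seed = 1)
  sim <- gen_photometry(p)
  fs <- p$sample_rate_hz
  amp <- 0.08
  t_ev <- 30
  i0 <- round(t_ev * fs) + 1
  dt <- sim$trace$time_s[i0:length(sim$trace$time_s)] - t_ev
  kern <- (1 - exp(-dt / p$rise_tau_s)) * exp(-dt / p$decay_tau_s)
  kern <- kern / max(kern)
  f465 <- sim$trace$f465
  f465[i0:length(f465)] <- f465[i0:length(f465)] * (1 + amp * kern)
  tr <- photometry_trace(sim$trace$time_s, f465, sim$trace$f560,
                         sim$trace$mask, fs)
  dff <- compute_dff(tr)
  expect_lt(abs(max(dff$dff) - amp) / amp, 0.10)
})

test_that("non-positive fitted control is reported with the sample index", {
  f560 <- seq(-5, 5, length.out = 50)
  expect_error(compute_dff(make_trace(f560, f560)), "non-positive at sample")
})

test_that("z-scoring normalizes and matches hand computation", {
  dff <- make_dff_trace(c(0, 0, 1, 0, 0, 0, 0, 0))
  z <- zscore_dff(dff)
  expect_equal(mean(z$z), 0, tolerance = 1e-12)
  expect_equal(sd(z$z), 1, tolerance = 1e-12)
  v <- c(0, 0, 1, 0, 0, 0, 0, 0)
  expect_equal(z$z[3], (1 - mean(v)) / sd(v), tolerance = 1e-12)
  expect_error(zscore_dff(make_dff_trace(rep(2, 10))), "zero standard deviation")
})

test_that("global and per-block z references differ when blocks differ", {
  dff <- make_dff_trace(c(rnorm(200, 0, 1), rnorm(200, 0, 5)),
                        block = rep(1:2, each = 200))
  zg <- zscore_dff(dff, "GLOBAL")
  zb <- zscore_dff(dff, "PER_BLOCK")
  expect_equal(sd(zb$z[1:200]), 1, tolerance = 1e-9)
  expect_equal(sd(zb$z[201:400]), 1, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(zg$z, zb$z)))
})

test_that("constant z trace yields no events; window errors when too long", {
  z <- make_z_trace(rep(0, 500))
  expect_equal(nrow(detect_transients(z)), 0)
  z_short <- make_z_trace(rnorm(30))
  expect_error(detect_transients(z_short), "longer than every")
})

test_that("detection matches the naive windowed oracle on random traces", {
  set.seed(101)
  for (r in 1:10) {
    z <- make_z_trace(rnorm(5000) + 0.5 * sin(seq(0, 40, length.out = 5000)))
    ev <- detect_transients(z)
    expect_equal(ev$onset_time_s, naive_detect_onsets(z))
  }
})

test_that("no onset is emitted within the window of a block start", {
  set.seed(7)
  nb <- 600
  z <- make_z_trace(rnorm(3 * nb, 0, 1) + rep(c(0, 3, 0), each = nb),
                    block = rep(1:3, each = nb))
  ev <- detect_transients(z)
  blocks_start <- tapply(z$time_s, z$block, min)
  for (i in seq_len(nrow(ev))) {
    expect_gte(ev$onset_time_s[i] - blocks_start[[ev$block_id[i]]], 0.5)
  }
})

test_that("pure-noise onset rate decreases as k grows", {
  set.seed(33)
  z <- make_z_trace(rnorm(20000))
  counts <- sapply(c(2, 3, 4), function(k)
    nrow(detect_transients(z, detection_params(k = k))))
  expect_true(all(diff(counts) < 0))
})

test_that("planted transients are recalled at default simulation settings", {
  sim <- gen_photometry(photometry_sim_params(duration_s = 720, seed = 5))
  z <- zscore_dff(compute_dff(sim$trace))
  ev <- detect_transients(z)
  m <- match_events(ev$onset_time_s, sim$ground_truth$event_times_s, 0.5)
  expect_gte(m$recall, 0.9)
})

test_that("transient frequency uses recorded time as denominator", {
  ev <- data.frame(onset_time_s = c(10, 50, 100, 150, 250),
                   peak_time_s = c(10, 50, 100, 150, 250),
                   peak_z = rep(4, 5), block_id = 1L)
  # one 300 s on / 60 s off cycle at 1 Hz sampling
  tr <- list(time_s = 0:359, mask = c(rep(TRUE, 300), rep(FALSE, 60)),
             sample_rate_hz = 1)
  expect_equal(transient_frequency(ev, epoch_spec(0, 360), tr), 1.0)
  expect_equal(transient_frequency(
    data.frame(onset_time_s = numeric(0)), epoch_spec(0, 360), tr), 0)
  ev12 <- data.frame(onset_time_s = seq(1, 239, length.out = 12))
  tr_on <- list(time_s = 0:239, mask = rep(TRUE, 240), sample_rate_hz = 1)
  expect_equal(transient_frequency(ev12, epoch_spec(0, 240), tr_on), 3.0)
  expect_error(transient_frequency(ev, epoch_spec(300, 360), tr),
               "no recorded time")
})

test_that("epoch comparison flags overlap and zero baselines", {
  tr <- list(time_s = 0:999, mask = rep(TRUE, 1000), sample_rate_hz = 1)
  ev <- data.frame(onset_time_s = c(600, 700, 800))
  expect_error(epoch_compare(ev, epoch_spec(0, 500), epoch_spec(0, 500), tr),
               "overlap")
  res <- epoch_compare(ev, epoch_spec(0, 500), epoch_spec(500, 1000), tr)
  expect_false(res$ratio_defined)
  res2 <- epoch_compare(data.frame(onset_time_s = c(100, 200)),
                        epoch_spec(0, 500), epoch_spec(500, 1000), tr)
  expect_equal(res2$ratio, 0)
})

test_that("a doubled event rate is recovered by epoch comparison", {
  set.seed(9)
  tr <- list(time_s = seq(0, 4800, by = 0.5), mask = rep(TRUE, 9601),
             sample_rate_hz = 2)
  pre_ev <- cumsum(rexp(500, 0.05)); pre_ev <- pre_ev[pre_ev < 2400]
  post_ev <- 2400 + cumsum(rexp(500, 0.10)); post_ev <- post_ev[post_ev < 4800]
  ev <- data.frame(onset_time_s = c(pre_ev, post_ev))
  res <- epoch_compare(ev, epoch_spec(0, 2400), epoch_spec(2400, 4800), tr)
  expect_gt(res$ratio, 1.6)
  expect_lt(res$ratio, 2.4)
})
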