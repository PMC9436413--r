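test_that("PR requirements reproduce the published series", {
  expect_equal(pr_requirement(1), 1L)
  expect_equal(pr_requirement(11), 31L)
  expect_equal(pr_requirement(17), 102L)
  expect_equal(pr_series(17),
               c(1L, 2L, 4L, 5L, 7L, 10L, 13L, 16L, 20L, 25L, 31L, 38L,
                 47L, 57L, 69L, 84L, 102L))
  expect_equal(pr_series(1), 1L)
  expect_error(pr_requirement(0), ">= 1")
})

test_that("the PR series is nondecreasing and floored at one", {
  s <- pr_series(200)
  expect_true(all(diff(s) >= 0))
  expect_true(all(s >= 1))
})

test_that("infusion durations scale proportionally with dose", {
  expect_equal(infusion_duration(0.25), 1.77)
  expect_equal(infusion_duration(0.0625), 0.44)
  expect_equal(infusion_duration(c(1, 0.125, 0.03125, 0)),
               c(7.07, 0.88, 0.22, 0))
  expect_error(infusion_duration(-0.1), ">= 0")
})

test_that("breakpoint follows the first hour-long infusion-free interval", {
  expect_equal(pr_breakpoint(pr_log_from_times(numeric(0))), 0L)
  # requirements 1,1?,... here indices 1..4 completed, then a 2 h gap, then one more
  times <- c(100, 300, 700, 1500, 1500 + 7200)
  expect_equal(pr_breakpoint(pr_log_from_times(times, session_s = 14400)),
               pr_requirement(4))
  # evenly spaced to session end: last requirement stands
  times2 <- seq(100, 10000, by = 450)
  expect_equal(pr_breakpoint(pr_log_from_times(times2, session_s = 10800)),
               pr_requirement(length(times2)))
  fr1 <- gen_session(agent_params(base_rate_hz = 0), schedule_spec("FR1"))
  expect_error(pr_breakpoint(fr1), "PR session")
})

test_that("breakpoint agrees with a brute-force gap scan on random logs", {
  set.seed(17)
  for (r in 1:200) {
    m <- rpois(1, 6)
    times <- sort(runif(m, 0, 14400))
    times <- times[c(TRUE, diff(times) > 10)]
    expect_equal(pr_breakpoint(pr_log_from_times(times), gap_s = 1800),
                 brute_breakpoint(times, 14400, gap_s = 1800))
  }
})

test_that("session summaries count events and conserve intake", {
  empty <- gen_session(agent_params(base_rate_hz = 0, inactive_rate_hz = 0),
                       schedule_spec("FR1"))
  s0 <- summarize_session(empty)
  expect_equal(s0$active_pokes, 0)
  expect_equal(s0$infusions, 0)
  expect_equal(s0$intake_mg_kg, 0)

  sched <- schedule_spec("FR1", unit_dose_mg_kg = 0.5)
  ev <- data.frame(time_s = seq(10, 100, by = 10),
                   event = "INFUSION_START", dose_mg_kg = 0.5, trial_id = 1L)
  s1 <- summarize_session(operant_log(ev, sched))
  expect_equal(s1$infusions, 10)
  expect_equal(s1$intake_mg_kg, 5.0)

  sched_md <- schedule_spec("MULTIDOSE", dose_sequence = c(1.0, 0.25))
  ev2 <- data.frame(
    time_s = c(0, 10, 20, 1860, 1900, 1950, 2000, 2050),
    event = c("TRIAL_START", "INFUSION_START", "INFUSION_START",
              "TRIAL_START", "INFUSION_START", "INFUSION_START",
              "INFUSION_START", "INFUSION_START"),
    dose_mg_kg = c(1.0, 1.0, 1.0, 0.25, 0.25, 0.25, 0.25, 0.25),
    trial_id = c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L))
  s2 <- summarize_session(operant_log(ev2, sched_md))
  expect_equal(s2$infusions, 6)
  expect_equal(s2$intake_mg_kg, 2 * 1.0 + 4 * 0.25)
  expect_equal(s2$intake_mg_kg, sum(s2$per_dose$intake_mg_kg))
})

test_that("acquisition criteria are applied day by day", {
  good <- data.frame(infusions = rep(30, 10), active_pokes = rep(90, 10),
                     inactive_pokes = rep(30, 10))
  res <- acquisition_filter(good, acquisition_criteria("cocaine"))
  expect_true(res$acquired)
  expect_equal(res$acquisition_day, 3)

  none <- data.frame(infusions = rep(0, 10), active_pokes = rep(0, 10),
                     inactive_pokes = rep(5, 10))
  res0 <- acquisition_filter(none)
  expect_false(res0$acquired)
  expect_equal(res0$exclusion_reason, "min_infusions_or_ratio")

  # a low day inside the window postpones acquisition
  var_bad <- data.frame(infusions = c(40, 40, 20, 40, 40, 40),
                        active_pokes = rep(90, 6), inactive_pokes = rep(10, 6))
  resv <- acquisition_filter(var_bad)
  expect_equal(resv$acquisition_day, 6)

  # day pair above the 20% variability bound blocks acquisition on that day:
  # |40 - 28| / mean(40, 28) = 0.353 > 0.20
  var_pair <- data.frame(infusions = c(40, 40, 28, 28),
                         active_pokes = rep(90, 4), inactive_pokes = rep(10, 4))
  resp <- acquisition_filter(var_pair)
  expect_equal(resp$acquisition_day, 4)

  # zero inactive pokes with positive active pokes passes the ratio test
  inf_ratio <- data.frame(infusions = rep(30, 3), active_pokes = rep(50, 3),
                          inactive_pokes = rep(0, 3))
  expect_true(acquisition_filter(inf_ratio)$acquired)
})

test_that("sucrose criteria require the run to include the last day", {
  daily <- data.frame(infusions = c(35, 35, 35, 35, 10),
                      active_pokes = rep(90, 5), inactive_pokes = rep(10, 5))
  expect_false(acquisition_filter(daily, acquisition_criteria("sucrose"))$acquired)
  daily_ok <- data.frame(infusions = rep(35, 5), active_pokes = rep(90, 5),
                         inactive_pokes = rep(10, 5))
  res <- acquisition_filter(daily_ok, acquisition_criteria("sucrose"))
  expect_true(res$acquired)
  expect_equal(res$acquisition_day, 5)
})

test_that("raising infusions never revokes acquisition", {
  set.seed(31)
  for (r in 1:30) {
    daily <- data.frame(infusions = rpois(10, 28),
                        active_pokes = rpois(10, 80) + 1,
                        inactive_pokes = rpois(10, 20))
    before <- acquisition_filter(daily)$acquired
    daily$infusions <- daily$infusions + 10
    after <- acquisition_filter(daily)$acquired
    expect_false(before && !after)
  }
})

test_that("dose-response curves identify the maximal-responding dose", {
  sched <- schedule_spec("MULTIDOSE")
  doses <- sched$dose_sequence
  counts <- c(2, 5, 9, 12, 8, 4, 1)
  starts <- cumsum(c(0, rep(1860, 6)))
  rows <- list()
  for (i in seq_along(doses)) {
    rows[[length(rows) + 1]] <- data.frame(
      time_s = starts[i], event = "TRIAL_START", dose_mg_kg = doses[i],
      trial_id = i)
    if (counts[i] > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        time_s = starts[i] + seq_len(counts[i]) * 20,
        event = "INFUSION_START", dose_mg_kg = doses[i], trial_id = i)
    }
  }
  log <- operant_log(do.call(rbind, rows), sched)
  dr <- dose_response(log)
  expect_equal(dr$curve$infusions, counts)
  expect_equal(dr$max_dose_mg_kg, 0.125)
  expect_equal(dr$total_intake_mg_kg, sum(counts * doses))

  # zero responding: flagged undefined argmax
  empty_rows <- do.call(rbind, lapply(seq_along(doses), function(i)
    data.frame(time_s = starts[i], event = "TRIAL_START",
               dose_mg_kg = doses[i], trial_id = i)))
  dr0 <- dose_response(operant_log(empty_rows, sched))
  expect_false(dr0$max_defined)
  expect_true(all(dr0$curve$infusions == 0))
})

test_that("multidose stability combines infusion variation and dose drift", {
  mk <- function(counts) {
    sched <- schedule_spec("MULTIDOSE")
    doses <- sched$dose_sequence
    starts <- cumsum(c(0, rep(1860, 6)))
    rows <- list()
    for (i in seq_along(doses)) {
      rows[[length(rows) + 1]] <- data.frame(
        time_s = starts[i], event = "TRIAL_START", dose_mg_kg = doses[i],
        trial_id = i)
      if (counts[i] > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          time_s = starts[i] + seq_len(counts[i]) * 20,
          event = "INFUSION_START", dose_mg_kg = doses[i], trial_id = i)
      }
    }
    dose_response(operant_log(do.call(rbind, rows), sched))
  }
  a <- mk(c(2, 5, 9, 12, 8, 4, 1))
  expect_true(multidose_stable(a, a)$stable)

  # totals 50 vs 80: variation 30/65 = 0.462 -> unstable
  b <- mk(c(5, 10, 15, 20, 15, 10, 5))   # 80 total, max at 0.125
  c50 <- mk(c(4, 7, 10, 12, 9, 6, 2))    # 50 total, max at 0.125
  res <- multidose_stable(b, c50)
  expect_false(res$stable)
  expect_equal(res$infusion_variation, 30 / 65, tolerance = 1e-12)

  # max dose drift 0.125 -> 0.25 is log10(2) = 0.301 <= 0.5: passes dose rule
  d <- mk(c(2, 5, 12, 9, 8, 4, 1))       # max at 0.25
  res2 <- multidose_stable(a, d)
  expect_lte(res2$dose_drift_log10, 0.5)
  expect_equal(res2$dose_drift_log10, log10(2), tolerance = 1e-12)

  e0 <- mk(rep(0, 7))
  expect_false(multidose_stable(a, e0)$defined)
})

test_that("inter-infusion interval statistics are computed directly", {
  log <- pr_log_from_times(c(0, 10, 20, 120))
  # PR log reuse is fine: interval_stats only reads INFUSION_START times
  st <- interval_stats(log, gap_threshold_s = 50)
  iv <- c(10, 10, 100)
  expect_equal(st$intervals_s, iv)
  expect_equal(st$mean_s, 40)
  expect_equal(st$cv, sd(iv) / mean(iv), tolerance = 1e-12)
  expect_equal(st$gaps_s, 100)
  expect_true(st$defined)

  one <- interval_stats(pr_log_from_times(5))
  expect_false(one$defined)
  expect_length(one$intervals_s, 0)

  # perfectly periodic infusions have zero CV
  per <- interval_stats(pr_log_from_times(seq(0, 1000, by = 50)))
  expect_equal(per$cv, 0)
})
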