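#!/usr/bin/env Rscript
# Operant schedule analytics on the simulated sessions: session summaries,
# PR breakpoint, dose-response curve from the multidose session, infusion
# patterning, and an acquisition-criteria demonstration on a simulated
# 10-day training history.
# Run analysis/01_simulate.R first.

suppressPackageStartupMessages(library(dopaflow))

fr1 <- read_event_log("results/data/session_fr1.csv")
md <- read_event_log("results/data/session_multidose.csv")
pr <- read_event_log("results/data/session_pr.csv")

s_fr1 <- summarize_session(fr1)
cat(sprintf("FR1: %d active, %d inactive pokes, %d infusions, intake %.1f mg/kg\n",
            s_fr1$active_pokes, s_fr1$inactive_pokes, s_fr1$infusions,
            s_fr1$intake_mg_kg))
iv <- interval_stats(fr1)
if (iv$defined) {
  cat(sprintf("FR1 inter-infusion intervals: mean %.0f s, CV %.2f, %d gaps > 10 min\n",
              iv$mean_s, iv$cv, length(iv$gaps_s)))
}

s_pr <- summarize_session(pr)
cat(sprintf("PR: %d infusions, breakpoint %d\n", s_pr$infusions,
            s_pr$breakpoint))
cat("PR requirement series (first 17):", pr_series(17), "\n")

dr <- dose_response(md)
cat("multidose dose-response:\n")
print(dr$curve, digits = 3, row.names = FALSE)
cat(sprintf("maximal responding at %.4g mg/kg; total intake %.2f mg/kg\n",
            dr$max_dose_mg_kg, dr$total_intake_mg_kg))
cat("infusion durations for the dose series:",
    infusion_duration(dr$curve$dose_mg_kg), "s\n")

# Acquisition filter on a simulated 10-day FR1 training history
set.seed(11)
histories <- lapply(1:10, function(day) {
  ag <- agent_params(base_rate_hz = 0.02 + 0.012 * day,
                     inactive_rate_hz = 0.01, post_infusion_pause_s = 40,
                     seed = 100 + day)
  summarize_session(gen_session(ag, schedule_spec("FR1")))
})
daily <- data.frame(
  infusions = vapply(histories, `[[`, numeric(1), "infusions"),
  active_pokes = vapply(histories, `[[`, numeric(1), "active_pokes"),
  inactive_pokes = vapply(histories, `[[`, numeric(1), "inactive_pokes"))
acq <- acquisition_filter(daily, acquisition_criteria("cocaine"))
cat("training history (infusions/day):", daily$infusions, "\n")
cat(sprintf("acquired: %s (day %s)\n", acq$acquired,
            format(acq$acquisition_day)))

dir.create("results", showWarnings = FALSE)
utils::write.csv(dr$curve, "results/dose_response.csv", row.names = FALSE)
write_results_json(
  list(fr1 = s_fr1[c("active_pokes", "inactive_pokes", "infusions",
                     "intake_mg_kg")],
       pr = list(infusions = s_pr$infusions, breakpoint = s_pr$breakpoint),
       multidose = list(max_dose_mg_kg = dr$max_dose_mg_kg,
                        total_intake_mg_kg = dr$total_intake_mg_kg),
       acquisition = acq),
  "results/behavior_summary.json")
cat("wrote results/dose_response.csv and results/behavior_summary.json\n")
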