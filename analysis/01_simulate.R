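#!/usr/bin/env Rscript
# Generate the synthetic datasets used by the downstream analysis scripts:
# one duty-cycled photometry recording with planted dopamine transients, a
# grid of evoked FSCV transients with known kinetics, and one operant
# session per schedule (FR1, MULTIDOSE, PR). All outputs land in
# results/data/ as the package's CSV dialects; ground truth goes to JSON.

suppressPackageStartupMessages(library(dopaflow))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260928

# Photometry: 24 min recording, 5 min on / 1 min off, ~0.05 transients/s
phot <- gen_photometry(photometry_sim_params(duration_s = 1440, seed = seed))
write_photometry_csv(phot$trace, file.path(out, "photometry_trace.csv"))
write_results_json(
  list(event_times_s = phot$ground_truth$event_times_s,
       event_amps = phot$ground_truth$event_amps, seed = seed),
  file.path(out, "photometry_ground_truth.json"))
cat(sprintf("photometry: %d samples, %d planted transients over %.0f s on-time\n",
            length(phot$trace$time_s),
            length(phot$ground_truth$event_times_s),
            sum(phot$trace$mask) / phot$trace$sample_rate_hz))

# FSCV: evoked transients at three reuptake time constants, 20 seeds each
taus <- c(0.3, 0.6, 1.2)
for (tau in taus) {
  sim <- gen_fscv(fscv_sim_params(decay_tau_s = tau, seed = seed))
  write_fscv_csv(sim$trace,
                 file.path(out, sprintf("fscv_tau%03.0fms.csv", 1000 * tau)))
}
cat("fscv: wrote evoked transients for tau =",
    paste(taus, collapse = ", "), "s\n")

# Operant sessions: one per schedule
sessions <- list(
  fr1 = list(agent_params(base_rate_hz = 0.08, inactive_rate_hz = 0.01,
                          post_infusion_pause_s = 40, seed = seed),
             schedule_spec("FR1")),
  multidose = list(agent_params(base_rate_hz = 0.15, inactive_rate_hz = 0.01,
                                post_infusion_pause_s = 120, seed = seed),
                   schedule_spec("MULTIDOSE")),
  pr = list(agent_params(base_rate_hz = 0.5, inactive_rate_hz = 0.01,
                         post_infusion_pause_s = 20,
                         quit_hazard_per_required_poke = 0.01, seed = seed),
            schedule_spec("PR")))
for (nm in names(sessions)) {
  log <- gen_session(sessions[[nm]][[1]], sessions[[nm]][[2]])
  validate_log(log)
  write_event_log(log, file.path(out, sprintf("session_%s.csv", nm)))
  cat(sprintf("session %s: %d active pokes, %d infusions\n", nm,
              sum(log$event == "ACTIVE_POKE"),
              sum(log$event == "INFUSION_START")))
}
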