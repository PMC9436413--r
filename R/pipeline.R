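#' Pipeline run configuration
#'
#' One place for every tunable of the simulate-and-analyze pipeline, with the
#' study's constants as defaults: detection window 0.5 s and threshold
#' multiplier 3, timeout 10 s, reinforcer cap 64, PR constants a = 5 and
#' b = 0.18, duty cycle 300 s on / 60 s off. Unknown keys are rejected.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param photometry list of overrides for [photometry_sim_params()].
#' @param fscv list of overrides for [fscv_sim_params()].
#' @param agent list of overrides for [agent_params()].
#' @param schedule list of overrides for [schedule_spec()].
#' @param detection list of overrides for [detection_params()].
#' @param fit_fraction decay-fit stop fraction for [fit_decay()].
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, photometry = list(), fscv = list(),
                       agent = list(), schedule = list(),
                       detection = list(), fit_fraction = 0.1) {
  check_override <- function(given, builder, name) {
    allowed <- names(formals(builder))
    unknown <- setdiff(names(given), allowed)
    if (length(unknown)) {
      stop_param("unknown ", name, " key(s): ", paste(unknown, collapse = ", "))
    }
    given
  }
  structure(
    list(seed = as.integer(seed),
         photometry = check_override(photometry, photometry_sim_params,
                                     "photometry"),
         fscv = check_override(fscv, fscv_sim_params, "fscv"),
         agent = check_override(agent, agent_params, "agent"),
         schedule = check_override(schedule, schedule_spec, "schedule"),
         detection = check_override(detection, detection_params, "detection"),
         fit_fraction = fit_fraction),
    class = "run_config")
}

derive_seed <- function(seed, k) (as.integer(seed) * 1009L + k * 101L) %% 1000000L

#' Run the full simulate-and-analyze pipeline
#'
#' Simulates one photometry recording, one evoked FSCV transient and one
#' operant session from a [run_config()], runs each through its analysis
#' stage (dF/F + transient detection and epoch rates; peak + decay fit;
#' session summary), writes traces/logs as CSV and results plus a manifest
#' as JSON under `out_dir`, and returns the result bundle. Deterministic for
#' a given (config, seed) apart from the manifest timestamp.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return list with `photometry`, `fscv`, `behavior` result lists and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) {
    stop_param("`config` must come from run_config()")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_param("[", name, "] ", conditionMessage(e))
    })
  }

  # photometry
  phot <- stage("photometry", {
    p <- do.call(photometry_sim_params,
                 c(config$photometry,
                   list(seed = derive_seed(config$seed, 1L))))
    sim <- gen_photometry(p)
    dff <- compute_dff(sim$trace)
    z <- zscore_dff(dff)
    det <- do.call(detection_params, config$detection)
    events <- detect_transients(z, det)
    half <- p$duration_s / 2
    rates <- epoch_compare(events,
                           epoch_spec(0, half, "first_half"),
                           epoch_spec(half, p$duration_s, "second_half"),
                           sim$trace)
    write_photometry_csv(sim$trace, file.path(out_dir, "photometry_trace.csv"))
    utils::write.csv(events, file.path(out_dir, "photometry_events.csv"),
                     row.names = FALSE)
    list(trace = sim$trace, ground_truth = sim$ground_truth,
         events = events, rates = rates,
         n_events = nrow(events), n_planted = length(sim$ground_truth$event_times_s))
  })

  # fscv
  fscv_res <- stage("fscv", {
    p <- do.call(fscv_sim_params,
                 c(config$fscv, list(seed = derive_seed(config$seed, 2L))))
    sim <- gen_fscv(p)
    pk <- peak_amplitude(sim$trace)
    fit <- fit_decay(sim$trace, fit_fraction = config$fit_fraction)
    write_fscv_csv(sim$trace, file.path(out_dir, "fscv_trace.csv"))
    list(trace = sim$trace, ground_truth = sim$ground_truth,
         peak = pk, decay = fit)
  })

  # behavior
  beh <- stage("behavior", {
    ag <- do.call(agent_params,
                  c(config$agent, list(seed = derive_seed(config$seed, 3L))))
    sch <- do.call(schedule_spec, config$schedule)
    log <- gen_session(ag, sch)
    validate_log(log)
    summ <- summarize_session(log)
    write_event_log(log, file.path(out_dir, "session_log.csv"))
    list(log = log, summary = summ)
  })

  manifest <- list(
    package = "dopaflow",
    version = as.character(utils::packageVersion("dopaflow")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = config[setdiff(names(config), "seed")],
    results = list(
      photometry = list(n_detected = phot$n_events,
                        n_planted = phot$n_planted,
                        rate_pre = phot$rates$rate_pre,
                        rate_post = phot$rates$rate_post),
      fscv = list(peak_um = fscv_res$peak$peak_um,
                  tau_s = fscv_res$decay$tau_s),
      behavior = list(infusions = beh$summary$infusions,
                      intake_mg_kg = beh$summary$intake_mg_kg,
                      active_pokes = beh$summary$active_pokes)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  write_results_json(manifest, file.path(out_dir, "manifest.json"))
  list(photometry = phot, fscv = fscv_res, behavior = beh,
       manifest = manifest)
}
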