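# Shared fixtures and cached heavy runs.
#
# Cohort-level experiments simulate at 120-s sampling (2-min actigraphy
# epochs) so a 48-h record block-averages to 72 model timesteps; the study
# cohort is 44 patients with 21 deaths, the composition of the final
# analysis set.

study_sim_params <- function(seed, null = FALSE, interval_s = 120) {
  mk <- if (null) null_sim_params else cohort_sim_params
  mk(n_patients = 44L, p_death = 21 / 44, sampling_interval_s = interval_s,
     seed = as.integer(seed))
}

# One full pipeline run (final preset) per seed; returns the report rows.
study_run <- function(seed, null = FALSE, horizons = c(24, 48)) {
  cfg <- run_config(simulator = study_sim_params(seed, null = null),
                    preset = "final", horizons = horizons,
                    seed = 1000L + as.integer(seed))
  suppressWarnings(suppressMessages(run_experiment(cfg)))$report
}

.heavy_cache <- new.env(parent = emptyenv())

# Paired-horizon AUCs over ten seeds, computed once per test session.
study_auc_table <- function(null = FALSE) {
  key <- if (null) "null" else "default"
  if (is.null(.heavy_cache[[key]])) {
    horizons <- if (null) 48 else c(24, 48)
    rows <- lapply(1:10, function(s) {
      rep <- study_run(s, null = null, horizons = horizons)
      data.frame(seed = s,
                 auc24 = if (null) NA_real_ else
                   rep$auc[rep$horizon_h == 24],
                 auc48 = rep$auc[rep$horizon_h == 48])
    })
    .heavy_cache[[key]] <- do.call(rbind, rows)
  }
  .heavy_cache[[key]]
}

# Small, fast pipeline configuration for plumbing tests.
tiny_run_cfg <- function(preset = "preliminary", seed = 5L, n = 12L,
                         horizons = c(24, 48), output_dir = NULL) {
  sim <- cohort_sim_params(n_patients = n, p_death = 0.5,
                           sampling_interval_s = 600,
                           stay_days_range = c(3L, 4L), seed = seed)
  run_config(simulator = sim, preset = preset, horizons = horizons,
             seed = seed, output_dir = output_dir)
}

# Constant-signal series built directly, bypassing the simulator.
constant_series <- function(value, n, interval_s = 1, id = "T001",
                            worn = rep(TRUE, n)) {
  act <- rep(value, n)
  act[!worn] <- NA_real_
  ns <- asNamespace("actisurv")
  ns$new_actigraphy_series(
    patient_id = id,
    start_time = as.POSIXct("2020-03-01 08:00:00", tz = "UTC"),
    interval_s = interval_s, activity = act, angle = act, spin = act,
    worn = worn)
}

# Scores reproducing the printed KPS two-by-two table: 23 deaths below the
# cutoff, 5 deaths at/above, 5 stable below, 26 stable at/above.
table1_kps_cohort <- function() {
  kps <- c(rep(30, 12), rep(40, 11), rep(50, 5),        # deaths
           rep(40, 5), rep(50, 10), rep(60, 8), rep(70, 8))  # stable
  outcome <- c(rep(1L, 28), rep(0L, 31))
  ids <- sprintf("K%02d", seq_along(kps))
  list(kps = stats::setNames(kps, ids),
       outcome = stats::setNames(outcome, ids))
}

# Scores reproducing the printed PPI two-by-two table (n = 20).
table1_ppi_cohort <- function() {
  ppi <- c(rep(8.5, 8), 5.0,                      # deaths: 8 above, 1 below
           rep(3.5, 11))                          # stable: all at/below
  outcome <- c(rep(1L, 9), rep(0L, 11))
  ids <- sprintf("Q%02d", seq_along(ppi))
  list(ppi = stats::setNames(ppi, ids),
       outcome = stats::setNames(outcome, ids))
}

# Separable four-sequence toy set: constant-high vs constant-low activity.
toy_separable_set <- function(T = 50L) {
  x <- array(0, c(4, T, 3))
  x[1, , ] <- 1; x[2, , ] <- 0.05; x[3, , ] <- 0.9; x[4, , ] <- 0.1
  list(x = x, y = c(1L, 0L, 1L, 0L))
}
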