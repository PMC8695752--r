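#' @useDynLib actisurv, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rpois qbeta t.test sd acf binom.test
#' @importFrom utils write.csv read.csv
NULL

# Frailty -> multiplicative activity scaling; decreasing in frailty,
# centred so the pooled cohort is scaled by ~1.
frailty_gain <- function(f, centre = 2.15, slope = 0.25) {
  exp(-slope * (f - centre))
}

round_to_step <- function(x, step) step * round(x / step)

#' Simulate one patient's actigraphy record and clinical metadata
#'
#' Generates a three-channel (activity, angle, spin) wrist-actigraphy series
#' over the patient's hospital stay together with the clinical side of the
#' record (outcome, KPS, PPI, stay length). The generating model is a
#' cosinor rest--activity rhythm whose level and amplitude are scaled by a
#' latent frailty shared with the clinical scores:
#'
#' \deqn{activity(t) = \max(0,\; g(f)\,(M + A \cos(2\pi (t - \phi)/24h)) + e_t)}
#'
#' with `M`, `A` the outcome group's mesor and amplitude, `phi` the
#' acrophase, `e_t` AR(1) noise, `f ~ Normal(mu_group, 1)` and `g`
#' decreasing in `f`. Angle and spin are noisy transforms of activity.
#' KPS is `100 - 25 f` plus noise, rounded to steps of 10 and clamped to
#' `[0, 100]`; PPI is `1 + 2.2 f` plus noise, clamped to `[0, 15]`.
#' Device-removal episodes arrive as a Poisson process; samples inside an
#' episode have `worn = FALSE` and `NA` in all three channels, so that
#' imputation policy is a preprocessing decision, not a simulation one.
#'
#' @param params a [cohort_sim_params()] object.
#' @param outcome 1 for death, 0 for discharge in stable condition.
#' @param patient_id identifier string.
#' @param stay_days optional stay length in days; drawn from
#'   `params$stay_days_range` when `NULL`.
#' @param start_time admission timestamp (`POSIXct`).
#'
#' The caller controls randomness with `set.seed()`; [simulate_cohort()]
#' seeds from `params$seed`.
#'
#' @return list with elements `series` (class `actigraphy_series`) and
#'   `meta` (one-row data frame: `patient_id`, `outcome`, `kps`, `ppi`,
#'   `stay_days`).
#' @export
simulate_patient <- function(params, outcome, patient_id = "P001",
                             stay_days = NULL,
                             start_time = as.POSIXct("2020-03-01 08:00:00",
                                                     tz = "UTC")) {
  stopifnot(inherits(params, "cohort_sim_params"))
  if (!outcome %in% c(0, 1))
    stop("outcome must be 0 (stable) or 1 (death)", call. = FALSE)
  grp <- if (outcome == 1) 1L else 2L   # (death, stable) ordering

  if (is.null(stay_days)) {
    rng <- params$stay_days_range
    stay_days <- if (rng[1] == rng[2]) rng[1] else
      sample(seq(rng[1], rng[2]), 1L)
  }

  f <- rnorm(1L, params$frailty_mu_by_group[grp], 1)
  gain <- frailty_gain(f)

  dt <- params$sampling_interval_s
  n <- as.integer(round(stay_days * 86400 / dt))
  t_s <- (seq_len(n) - 1L) * dt
  hour <- (as.numeric(start_time) %% 86400 + t_s) / 3600  # clock hours

  mesor <- params$mesor_by_group[grp]
  amp <- params$amplitude_by_group[grp]
  rhythm <- gain * (mesor + amp * cos(2 * pi * (hour - params$acrophase_h) / 24))

  if (params$noise_sd > 0) {
    innov_sd <- params$noise_sd * sqrt(1 - params$ar1_coef^2)
    e <- as.numeric(stats::filter(rnorm(n, 0, innov_sd), params$ar1_coef,
                                  method = "recursive"))
  } else {
    e <- numeric(n)
  }
  activity <- pmax(0, rhythm + e)

  angle <- -20 + 30 * tanh(activity) + rnorm(n, 0, 5)
  spin <- pmax(0, 2 * activity + rnorm(n, 0, 0.3))

  worn <- rep(TRUE, n)
  n_events <- if (params$offwrist_rate_per_day > 0)
    rpois(1L, params$offwrist_rate_per_day * stay_days) else 0L
  if (n_events > 0L) {
    starts <- runif(n_events, 0, stay_days * 86400)
    durs <- runif(n_events, params$offwrist_duration_minutes[1],
                  params$offwrist_duration_minutes[2]) * 60
    for (k in seq_len(n_events)) {
      idx <- which(t_s >= starts[k] & t_s < starts[k] + durs[k])
      worn[idx] <- FALSE
    }
    activity[!worn] <- NA_real_
    angle[!worn] <- NA_real_
    spin[!worn] <- NA_real_
  }

  kps <- round_to_step(100 - 25 * f + rnorm(1L, 0, params$kps_noise_sd), 10)
  kps <- min(100, max(0, kps))
  if (params$kps_missing_rate > 0 && runif(1L) < params$kps_missing_rate)
    kps <- NA_real_
  ppi <- min(15, max(0, 1 + 2.2 * f + rnorm(1L, 0, params$ppi_noise_sd)))

  series <- new_actigraphy_series(
    patient_id = patient_id, start_time = start_time, interval_s = dt,
    activity = activity, angle = angle, spin = spin, worn = worn)
  meta <- data.frame(patient_id = patient_id, outcome = as.integer(outcome),
                     kps = kps, ppi = ppi, stay_days = as.integer(stay_days),
                     stringsAsFactors = FALSE)
  list(series = series, meta = meta)
}

new_actigraphy_series <- function(patient_id, start_time, interval_s,
                                  activity, angle, spin, worn) {
  n <- length(activity)
  stopifnot(length(angle) == n, length(spin) == n, length(worn) == n)
  if (any(activity[worn] < 0, na.rm = TRUE))
    stop("activity must be nonnegative wherever worn", call. = FALSE)
  structure(
    list(patient_id = patient_id, start_time = start_time,
         interval_s = interval_s, activity = activity, angle = angle,
         spin = spin, worn = worn),
    class = "actigraphy_series")
}

#' @export
print.actigraphy_series <- function(x, ...) {
  n <- length(x$activity)
  cat(sprintf(
    "Actigraphy series %s: %d samples @ %g s (%.1f h), %.1f%% worn\n",
    x$patient_id, n, x$interval_s, n * x$interval_s / 3600,
    100 * mean(x$worn)))
  invisible(x)
}

#' Length of an actigraphy series in samples
#' @param x an `actigraphy_series`.
#' @export
length.actigraphy_series <- function(x) length(x$activity)

#' Simulate a full cohort
#'
#' Produces `n_patients` records with a deterministic outcome composition:
#' exactly `round(n_patients * p_death)` deaths. All randomness is governed
#' by `params$seed`; two calls with identical parameters give identical
#' cohorts. PPI is assessed only for the last
#' `ceil(ppi_assessed_fraction * n)` patients recruited, mirroring a score
#' adopted partway through a study; the others get `NA`.
#'
#' @param params a [cohort_sim_params()] object.
#' @param signals if `FALSE`, skip generation of the actigraphy signals and
#'   return only clinical metadata (fast path for score-level Monte Carlo).
#' @return list with elements `patients` (list of `actigraphy_series`, or
#'   `NULL` when `signals = FALSE`) and `meta` (data frame, one row per
#'   patient).
#' @export
simulate_cohort <- function(params, signals = TRUE) {
  stopifnot(inherits(params, "cohort_sim_params"))
  n <- params$n_patients
  if (n < 2L) stop("n_patients must be >= 2", call. = FALSE)
  n_death <- as.integer(round(n * params$p_death))
  if (n_death == 0L || n_death == n)
    warning("cohort has a single outcome class", call. = FALSE)
  outcomes <- c(rep(1L, n_death), rep(0L, n - n_death))
  ids <- sprintf("P%03d", seq_len(n))

  set.seed(params$seed)
  # shuffle recruitment order so outcome is not confounded with the
  # PPI-assessment window (the tail of the recruitment sequence)
  outcomes <- sample(outcomes)

  patients <- if (signals) vector("list", n) else NULL
  metas <- vector("list", n)
  day0 <- as.POSIXct("2020-03-01 08:00:00", tz = "UTC")
  for (i in seq_len(n)) {
    if (signals) {
      rec <- simulate_patient(params, outcomes[i], patient_id = ids[i],
                              start_time = day0 + (i - 1L) * 86400)
      patients[[i]] <- rec$series
      metas[[i]] <- rec$meta
    } else {
      metas[[i]] <- simulate_meta_only(params, outcomes[i], ids[i])
    }
  }
  meta <- do.call(rbind, metas)

  n_ppi <- as.integer(ceiling(params$ppi_assessed_fraction * n))
  if (n_ppi < n) meta$ppi[seq_len(n - n_ppi)] <- NA_real_

  list(patients = patients, meta = meta)
}

# Clinical scores only, on the same frailty model as simulate_patient.
simulate_meta_only <- function(params, outcome, patient_id) {
  grp <- if (outcome == 1) 1L else 2L
  f <- rnorm(1L, params$frailty_mu_by_group[grp], 1)
  kps <- round_to_step(100 - 25 * f + rnorm(1L, 0, params$kps_noise_sd), 10)
  kps <- min(100, max(0, kps))
  if (params$kps_missing_rate > 0 && runif(1L) < params$kps_missing_rate)
    kps <- NA_real_
  ppi <- min(15, max(0, 1 + 2.2 * f + rnorm(1L, 0, params$ppi_noise_sd)))
  rng <- params$stay_days_range
  stay <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1L)
  data.frame(patient_id = patient_id, outcome = as.integer(outcome),
             kps = kps, ppi = ppi, stay_days = as.integer(stay),
             stringsAsFactors = FALSE)
}

#' Write a cohort to per-patient CSV files plus a cohort table
#'
#' Each patient is written as `<patient_id>.csv` with header
#' `timestamp,activity,angle,spin,worn` (ISO-8601 timestamps, `worn` coded
#' 0/1, off-wrist channel values empty), and the metadata as `cohort.csv`
#' with header `patient_id,outcome,kps,ppi,stay_days` (missing scores as
#' empty fields).
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in cohort$patients) {
    ts <- s$start_time + (seq_along(s$activity) - 1L) * s$interval_s
    df <- data.frame(
      timestamp = format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      activity = s$activity, angle = s$angle, spin = s$spin,
      worn = as.integer(s$worn))
    p <- file.path(dir, paste0(s$patient_id, ".csv"))
    write.csv(df, p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  p <- file.path(dir, "cohort.csv")
  write.csv(cohort$meta, p, row.names = FALSE, na = "")
  invisible(c(paths, p))
}

#' Read a patient CSV written by [write_cohort_csv()]
#' @param path path to `<patient_id>.csv`.
#' @param patient_id id to attach; defaults to the file name.
#' @return an `actigraphy_series`.
#' @export
read_patient_csv <- function(path, patient_id = NULL) {
  if (is.null(patient_id))
    patient_id <- sub("\\.csv$", "", basename(path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  interval <- if (nrow(df) > 1L) as.numeric(difftime(ts[2], ts[1],
                                                     units = "secs")) else 1
  new_actigraphy_series(patient_id = patient_id, start_time = ts[1],
                        interval_s = interval, activity = df$activity,
                        angle = df$angle, spin = df$spin,
                        worn = df$worn == 1L)
}

#' Read a cohort metadata table
#' @param path path to `cohort.csv`.
#' @return data frame with columns `patient_id,outcome,kps,ppi,stay_days`.
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(patient_id = "character"))
  df
}
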