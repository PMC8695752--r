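#' Simulation parameters for a synthetic actigraphy cohort
#'
#' Bundles every knob of the synthetic-cohort generator: cohort composition,
#' circadian signal structure per outcome group, noise, device-removal
#' (off-wrist) behaviour, and the coupling of the clinical scores (KPS, PPI)
#' to the latent frailty that also drives the activity signal.
#'
#' The two outcome groups share a cosinor (mesor + amplitude + acrophase)
#' rest--activity model; the death group's mesor and amplitude default to
#' 0.5x and 0.3x the stable group's, encoding the qualitative contrast of a
#' dying patient's flattened, damped rest--activity rhythm. A per-patient
#' latent frailty f ~ Normal(mu_group, 1) scales the signal multiplicatively
#' (higher frailty, lower activity) and generates KPS and PPI, so that
#' score-based and signal-based prediction are consistent by construction.
#'
#' @param n_patients cohort size (default 60).
#' @param p_death probability of the death outcome; the realised number of
#'   deaths is `round(n_patients * p_death)` (deterministic composition, not
#'   Bernoulli sampling). Default 28/60.
#' @param sampling_interval_s sampling interval of the device in seconds
#'   (default 1, i.e. 1 Hz).
#' @param stay_days_range integer `(min, max)` length of hospital stay in
#'   days; each patient's stay is drawn uniformly from this range.
#' @param mesor_by_group circadian mesor (mean activity level, arbitrary
#'   device units) as `c(death, stable)`.
#' @param amplitude_by_group circadian amplitude as `c(death, stable)`.
#' @param acrophase_h clock hour in `[0, 24)` of peak activity.
#' @param ar1_coef lag-one autocorrelation of the additive activity noise.
#' @param noise_sd stationary standard deviation of the activity noise.
#' @param offwrist_rate_per_day expected number of device-removal episodes
#'   per day (Poisson process).
#' @param offwrist_duration_minutes `(min, max)` duration in minutes of one
#'   removal episode (uniform).
#' @param kps_noise_sd sd of the noise added to the KPS generating formula
#'   (on the 0--100 scale, before rounding to steps of 10).
#' @param ppi_noise_sd sd of the noise added to the PPI generating formula.
#' @param frailty_mu_by_group mean of the latent frailty as
#'   `c(death, stable)`; the within-group sd is fixed at 1.
#' @param ppi_assessed_fraction fraction of the cohort (the last patients
#'   recruited) with a PPI assessment; mirrors a score introduced partway
#'   through recruitment. Default 1/3.
#' @param kps_missing_rate probability that a patient's KPS is missing.
#' @param seed integer seed controlling all simulation randomness.
#'
#' @return an object of class `cohort_sim_params` (a validated list).
#' @seealso [simulate_cohort()], [simulate_patient()], [null_sim_params()]
#' @export
cohort_sim_params <- function(n_patients = 60L,
                              p_death = 28 / 60,
                              sampling_interval_s = 1,
                              stay_days_range = c(3L, 18L),
                              mesor_by_group = c(death = 0.5, stable = 1.0),
                              amplitude_by_group = c(death = 0.09, stable = 0.3),
                              acrophase_h = 14,
                              ar1_coef = 0.6,
                              noise_sd = 0.25,
                              offwrist_rate_per_day = 1.5,
                              offwrist_duration_minutes = c(10, 40),
                              kps_noise_sd = 5,
                              ppi_noise_sd = 1,
                              frailty_mu_by_group = c(death = 3.1, stable = 1.2),
                              ppi_assessed_fraction = 1 / 3,
                              kps_missing_rate = 0,
                              seed = 1L) {
  p <- list(
    n_patients = as.integer(n_patients),
    p_death = p_death,
    sampling_interval_s = sampling_interval_s,
    stay_days_range = as.integer(stay_days_range),
    mesor_by_group = unname(mesor_by_group),
    amplitude_by_group = unname(amplitude_by_group),
    acrophase_h = acrophase_h,
    ar1_coef = ar1_coef,
    noise_sd = noise_sd,
    offwrist_rate_per_day = offwrist_rate_per_day,
    offwrist_duration_minutes = offwrist_duration_minutes,
    kps_noise_sd = kps_noise_sd,
    ppi_noise_sd = ppi_noise_sd,
    frailty_mu_by_group = unname(frailty_mu_by_group),
    ppi_assessed_fraction = ppi_assessed_fraction,
    kps_missing_rate = kps_missing_rate,
    seed = as.integer(seed)
  )
  class(p) <- "cohort_sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  fail <- function(field, msg) {
    stop(sprintf("invalid CohortSimParams field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (is.na(p$n_patients) || p$n_patients < 1L)
    fail("n_patients", "must be a positive integer")
  if (p$p_death < 0 || p$p_death > 1)
    fail("p_death", "must lie in [0, 1]")
  if (p$sampling_interval_s <= 0)
    fail("sampling_interval_s", "must be positive")
  if (length(p$stay_days_range) != 2L || p$stay_days_range[1] < 1L ||
      p$stay_days_range[2] < p$stay_days_range[1])
    fail("stay_days_range", "must be (min, max) with min >= 1")
  if (length(p$mesor_by_group) != 2L || any(p$mesor_by_group < 0))
    fail("mesor_by_group", "must be a nonnegative (death, stable) pair")
  if (p$mesor_by_group[1] > p$mesor_by_group[2])
    fail("mesor_by_group", "death-group mesor must not exceed stable-group mesor")
  if (length(p$amplitude_by_group) != 2L || any(p$amplitude_by_group < 0))
    fail("amplitude_by_group", "must be a nonnegative (death, stable) pair")
  if (p$amplitude_by_group[1] > p$amplitude_by_group[2])
    fail("amplitude_by_group",
         "death-group amplitude must not exceed stable-group amplitude")
  if (p$acrophase_h < 0 || p$acrophase_h >= 24)
    fail("acrophase_h", "must lie in [0, 24)")
  if (p$ar1_coef < 0 || p$ar1_coef >= 1)
    fail("ar1_coef", "must lie in [0, 1)")
  if (p$noise_sd < 0) fail("noise_sd", "must be nonnegative")
  if (p$offwrist_rate_per_day < 0)
    fail("offwrist_rate_per_day", "must be nonnegative")
  if (length(p$offwrist_duration_minutes) != 2L ||
      any(p$offwrist_duration_minutes < 0) ||
      p$offwrist_duration_minutes[2] < p$offwrist_duration_minutes[1])
    fail("offwrist_duration_minutes", "must be (min, max), both nonnegative")
  if (p$kps_noise_sd < 0) fail("kps_noise_sd", "must be nonnegative")
  if (p$ppi_noise_sd < 0) fail("ppi_noise_sd", "must be nonnegative")
  if (length(p$frailty_mu_by_group) != 2L)
    fail("frailty_mu_by_group", "must be a (death, stable) pair")
  if (p$frailty_mu_by_group[1] < p$frailty_mu_by_group[2])
    fail("frailty_mu_by_group",
         "death-group frailty mean must be >= stable-group mean")
  if (p$ppi_assessed_fraction < 0 || p$ppi_assessed_fraction > 1)
    fail("ppi_assessed_fraction", "must lie in [0, 1]")
  if (p$kps_missing_rate < 0 || p$kps_missing_rate > 1)
    fail("kps_missing_rate", "must lie in [0, 1]")
  invisible(p)
}

#' Parameters for a null cohort with no outcome-group signal
#'
#' Returns [cohort_sim_params()] with both outcome groups sharing the stable
#' group's mesor, amplitude and frailty mean, so activity carries no
#' information about the outcome; a downstream classifier's AUC should be
#' statistically indistinguishable from 0.5.
#'
#' @param ... overrides passed on to [cohort_sim_params()].
#' @return a `cohort_sim_params` object.
#' @export
null_sim_params <- function(...) {
  p <- cohort_sim_params(...)
  p$mesor_by_group <- rep(p$mesor_by_group[2], 2)
  p$amplitude_by_group <- rep(p$amplitude_by_group[2], 2)
  p$frailty_mu_by_group <- rep(mean(p$frailty_mu_by_group), 2)
  validate_sim_params(p)
  p
}

#' @export
print.cohort_sim_params <- function(x, ...) {
  cat("Synthetic actigraphy cohort parameters\n")
  cat(sprintf("  n_patients: %d (p_death = %.3f -> %d deaths)\n",
              x$n_patients, x$p_death, round(x$n_patients * x$p_death)))
  cat(sprintf("  sampling interval: %g s; stay: %d-%d days\n",
              x$sampling_interval_s, x$stay_days_range[1], x$stay_days_range[2]))
  cat(sprintf("  mesor (death/stable): %g/%g; amplitude: %g/%g; acrophase %g h\n",
              x$mesor_by_group[1], x$mesor_by_group[2],
              x$amplitude_by_group[1], x$amplitude_by_group[2], x$acrophase_h))
  cat(sprintf("  AR(1) noise: coef %g, sd %g; off-wrist %g/day x %g-%g min\n",
              x$ar1_coef, x$noise_sd, x$offwrist_rate_per_day,
              x$offwrist_duration_minutes[1], x$offwrist_duration_minutes[2]))
  cat(sprintf("  frailty mu (death/stable): %g/%g; seed %d\n",
              x$frailty_mu_by_group[1], x$frailty_mu_by_group[2], x$seed))
  invisible(x)
}

#' Preprocessing configuration
#'
#' @param horizon_h analysis horizon in hours from admission; the study
#'   design compares 48 h and 24 h. Any positive value is allowed.
#' @param block_window number of consecutive timesteps averaged into one
#'   model timestep (default 20).
#' @param max_gap_tolerance_min longest tolerated contiguous off-wrist /
#'   missing run, in minutes; longer runs make a recording ineligible as a
#'   tracking interruption. Default 60.
#' @param pad_value value used to pad sequences to a common length
#'   (default 0).
#' @param pad_side `"end"` (default) or `"front"`; where padding is added.
#' @param offwrist_as_zero if `TRUE`, off-wrist samples enter block means as
#'   zero activity instead of being excluded from the mean. Default `FALSE`.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(horizon_h = 48,
                              block_window = 20L,
                              max_gap_tolerance_min = 60,
                              pad_value = 0,
                              pad_side = c("end", "front"),
                              offwrist_as_zero = FALSE) {
  pad_side <- match.arg(pad_side)
  if (horizon_h <= 0) stop("horizon_h must be positive", call. = FALSE)
  if (block_window < 1) stop("block_window must be >= 1", call. = FALSE)
  if (max_gap_tolerance_min < 0)
    stop("max_gap_tolerance_min must be nonnegative", call. = FALSE)
  structure(
    list(horizon_h = horizon_h, block_window = as.integer(block_window),
         max_gap_tolerance_min = max_gap_tolerance_min, pad_value = pad_value,
         pad_side = pad_side, offwrist_as_zero = offwrist_as_zero),
    class = "preprocess_config")
}

#' LSTM model configuration
#'
#' The two study configurations are `units = 64, batch_size = 8, epochs = 50`
#' (preliminary) and `units = 256, batch_size = 16, epochs = 100` (final),
#' both trained with Adam at its default hyperparameters on mean-absolute-
#' error loss.
#'
#' @param units LSTM hidden width.
#' @param batch_size minibatch size.
#' @param epochs number of training epochs.
#' @param optimizer optimizer name; only `"adam"` is implemented.
#' @param loss loss name; only `"mae"` (mean absolute error) is implemented.
#' @param per_step_dense_width width of the per-timestep affine map applied
#'   to each LSTM output before flattening (default 1).
#' @param classification_threshold probability cutoff for [classify()];
#'   strictly inside (0, 1). Ties (probability equal to the threshold) are
#'   classified as death.
#' @param learning_rate Adam step size (default 1e-3).
#' @param normalize if `TRUE`, channels are z-scored with training-set
#'   statistics inside [train_model()] / [predict_proba()]. Default `FALSE`.
#' @param mask_padding if `TRUE`, padded timesteps contribute neither to the
#'   recurrence updates nor to the flattened features. Default `FALSE`.
#' @param seed integer seed for weight initialisation and minibatch
#'   shuffling.
#' @return an object of class `model_config`.
#' @export
model_config <- function(units = 256L,
                         batch_size = 16L,
                         epochs = 100L,
                         optimizer = "adam",
                         loss = "mae",
                         per_step_dense_width = 1L,
                         classification_threshold = 0.5,
                         learning_rate = 1e-3,
                         normalize = FALSE,
                         mask_padding = FALSE,
                         seed = 1L) {
  if (units < 1 || batch_size < 1 || epochs < 1 || per_step_dense_width < 1)
    stop("units, batch_size, epochs and per_step_dense_width must be positive",
         call. = FALSE)
  if (classification_threshold <= 0 || classification_threshold >= 1)
    stop("classification_threshold must lie strictly inside (0, 1)",
         call. = FALSE)
  optimizer <- match.arg(optimizer, "adam")
  loss <- match.arg(loss, c("mae", "mean_absolute_error"))
  structure(
    list(units = as.integer(units), batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), optimizer = optimizer, loss = "mae",
         per_step_dense_width = as.integer(per_step_dense_width),
         classification_threshold = classification_threshold,
         learning_rate = learning_rate, normalize = normalize,
         mask_padding = mask_padding, seed = as.integer(seed)),
    class = "model_config")
}

#' Study presets for the sequence model
#'
#' `"preliminary"`: 64 units, batch 8, 50 epochs, 7:3 train/test split.
#' `"final"`: 256 units, batch 16, 100 epochs, 7:2:1 train/validation/test
#' split.
#'
#' @param preset `"preliminary"` or `"final"`.
#' @param seed seed forwarded to [model_config()].
#' @param ... further overrides passed to [model_config()].
#' @return list with elements `model` (a `model_config`) and `ratios`
#'   (the split ratios).
#' @export
preset_config <- function(preset = c("final", "preliminary"), seed = 1L, ...) {
  preset <- match.arg(preset)
  if (preset == "preliminary") {
    list(preset = preset,
         model = model_config(units = 64L, batch_size = 8L, epochs = 50L,
                              seed = seed, ...),
         ratios = c(train = 0.7, test = 0.3))
  } else {
    list(preset = preset,
         model = model_config(units = 256L, batch_size = 16L, epochs = 100L,
                              seed = seed, ...),
         ratios = c(train = 0.7, validation = 0.2, test = 0.1))
  }
}
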