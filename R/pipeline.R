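#' Derive named sub-seeds from one top-level seed
#'
#' All pipeline randomness flows from one seed, split into named substreams
#' (simulate / split / model / ...) so that stages can be re-run in
#' isolation and remain reproducible.
#'
#' @param seed top-level integer seed.
#' @param names character vector of substream names.
#' @return named integer vector of derived seeds (each below 2^31).
#' @export
derive_seeds <- function(seed, names) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(names)), names)
}

#' Full experiment configuration
#'
#' @param simulator a [cohort_sim_params()].
#' @param preprocess a [preprocess_config()]; its `horizon_h` is overridden
#'   per entry of `horizons`.
#' @param preset `"final"` (256 units, batch 16, 100 epochs, 7:2:1 split)
#'   or `"preliminary"` (64 units, batch 8, 50 epochs, 7:3 split).
#' @param horizons analysis horizons in hours (default `c(24, 48)`).
#'   Horizons below 24 h are allowed but warn: they cover less than one
#'   circadian cycle.
#' @param normalize z-score channels with training-set statistics (pipeline
#'   default `TRUE`; the three channels are on incommensurate scales).
#' @param seed top-level seed split into substreams.
#' @param output_dir optional directory; when given, every artifact
#'   (cohort CSVs, splits, history, metrics, run config) is written there.
#' @return an object of class `run_config`.
#' @export
run_config <- function(simulator = cohort_sim_params(),
                       preprocess = preprocess_config(),
                       preset = c("final", "preliminary"),
                       horizons = c(24, 48),
                       normalize = TRUE,
                       seed = 1L,
                       output_dir = NULL) {
  preset <- match.arg(preset)
  if (any(horizons < 24))
    warning("horizons below 24 h cover less than one circadian cycle",
            call. = FALSE)
  structure(list(simulator = simulator, preprocess = preprocess,
                 preset = preset, horizons = horizons, normalize = normalize,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Top-level keys `simulator`, `preprocess`, `preset`, `horizons`,
#' `normalize`, `seed`, `output_dir`; unknown keys are rejected. Each
#' section takes the same fields as the corresponding constructor.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- c("simulator", "preprocess", "preset", "horizons", "normalize",
             "seed", "output_dir")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  sim <- do.call(cohort_sim_params, as.list(raw$simulator %||% list()))
  pre <- do.call(preprocess_config, as.list(raw$preprocess %||% list()))
  run_config(simulator = sim, preprocess = pre,
             preset = raw$preset %||% "final",
             horizons = unlist(raw$horizons %||% c(24, 48)),
             normalize = raw$normalize %||% TRUE,
             seed = raw$seed %||% 1L,
             output_dir = raw$output_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

split_sets <- function(tensors, assignment) {
  part_of <- function(t) assignment[[t$patient_id]]
  sets <- list()
  for (part in c("train", "validation", "test")) {
    sel <- tensors[vapply(tensors, function(t) identical(part_of(t), part),
                          logical(1))]
    sets[[part]] <- if (length(sel)) stack_with_lengths(sel) else NULL
  }
  sets
}

stack_with_lengths <- function(tensors) {
  s <- stack_tensors(tensors)
  s$valid_lengths <- vapply(tensors, function(t) t$valid_length, integer(1))
  s
}

#' Run the full study pipeline for one or more horizons
#'
#' For each requested horizon: simulate (or reuse) a cohort, preprocess
#' (truncate, screen eligibility, block-average, pad), split stratified by
#' outcome according to the preset's ratios, train the LSTM, and evaluate
#' on every partition. Produces one report row per horizon with the
#' training / validation / testing accuracies and the test-set
#' sensitivity, specificity, PPV, NPV and AUC.
#'
#' @param cfg a [run_config()].
#' @param cohort optional pre-simulated cohort (from [simulate_cohort()]);
#'   simulated from `cfg$simulator` when `NULL`.
#' @return an `experiment_report`: list with `report` (data frame, one row
#'   per horizon), `runs` (per-horizon details: model, split, evaluation,
#'   excluded patients) and `seeds`.
#' @export
run_experiment <- function(cfg, cohort = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  seeds <- derive_seeds(cfg$seed, c("simulate", "split", "model"))

  if (is.null(cohort)) {
    sim <- cfg$simulator
    sim$seed <- seeds[["simulate"]]
    cohort <- simulate_cohort(sim)
  }

  out_dir <- cfg$output_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_csv(cohort, file.path(out_dir, "cohort"))
  }

  pc <- preset_config(cfg$preset, seed = seeds[["model"]],
                      normalize = cfg$normalize)
  rows <- list()
  runs <- list()
  for (h in cfg$horizons) {
    pre <- cfg$preprocess
    pre$horizon_h <- h
    proc <- preprocess_cohort(cohort, pre)
    labels <- stats::setNames(proc$meta$outcome, proc$meta$patient_id)
    assignment <- split_dataset(labels, ratios = pc$ratios,
                                seed = seeds[["split"]])
    sets <- split_sets(proc$tensors, assignment)
    if (is.null(sets$train)) stop("training partition is empty", call. = FALSE)

    model <- build_model(pc$model, input_length = dim(sets$train$x)[2])
    model <- train_model(model, sets$train, val_set = sets$validation)

    evals <- list()
    for (part in names(sets)) {
      if (is.null(sets[[part]])) next
      p <- predict_proba(model, sets[[part]])
      names(p) <- sets[[part]]$ids
      evals[[part]] <- evaluate_predictions(
        p, stats::setNames(sets[[part]]$y, sets[[part]]$ids),
        threshold = pc$model$classification_threshold)
    }
    te <- evals$test$metrics
    acc_of <- function(ev) if (is.null(ev)) NA_real_ else
      ev$metrics["accuracy", "estimate"]
    rows[[length(rows) + 1L]] <- data.frame(
      model = cfg$preset, horizon_h = h,
      n_included = length(proc$tensors),
      train_acc = acc_of(evals$train),
      val_acc = acc_of(evals$validation),
      test_acc = acc_of(evals$test),
      sensitivity = te["sensitivity", "estimate"],
      specificity = te["specificity", "estimate"],
      ppv = te["ppv", "estimate"],
      npv = te["npv", "estimate"],
      auc = evals$test$auc)
    runs[[paste0("h", h)]] <- list(
      horizon_h = h, model = model, assignment = assignment,
      evaluations = evals, excluded = proc$excluded)

    if (!is.null(out_dir)) {
      hdir <- file.path(out_dir, sprintf("horizon_%gh", h))
      dir.create(hdir, showWarnings = FALSE, recursive = TRUE)
      write_splits_csv(assignment, file.path(hdir, "splits.csv"))
      write_history_csv(model, file.path(hdir, "history.csv"))
      save_model_json(model, file.path(hdir, "model.json"))
      write_metrics_json(te, file.path(hdir, "metrics_test.json"),
                         provenance = list(comparator = "LSTM",
                                           horizon_h = h, seed = cfg$seed))
      write_roc_csv(evals$test$roc, file.path(hdir, "roc_lstm.csv"))
    }
  }
  report <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seed = cfg$seed, seeds = as.list(seeds), preset = cfg$preset,
           horizons = cfg$horizons, normalize = cfg$normalize,
           simulator = unclass(cfg$simulator),
           preprocess = unclass(cfg$preprocess),
           package_version = as.character(utils::packageVersion("actisurv")),
           r_version = R.version.string),
      file.path(out_dir, "run_config.json"), digits = NA, auto_unbox = TRUE)
  }
  structure(list(report = report, runs = runs, seeds = seeds,
                 config = cfg),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment report\n")
  print(x$report, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare the LSTM against the KPS and PPI cutoff comparators
#'
#' Computes one metric report per comparator on the patients they share:
#' the KPS cutoff classifier (KPS < 50 predicts death), the PPI cutoff
#' classifier (PPI > 6.0 predicts death) where PPI is available, and the
#' LSTM probabilities where given. A comparator whose score is entirely
#' missing is dropped with a message. Each report is computed on the ids
#' common to all retained comparators, so the comparison is like-for-like;
#' the common subset size is returned alongside.
#'
#' @param meta cohort metadata (columns `patient_id`, `outcome`, `kps`,
#'   `ppi`).
#' @param lstm_probs optional named vector of LSTM death probabilities.
#' @param threshold classification threshold for the LSTM probabilities.
#' @param restrict_to_common if `TRUE` (default) evaluate every comparator
#'   on the common id set; otherwise each uses all its scored patients.
#' @return a `comparison_report`: list with `reports` (named list of
#'   `metric_report`s), `n_common`, `ids`.
#' @export
compare_comparators <- function(meta, lstm_probs = NULL, threshold = 0.5,
                                restrict_to_common = TRUE) {
  outcomes <- stats::setNames(meta$outcome, meta$patient_id)
  preds <- list()
  scores <- list()
  kps <- stats::setNames(meta$kps, meta$patient_id)
  if (all(is.na(kps))) {
    message("KPS entirely missing; comparator dropped")
  } else {
    preds$KPS <- apply_cutoff(kps, cutoff_rule("KPS"))
    scores$KPS <- list(values = kps[!is.na(kps)],
                       direction = "below_predicts_death")
  }
  ppi <- stats::setNames(meta$ppi, meta$patient_id)
  if (all(is.na(ppi))) {
    message("PPI entirely missing; comparator dropped")
  } else {
    preds$PPI <- apply_cutoff(ppi, cutoff_rule("PPI"))
    scores$PPI <- list(values = ppi[!is.na(ppi)],
                       direction = "above_predicts_death")
  }
  if (!is.null(lstm_probs)) {
    preds$LSTM <- classify(lstm_probs, threshold)
    scores$LSTM <- list(values = lstm_probs,
                        direction = "above_predicts_death")
  }
  if (length(preds) == 0L)
    stop("no comparator has any scored patient", call. = FALSE)

  ids <- Reduce(intersect, lapply(preds, names))
  if (length(ids) == 0L)
    stop("comparators share no common patients", call. = FALSE)

  reports <- lapply(names(preds), function(nm) {
    use <- if (restrict_to_common) ids else names(preds[[nm]])
    tab <- contingency_from_predictions(preds[[nm]][use], outcomes[use])
    sc <- scores[[nm]]
    keep <- intersect(use, names(sc$values))
    auc <- roc_and_auc(sc$values[keep], outcomes[keep], sc$direction)$auc
    metrics_from_contingency(tab, auc = auc)
  })
  names(reports) <- names(preds)
  structure(list(reports = reports, n_common = length(ids), ids = ids),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Comparator evaluation on %d common patients\n", x$n_common))
  for (nm in names(x$reports)) {
    cat(sprintf("-- %s --\n", nm))
    print(x$reports[[nm]])
  }
  invisible(x)
}
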