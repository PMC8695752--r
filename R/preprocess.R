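#' Truncate a series to the analysis horizon
#'
#' Keeps samples in `[start_time, start_time + horizon_h)`. Series shorter
#' than the horizon pass through unchanged; exclusion is the job of
#' [is_eligible()].
#'
#' @param series an `actigraphy_series`.
#' @param cfg a [preprocess_config()].
#' @return an `actigraphy_series` covering at most `horizon_h` hours.
#' @export
truncate_to_horizon <- function(series, cfg) {
  stopifnot(inherits(series, "actigraphy_series"),
            inherits(cfg, "preprocess_config"))
  n <- length(series$activity)
  if (n == 0L) stop("series is empty", call. = FALSE)
  n_keep <- min(n, ceiling(cfg$horizon_h * 3600 / series$interval_s))
  if (n_keep == n) return(series)
  idx <- seq_len(n_keep)
  new_actigraphy_series(series$patient_id, series$start_time,
                        series$interval_s, series$activity[idx],
                        series$angle[idx], series$spin[idx], series$worn[idx])
}

#' Eligibility screen: enough data and no tracking interruption
#'
#' A recording is eligible when, within the analysis horizon, (i) the total
#' recorded span reaches `horizon_h` hours and (ii) no contiguous off-wrist
#' or missing run exceeds `max_gap_tolerance_min` minutes.
#'
#' @param series an `actigraphy_series` (pre- or post-truncation; the check
#'   is applied to the horizon window).
#' @param cfg a [preprocess_config()].
#' @return list with `eligible` (logical) and `reason` (`"ok"`,
#'   `"insufficient duration"` or `"tracking interruption"`).
#' @export
is_eligible <- function(series, cfg) {
  stopifnot(inherits(series, "actigraphy_series"),
            inherits(cfg, "preprocess_config"))
  s <- truncate_to_horizon(series, cfg)
  span_h <- length(s$activity) * s$interval_s / 3600
  if (span_h < cfg$horizon_h)
    return(list(eligible = FALSE, reason = "insufficient duration"))
  bad <- !s$worn | is.na(s$activity)
  if (any(bad)) {
    r <- rle(bad)
    max_run <- max(r$lengths[r$values])
    if (max_run * s$interval_s / 60 > cfg$max_gap_tolerance_min)
      return(list(eligible = FALSE, reason = "tracking interruption"))
  }
  list(eligible = TRUE, reason = "ok")
}

#' Block-average a series into model timesteps
#'
#' Averages each channel over consecutive non-overlapping windows of
#' `block_window` samples; a trailing partial window is averaged over its
#' actual sample count. Off-wrist / missing samples are excluded from the
#' window mean (or treated as zero activity if `cfg$offwrist_as_zero`); a
#' window with no worn sample yields `pad_value`.
#'
#' @param series an eligible `actigraphy_series`.
#' @param cfg a [preprocess_config()].
#' @param label optional binary outcome attached to the tensor.
#' @return a `processed_tensor`: list with `patient_id`, `values`
#'   (matrix, timesteps x 3 channels `activity,angle,spin`), `valid_length`,
#'   `label`.
#' @export
block_average <- function(series, cfg, label = NA_integer_) {
  stopifnot(inherits(series, "actigraphy_series"),
            inherits(cfg, "preprocess_config"))
  n <- length(series$activity)
  if (n == 0L) stop("cannot block-average an empty series", call. = FALSE)
  w <- cfg$block_window
  n_blocks <- ceiling(n / w)
  grp <- rep(seq_len(n_blocks), each = w, length.out = n)

  one <- function(x) {
    if (cfg$offwrist_as_zero) x[is.na(x)] <- 0
    m <- vapply(split(x, grp), function(v) mean(v, na.rm = TRUE), numeric(1))
    m[!is.finite(m)] <- cfg$pad_value  # window entirely off-wrist
    unname(m)
  }
  vals <- cbind(activity = one(series$activity),
                angle = one(series$angle),
                spin = one(series$spin))
  new_processed_tensor(series$patient_id, vals, n_blocks, label)
}

new_processed_tensor <- function(patient_id, values, valid_length, label) {
  stopifnot(is.matrix(values), ncol(values) == 3L,
            valid_length <= nrow(values))
  structure(list(patient_id = patient_id, values = values,
                 valid_length = as.integer(valid_length),
                 label = as.integer(label)),
            class = "processed_tensor")
}

#' @export
print.processed_tensor <- function(x, ...) {
  cat(sprintf("Processed tensor %s: %d x 3 (valid %d), label %s\n",
              x$patient_id, nrow(x$values), x$valid_length,
              ifelse(is.na(x$label), "?", x$label)))
  invisible(x)
}

#' Pad a batch of tensors to a common length
#'
#' Pads every tensor with `cfg$pad_value` to the maximum `valid_length` in
#' the batch. Padding is appended at the end of the sequence by default
#' (`cfg$pad_side = "front"` prepends instead); `valid_length` is preserved.
#'
#' @param tensors nonempty list of `processed_tensor`s.
#' @param cfg a [preprocess_config()].
#' @return list of `processed_tensor`s, all with the same number of rows.
#' @export
pad_batch <- function(tensors, cfg) {
  stopifnot(length(tensors) > 0L)
  max_len <- max(vapply(tensors, function(t) t$valid_length, integer(1)))
  lapply(tensors, function(t) {
    v <- t$values[seq_len(t$valid_length), , drop = FALSE]
    extra <- max_len - t$valid_length
    if (extra > 0L) {
      padm <- matrix(cfg$pad_value, nrow = extra, ncol = 3L,
                     dimnames = list(NULL, colnames(t$values)))
      v <- if (cfg$pad_side == "end") rbind(v, padm) else rbind(padm, v)
    }
    new_processed_tensor(t$patient_id, v, t$valid_length, t$label)
  })
}

#' Stratified train/validation/test split
#'
#' Splits per outcome class: each class contributes
#' `floor(ratio_train * n_class)` patients to the training set, then
#' `floor(ratio_val * n_class)` to the validation set (if a validation ratio
#' is given), and the remainder to the test set. Within-class assignment is
#' randomised by `seed`. An explicit per-class `counts` override reproduces
#' splits that follow no floor rule (e.g. a balanced training set).
#'
#' @param labels named integer vector (patient_id -> 0/1 outcome).
#' @param ratios numeric vector of length 2 `(train, test)` or 3
#'   `(train, validation, test)`, summing to 1.
#' @param seed integer seed for the within-class shuffles.
#' @param counts optional list with elements `death` and `stable`, each a
#'   length-3 integer vector `(train, validation, test)` summing to the
#'   class size; overrides `ratios`.
#' @return a `split_assignment`: named character vector patient_id ->
#'   `"train" | "validation" | "test"`.
#' @export
split_dataset <- function(labels, ratios = c(0.7, 0.2, 0.1), seed = 1L,
                          counts = NULL) {
  stopifnot(!is.null(names(labels)), all(labels %in% c(0L, 1L)))
  if (is.null(counts)) {
    if (!length(ratios) %in% c(2L, 3L) || abs(sum(ratios) - 1) > 1e-8)
      stop("ratios must be length 2 or 3 and sum to 1", call. = FALSE)
    if (length(ratios) == 2L) ratios <- c(ratios[1], 0, ratios[2])
  }
  if (min(table(labels)) < 1L)
    stop("need at least one patient per class", call. = FALSE)

  set.seed(seed)
  assign_class <- function(ids, cls) {
    n <- length(ids)
    if (is.null(counts)) {
      n_tr <- floor(ratios[1] * n)
      n_va <- floor(ratios[2] * n)
      n_te <- n - n_tr - n_va
    } else {
      key <- if (cls == 1L) "death" else "stable"
      cc <- counts[[key]]
      if (length(cc) != 3L || sum(cc) != n)
        stop(sprintf("counts$%s must be (train, validation, test) summing to %d",
                     key, n), call. = FALSE)
      n_tr <- cc[1]; n_va <- cc[2]; n_te <- cc[3]
    }
    ids <- sample(ids)
    stats::setNames(rep(c("train", "validation", "test"),
                        c(n_tr, n_va, n_te)), ids)
  }
  out <- c(assign_class(names(labels)[labels == 1L], 1L),
           assign_class(names(labels)[labels == 0L], 0L))
  out <- out[names(labels)]
  want_val <- if (is.null(counts)) ratios[2] > 0 else
    sum(vapply(counts, `[`, numeric(1), 2L)) > 0
  for (part in c("train", if (want_val) "validation", "test"))
    if (!part %in% out)
      warning(sprintf("partition '%s' is empty", part), call. = FALSE)
  structure(out, class = "split_assignment")
}

#' Run the preprocessing chain over a cohort
#'
#' Composition order is fixed: truncate to horizon, screen eligibility,
#' block-average, pad to the batch maximum.
#'
#' @param cohort result of [simulate_cohort()] (with signals).
#' @param cfg a [preprocess_config()].
#' @return list with `tensors` (padded `processed_tensor`s of the eligible
#'   patients), `meta` (metadata restricted to eligible patients) and
#'   `excluded` (data frame `patient_id`, `reason`).
#' @export
preprocess_cohort <- function(cohort, cfg) {
  stopifnot(inherits(cfg, "preprocess_config"))
  labels <- stats::setNames(cohort$meta$outcome, cohort$meta$patient_id)
  tensors <- list()
  excl <- list()
  for (s in cohort$patients) {
    el <- is_eligible(s, cfg)
    if (!el$eligible) {
      excl[[length(excl) + 1L]] <-
        data.frame(patient_id = s$patient_id, reason = el$reason,
                   stringsAsFactors = FALSE)
      next
    }
    tr <- truncate_to_horizon(s, cfg)
    tensors[[length(tensors) + 1L]] <-
      block_average(tr, cfg, label = labels[[s$patient_id]])
  }
  if (length(tensors) == 0L)
    stop("no eligible patients after preprocessing", call. = FALSE)
  tensors <- pad_batch(tensors, cfg)
  kept <- vapply(tensors, function(t) t$patient_id, character(1))
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(patient_id = character(0), reason = character(0))
  list(tensors = tensors,
       meta = cohort$meta[cohort$meta$patient_id %in% kept, , drop = FALSE],
       excluded = excluded)
}

#' Stack padded tensors into a model input array
#'
#' @param tensors list of equal-length `processed_tensor`s.
#' @return list with `x` (array n x timesteps x 3), `y` (integer labels),
#'   `ids` (patient ids).
#' @export
stack_tensors <- function(tensors) {
  lens <- vapply(tensors, function(t) nrow(t$values), integer(1))
  if (length(unique(lens)) != 1L)
    stop("tensors must share a common padded length; run pad_batch() first",
         call. = FALSE)
  n <- length(tensors)
  x <- array(0, dim = c(n, lens[1], 3L))
  for (i in seq_len(n)) x[i, , ] <- tensors[[i]]$values
  list(x = x,
       y = vapply(tensors, function(t) t$label, integer(1)),
       ids = vapply(tensors, function(t) t$patient_id, character(1)))
}

#' Write processed tensors as a long CSV
#'
#' One row per patient and timestep, with header
#' `patient_id,timestep,activity,angle,spin`; timesteps run over the full
#' padded length.
#'
#' @param tensors list of `processed_tensor`s.
#' @param path output path.
#' @export
write_tensors_csv <- function(tensors, path) {
  rows <- lapply(tensors, function(t) {
    data.frame(patient_id = t$patient_id, timestep = seq_len(nrow(t$values)),
               activity = t$values[, "activity"], angle = t$values[, "angle"],
               spin = t$values[, "spin"])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a split assignment as CSV (`patient_id,partition`)
#' @param split a `split_assignment`.
#' @param path output path.
#' @export
write_splits_csv <- function(split, path) {
  write.csv(data.frame(patient_id = names(split),
                       partition = as.character(unclass(split))),
            path, row.names = FALSE)
  invisible(path)
}
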