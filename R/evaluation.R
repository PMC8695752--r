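#' Clopper--Pearson exact binomial confidence interval
#'
#' Computed by inverting the binomial tail probabilities via the beta
#' quantile representation; the lower bound is 0 when `x = 0` and the upper
#' bound 1 when `x = n`.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
clopper_pearson_ci <- function(x, n, level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  alpha <- 1 - level
  lo <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lo, upper = hi)
}

#' Diagnostic metrics from a 2x2 contingency table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`,
#' NPV `tn/(tn+fn)` and accuracy `(tp+tn)/n`, each with a Clopper--Pearson
#' exact confidence interval. A metric whose denominator is zero is
#' reported as missing (with a message) rather than 0/0.
#'
#' @param tab a `contingency_table` (see [contingency_table()]).
#' @param ci_level confidence level for the intervals.
#' @param auc optional AUC to attach to the report.
#' @return a `metric_report`: data frame with one row per metric and
#'   columns `metric`, `estimate`, `ci_low`, `ci_high`, `x`, `n`, plus
#'   attributes `auc` and `n`.
#' @export
metrics_from_contingency <- function(tab, ci_level = 0.95, auc = NA_real_) {
  stopifnot(inherits(tab, "contingency_table"))
  if (tab$n == 0) stop("empty contingency table", call. = FALSE)
  defs <- list(
    sensitivity = c(tab$tp, tab$tp + tab$fn),
    specificity = c(tab$tn, tab$tn + tab$fp),
    ppv = c(tab$tp, tab$tp + tab$fp),
    npv = c(tab$tn, tab$tn + tab$fn),
    accuracy = c(tab$tp + tab$tn, tab$n))
  rows <- lapply(names(defs), function(m) {
    x <- defs[[m]][1]; n <- defs[[m]][2]
    if (n == 0) {
      message(sprintf("%s undefined (zero denominator); reported as missing", m))
      return(data.frame(metric = m, estimate = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, x = NA_integer_, n = 0L))
    }
    ci <- clopper_pearson_ci(x, n, ci_level)
    data.frame(metric = m, estimate = x / n, ci_low = ci[1], ci_high = ci[2],
               x = as.integer(x), n = as.integer(n))
  })
  rep <- do.call(rbind, rows)
  rownames(rep) <- rep$metric
  attr(rep, "auc") <- auc
  attr(rep, "n") <- tab$n
  attr(rep, "ci_level") <- ci_level
  class(rep) <- c("metric_report", "data.frame")
  rep
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Diagnostic metrics (n = %d, %g%% exact CIs)\n",
              attr(x, "n"), 100 * attr(x, "ci_level")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %5.1f%%  (%.1f-%.1f%%)\n", x$metric[i],
                100 * x$estimate[i], 100 * x$ci_low[i], 100 * x$ci_high[i]))
  }
  if (!is.na(attr(x, "auc")))
    cat(sprintf("  %-12s %.4f\n", "auc", attr(x, "auc")))
  invisible(x)
}

#' Confusion matrix from prediction and label vectors
#'
#' Rows are the true class (`stable`, `death`), columns the predicted
#' class. With `normalize = TRUE` each row is divided by its sum so rows
#' sum to 1; a true class with no observations is reported as `NA` in
#' normalized form, never as 0/0.
#'
#' @param predictions 0/1 vector.
#' @param labels 0/1 vector of the same length.
#' @param normalize divide each row by its sum?
#' @return 2x2 numeric matrix.
#' @export
confusion_matrix <- function(predictions, labels, normalize = FALSE) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length", call. = FALSE)
  m <- matrix(0, 2, 2, dimnames = list(truth = c("stable", "death"),
                                       predicted = c("stable", "death")))
  for (truth in 0:1) for (pred in 0:1)
    m[truth + 1L, pred + 1L] <- sum(labels == truth & predictions == pred)
  if (normalize) {
    rs <- rowSums(m)
    for (r in 1:2) {
      m[r, ] <- if (rs[r] > 0) m[r, ] / rs[r] else NA_real_
    }
  }
  m
}

orient_scores <- function(scores, direction) {
  direction <- match.arg(direction,
                         c("above_predicts_death", "below_predicts_death"))
  if (direction == "below_predicts_death") -scores else scores
}

#' Empirical ROC curve and Mann--Whitney AUC
#'
#' Scores are oriented so that a higher oriented score means higher death
#' risk; the curve is built from the empirical score set (no smoothing).
#' The AUC is the Mann--Whitney concordance probability: the fraction of
#' (death, stable) pairs in which the death patient has the higher oriented
#' score, ties counting one half.
#'
#' @param scores named numeric vector of risk scores.
#' @param outcomes named 0/1 vector over the same ids.
#' @param direction `"above_predicts_death"` (default; e.g. PPI, model
#'   probabilities) or `"below_predicts_death"` (e.g. KPS).
#' @return list with `roc` (a `roc_curve` data frame:
#'   `threshold,fpr,tpr`, thresholds descending on the oriented scale) and
#'   `auc`.
#' @export
roc_and_auc <- function(scores, outcomes, direction = "above_predicts_death") {
  if (!is.null(names(scores)) && !is.null(names(outcomes)))
    outcomes <- outcomes[names(scores)]
  if (length(scores) != length(outcomes))
    stop("scores and outcomes must cover the same patients", call. = FALSE)
  keep <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[keep]; outcomes <- outcomes[keep]
  n1 <- sum(outcomes == 1); n0 <- sum(outcomes == 0)
  if (n1 == 0 || n0 == 0)
    stop("both outcome classes must be present to build a ROC curve",
         call. = FALSE)
  s <- orient_scores(scores, direction)

  # Mann-Whitney AUC via midranks
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(s >= t & outcomes == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(s >= t & outcomes == 0) / n0, numeric(1))
  roc <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  class(roc) <- c("roc_curve", "data.frame")
  attr(roc, "direction") <- direction
  list(roc = roc, auc = auc)
}

#' Youden-optimal cutoff from a ROC curve
#'
#' Maximises Youden's J = tpr - fpr over the curve's thresholds; ties are
#' broken toward the threshold that classifies fewer patients as death
#' (the highest oriented threshold among the maximisers).
#'
#' @param roc a `roc_curve` from [roc_and_auc()].
#' @return list with `threshold` (on the oriented scale), `j`, `tpr`,
#'   `fpr`, and — when the curve came from a `below_predicts_death` score —
#'   `threshold_original` on the score's own scale.
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"), nrow(roc) > 0)
  j <- roc$tpr - roc$fpr
  best <- which(j == max(j))
  # thresholds are descending; the first maximiser is the highest
  # threshold, i.e. the fewest predicted deaths
  pick <- best[1]
  out <- list(threshold = roc$threshold[pick], j = j[pick],
              tpr = roc$tpr[pick], fpr = roc$fpr[pick])
  if (identical(attr(roc, "direction"), "below_predicts_death"))
    out$threshold_original <- -out$threshold
  out
}

#' Assemble a full evaluation of binary predictions with scores
#'
#' Convenience wrapper producing the contingency table, metric report with
#' exact CIs, AUC and both confusion-matrix forms.
#'
#' @param probabilities named numeric risk scores.
#' @param outcomes named 0/1 outcomes over the same ids.
#' @param threshold classification threshold (default 0.5).
#' @param ci_level confidence level.
#' @return list with `contingency`, `metrics`, `auc`, `roc`,
#'   `confusion_raw`, `confusion_normalized`.
#' @export
evaluate_predictions <- function(probabilities, outcomes, threshold = 0.5,
                                 ci_level = 0.95) {
  outcomes <- outcomes[names(probabilities)]
  pred <- classify(probabilities, threshold)
  tab <- contingency_from_predictions(pred, outcomes)
  ra <- roc_and_auc(probabilities, outcomes)
  list(contingency = tab,
       metrics = metrics_from_contingency(tab, ci_level, auc = ra$auc),
       auc = ra$auc, roc = ra$roc,
       confusion_raw = confusion_matrix(pred, outcomes, normalize = FALSE),
       confusion_normalized = confusion_matrix(pred, outcomes,
                                               normalize = TRUE))
}

#' Write a metric report as JSON
#' @param report a `metric_report`.
#' @param path output path.
#' @param provenance optional named list (score name, cutoff, ...) stored
#'   alongside the metrics.
#' @export
write_metrics_json <- function(report, path, provenance = list()) {
  obj <- c(provenance,
           list(n = attr(report, "n"), ci_level = attr(report, "ci_level"),
                auc = attr(report, "auc"),
                metrics = as.data.frame(report)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Write a ROC curve as CSV (`threshold,fpr,tpr`)
#' @param roc a `roc_curve`.
#' @param path output path.
#' @export
write_roc_csv <- function(roc, path) {
  write.csv(as.data.frame(roc), path, row.names = FALSE)
  invisible(path)
}
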