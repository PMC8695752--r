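#' Cutoff rule for a clinical prognostic score
#'
#' The two validated rules are KPS < 50 predicts death (a KPS of exactly 50
#' is predicted stable) and PPI > 6.0 predicts death (a PPI of exactly 6.0
#' is predicted stable); both inequalities are strict.
#'
#' @param score_name `"KPS"` or `"PPI"`.
#' @param cutoff cutoff value; defaults to the validated cutoff for the
#'   score (50 for KPS, 6.0 for PPI).
#' @param direction `"below_predicts_death"` (KPS) or
#'   `"above_predicts_death"` (PPI); defaults to the score's convention.
#' @return an object of class `cutoff_rule`.
#' @export
cutoff_rule <- function(score_name = c("KPS", "PPI"), cutoff = NULL,
                        direction = NULL) {
  score_name <- match.arg(score_name)
  defaults <- list(
    KPS = list(cutoff = 50, direction = "below_predicts_death"),
    PPI = list(cutoff = 6.0, direction = "above_predicts_death"))
  d <- defaults[[score_name]]
  if (is.null(cutoff)) cutoff <- d$cutoff
  if (is.null(direction)) direction <- d$direction
  direction <- match.arg(direction,
                         c("below_predicts_death", "above_predicts_death"))
  structure(list(score_name = score_name, cutoff = cutoff,
                 direction = direction),
            class = "cutoff_rule")
}

#' Apply a cutoff rule to a set of scores
#'
#' Patients with a missing score are excluded from the prediction map (a
#' message logs how many were dropped), mirroring score availability in
#' real cohorts.
#'
#' @param scores named numeric vector (patient_id -> score).
#' @param rule a [cutoff_rule()].
#' @return named integer vector of 0/1 predictions for the scored patients.
#' @export
apply_cutoff <- function(scores, rule) {
  if (!inherits(rule, "cutoff_rule"))
    stop("unknown score rule; use cutoff_rule()", call. = FALSE)
  miss <- is.na(scores)
  if (any(miss)) {
    message(sprintf("%s: excluding %d patient(s) with missing score",
                    rule$score_name, sum(miss)))
    scores <- scores[!miss]
  }
  if (length(scores) == 0L)
    return(stats::setNames(integer(0), character(0)))
  pred <- if (rule$direction == "below_predicts_death")
    scores < rule$cutoff else scores > rule$cutoff
  stats::setNames(as.integer(pred), names(scores))
}

#' Build a 2x2 contingency table from predictions and outcomes
#'
#' True positive = predicted death and observed death; false positive =
#' predicted death, discharged stable; false negative and true negative
#' analogously.
#'
#' @param predictions named 0/1 vector (patient_id -> predicted outcome).
#' @param outcomes named 0/1 vector (patient_id -> observed outcome) over
#'   the same ids.
#' @return a `contingency_table`: list with `tp`, `fp`, `fn`, `tn`, `n`.
#' @export
contingency_from_predictions <- function(predictions, outcomes) {
  if (!setequal(names(predictions), names(outcomes))) {
    only_p <- setdiff(names(predictions), names(outcomes))
    only_o <- setdiff(names(outcomes), names(predictions))
    stop(sprintf(
      "prediction/outcome id mismatch: only in predictions {%s}; only in outcomes {%s}",
      paste(only_p, collapse = ","), paste(only_o, collapse = ",")),
      call. = FALSE)
  }
  outcomes <- outcomes[names(predictions)]
  contingency_table(
    tp = sum(predictions == 1L & outcomes == 1L),
    fp = sum(predictions == 1L & outcomes == 0L),
    fn = sum(predictions == 0L & outcomes == 1L),
    tn = sum(predictions == 0L & outcomes == 0L))
}

#' Construct a contingency table from counts
#' @param tp,fp,fn,tn nonnegative cell counts.
#' @return a `contingency_table`.
#' @export
contingency_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("contingency cells must be nonnegative integers", call. = FALSE)
  n <- sum(cells)
  if (n < 1) stop("contingency table must contain at least one count",
                  call. = FALSE)
  structure(as.list(c(cells, n = n)), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("death", "stable"),
                              predicted = c("death", "stable")))
  cat(sprintf("2x2 contingency table (n = %d)\n", x$n))
  print(m)
  invisible(x)
}

#' Write a contingency table as CSV (`tp,fp,fn,tn,n`)
#' @param tab a `contingency_table`.
#' @param path output path.
#' @export
write_contingency_csv <- function(tab, path) {
  write.csv(data.frame(tp = tab$tp, fp = tab$fp, fn = tab$fn, tn = tab$tn,
                       n = tab$n),
            path, row.names = FALSE)
  invisible(path)
}
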