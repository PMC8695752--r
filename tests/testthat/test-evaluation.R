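test_that("metric point estimates follow the 2x2 definitions", {
  rep1 <- metrics_from_contingency(contingency_table(23, 5, 5, 26))
  est <- function(r, m) r[m, "estimate"]
  expect_equal(est(rep1, "accuracy"), 49 / 59)
  expect_equal(est(rep1, "sensitivity"), 23 / 28)
  expect_equal(est(rep1, "specificity"), 26 / 31)
  expect_equal(est(rep1, "ppv"), 23 / 28)
  expect_equal(est(rep1, "npv"), 26 / 31)

  rep2 <- metrics_from_contingency(contingency_table(8, 0, 1, 11))
  expect_equal(est(rep2, "specificity"), 1)
  expect_equal(est(rep2, "ppv"), 1)
  expect_equal(est(rep2, "npv"), 11 / 12)

  rep3 <- metrics_from_contingency(contingency_table(1, 0, 0, 1))
  expect_true(all(rep3$estimate == 1))

  # every point estimate lies inside its own interval
  for (r in list(rep1, rep2, rep3)) {
    expect_true(all(r$estimate >= r$ci_low & r$estimate <= r$ci_high))
    expect_true(all(r$ci_low >= 0 & r$ci_high <= 1))
  }
})

test_that("degenerate denominators are reported as missing, not 0/0", {
  # nobody predicted positive: PPV has an empty denominator
  tab <- contingency_table(0, 0, 3, 7)
  expect_message(r <- metrics_from_contingency(tab), "ppv undefined")
  expect_true(is.na(r["ppv", "estimate"]))
  expect_false(is.na(r["npv", "estimate"]))
})

test_that("exact binomial intervals match the inverted-test oracle", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(1:80, 1)
    x <- sample(0:n, 1)
    ci <- clopper_pearson_ci(x, n)
    bt <- binom.test(x, n)$conf.int
    expect_equal(unname(ci), as.numeric(bt), tolerance = 1e-10)
  }
})

test_that("metrics agree with direct counting from prediction vectors", {
  set.seed(29)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    ids <- sprintf("p%02d", 1:n)
    pred <- stats::setNames(sample(0:1, n, TRUE), ids)
    out <- stats::setNames(sample(0:1, n, TRUE), ids)
    tab <- contingency_from_predictions(pred, out)
    r <- suppressMessages(metrics_from_contingency(tab))
    expect_equal(r["accuracy", "estimate"], mean(pred == out))
    if (any(out == 1))
      expect_equal(r["sensitivity", "estimate"],
                   mean(pred[out == 1] == 1))
    if (any(out == 0))
      expect_equal(r["specificity", "estimate"],
                   mean(pred[out == 0] == 0))
  }
})

test_that("confusion matrices count rows by truth and normalize to unit rows", {
  pred <- c(0, 1, 1, 0, 1)
  lab <- c(0, 1, 0, 0, 1)
  raw <- confusion_matrix(pred, lab)
  expect_equal(sum(raw), 5)
  expect_equal(raw["stable", "death"], 1)
  norm <- confusion_matrix(pred, lab, normalize = TRUE)
  expect_equal(unname(rowSums(norm)), c(1, 1))

  perfect <- confusion_matrix(c(0, 1), c(0, 1), normalize = TRUE)
  expect_equal(unname(perfect), diag(2))

  # absent true class: normalized row is missing, not 0/0
  one_class <- confusion_matrix(c(1, 1), c(1, 1), normalize = TRUE)
  expect_true(all(is.na(one_class["stable", ])))
  expect_equal(unname(one_class["death", ]), c(0, 1))
  expect_error(confusion_matrix(c(1, 0), c(1)), "equal length")
})

test_that("AUC equals brute-force pairwise concordance", {
  brute_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  set.seed(37)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    y <- c(0, 1, sample(0:1, n - 2, TRUE))
    s <- sample(seq(0, 1, 0.1), n, TRUE)  # coarse grid forces ties
    expect_equal(roc_and_auc(s, y)$auc, brute_auc(s, y))
  }
})

test_that("AUC degenerate and invariance properties hold", {
  y <- c(1, 1, 0, 0)
  expect_equal(roc_and_auc(c(0.9, 0.8, 0.2, 0.1), y)$auc, 1)
  expect_equal(roc_and_auc(c(0.5, 0.5, 0.5, 0.5), y)$auc, 0.5)
  expect_error(roc_and_auc(c(1, 2), c(1, 1)), "both outcome classes")

  set.seed(41)
  s <- runif(20); yy <- sample(0:1, 20, TRUE, prob = c(0.5, 0.5))
  yy[1:2] <- c(0, 1)
  a1 <- roc_and_auc(s, yy)$auc
  expect_equal(roc_and_auc(exp(3 * s) + 2, yy)$auc, a1)  # monotone transform
  # orientation: a protective score mirrors the AUC
  expect_equal(roc_and_auc(-s, yy, "below_predicts_death")$auc, a1)
})

test_that("AUC matches an established ROC implementation", {
  library(pROC)
  set.seed(43)
  s <- c(runif(15, 0.3, 1), runif(12, 0, 0.7))
  y <- c(rep(1, 15), rep(0, 12))
  ours <- roc_and_auc(s, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("ROC curves are stepwise, anchored and monotone", {
  set.seed(47)
  s <- runif(25); y <- sample(0:1, 25, TRUE); y[1:2] <- c(0, 1)
  roc <- roc_and_auc(s, y)$roc
  expect_equal(roc$tpr[1], 0); expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[nrow(roc)], 1); expect_equal(roc$fpr[nrow(roc)], 1)
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
})

test_that("the Youden cutoff maximises J and resolves ties conservatively", {
  set.seed(53)
  for (i in 1:10) {
    n <- sample(6:25, 1)
    y <- c(0, 1, sample(0:1, n - 2, TRUE))
    s <- sample(seq(0, 1, 0.2), n, TRUE)
    ra <- roc_and_auc(s, y)
    opt <- optimal_cutoff(ra$roc)
    # exhaustive oracle over all thresholds on the curve
    j_all <- ra$roc$tpr - ra$roc$fpr
    expect_equal(opt$j, max(j_all))
    n_pos_at <- function(thr) sum(s >= thr)
    ties <- ra$roc$threshold[j_all == max(j_all)]
    expect_equal(n_pos_at(opt$threshold),
                 min(vapply(ties, n_pos_at, numeric(1))))
  }

  # perfectly separated two-point curve: tie rule picks the higher threshold
  two <- roc_and_auc(c(a = 0.9, b = 0.1), c(a = 1, b = 0))
  expect_equal(optimal_cutoff(two$roc)$threshold, 0.9)
})

test_that("KPS scores built from the printed table yield the adopted cutoff", {
  k <- table1_kps_cohort()
  ra <- roc_and_auc(k$kps, k$outcome, direction = "below_predicts_death")
  opt <- optimal_cutoff(ra$roc)
  # the rule 'KPS <= 40' is the strict rule 'KPS < 50' on a 10-step scale:
  # the optimal cutoff agrees with the adopted cutoff of 50
  expect_equal(opt$threshold_original, 40)
  j_all <- ra$roc$tpr - ra$roc$fpr
  expect_true(all(opt$j >= j_all))
})

test_that("evaluate_predictions wires metrics, ROC and confusions together", {
  set.seed(59)
  ids <- sprintf("e%02d", 1:12)
  p <- stats::setNames(runif(12), ids)
  y <- stats::setNames(c(rep(1L, 5), rep(0L, 7)), ids)
  ev <- suppressMessages(evaluate_predictions(p, y))
  expect_s3_class(ev$metrics, "metric_report")
  expect_equal(sum(ev$confusion_raw), 12)
  expect_equal(unname(rowSums(ev$confusion_normalized)), c(1, 1))
  expect_equal(attr(ev$metrics, "auc"), ev$auc)
})
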