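test_that("horizon truncation keeps exactly the leading window", {
  cfg <- preprocess_config(horizon_h = 48)
  ten_days <- constant_series(1, 10 * 86400, interval_s = 1)
  tr <- truncate_to_horizon(ten_days, cfg)
  expect_equal(length(tr$activity), 172800L)

  forty_h <- constant_series(1, 40 * 3600, interval_s = 1)
  expect_identical(truncate_to_horizon(forty_h, cfg), forty_h)

  p <- cohort_sim_params(sampling_interval_s = 600,
                         stay_days_range = c(3L, 3L))
  set.seed(2)
  s <- simulate_patient(p, 0)$series
  tr24 <- truncate_to_horizon(s, preprocess_config(horizon_h = 24))
  last_offset_s <- (length(tr24$activity) - 1L) * tr24$interval_s
  expect_lt(last_offset_s, 24 * 3600)
})

test_that("eligibility screens duration and tracking interruptions", {
  cfg <- preprocess_config(horizon_h = 48, max_gap_tolerance_min = 30)

  full <- constant_series(1, 48 * 3600 / 600, interval_s = 600)
  expect_true(is_eligible(full, cfg)$eligible)

  n <- 48 * 3600 / 600
  worn <- rep(TRUE, n)
  worn[10:(10 + 2 * 6 - 1)] <- FALSE  # a single 2-h gap at 600 s sampling
  gappy <- constant_series(1, n, interval_s = 600, worn = worn)
  el <- is_eligible(gappy, cfg)
  expect_false(el$eligible)
  expect_equal(el$reason, "tracking interruption")

  short <- constant_series(1, 40 * 3600 / 600, interval_s = 600)
  el2 <- is_eligible(short, cfg)
  expect_false(el2$eligible)
  expect_equal(el2$reason, "insufficient duration")
})

test_that("cohort-level exclusions agree with an independent recount", {
  # stays down to 1 day and removals up to 3 h produce both failure modes
  p <- cohort_sim_params(n_patients = 60L, sampling_interval_s = 600,
                         stay_days_range = c(1L, 12L),
                         offwrist_rate_per_day = 1,
                         offwrist_duration_minutes = c(30, 180), seed = 4L)
  co <- simulate_cohort(p)
  cfg <- preprocess_config(horizon_h = 48)
  proc <- preprocess_cohort(co, cfg)
  n_eligible <- length(proc$tensors)
  expect_equal(n_eligible + nrow(proc$excluded), 60L)
  expect_gt(nrow(proc$excluded), 0L)
  expect_gt(n_eligible, 0L)

  # independent recount straight off the raw series
  horizon_n <- 48 * 3600 / 600
  recount <- vapply(co$patients, function(s) {
    n <- min(length(s$activity), horizon_n)
    if (n < horizon_n) return(FALSE)
    bad <- !s$worn[1:n]
    if (!any(bad)) return(TRUE)
    r <- rle(bad)
    max(r$lengths[r$values]) * 600 / 60 <= cfg$max_gap_tolerance_min
  }, logical(1))
  expect_equal(n_eligible, sum(recount))
  expect_setequal(proc$excluded$patient_id,
                  vapply(co$patients, `[[`, "", "patient_id")[!recount])
})

test_that("block averaging follows the window-mean definition", {
  cfg <- preprocess_config(block_window = 2)
  s <- constant_series(0, 4)
  s$activity <- c(1, 2, 3, 4)
  t <- block_average(s, cfg)
  expect_equal(t$values[, "activity"], c(1.5, 3.5))
  expect_equal(t$valid_length, 2L)

  # constant series: any window returns the constant
  cfg20 <- preprocess_config(block_window = 20)
  c7 <- constant_series(7, 103)
  t7 <- block_average(c7, cfg20)
  expect_true(all(t7$values[, "activity"] == 7))
  expect_equal(t7$valid_length, ceiling(103 / 20))

  # trailing partial window is averaged over its actual count
  s2 <- constant_series(0, 5)
  s2$activity <- c(2, 4, 6, 8, 10)
  expect_equal(block_average(s2, cfg)$values[, "activity"], c(3, 7, 10))
})

test_that("48 h at 1 Hz with window 20 gives 8,640 model timesteps", {
  cfg <- preprocess_config(horizon_h = 48, block_window = 20)
  s <- constant_series(1, 172800, interval_s = 1)
  t <- block_average(truncate_to_horizon(s, cfg), cfg)
  expect_equal(t$valid_length, 8640L)
  expect_equal(nrow(t$values), 8640L)
})

test_that("off-wrist samples are excluded from window means", {
  cfg <- preprocess_config(block_window = 4)
  worn <- c(TRUE, TRUE, FALSE, FALSE, rep(FALSE, 4))
  s <- constant_series(0, 8, worn = worn)
  s$activity[worn] <- c(2, 6)
  t <- block_average(s, cfg)
  expect_equal(t$values[, "activity"], c(4, cfg$pad_value))

  cfg0 <- preprocess_config(block_window = 4, offwrist_as_zero = TRUE)
  t0 <- block_average(s, cfg0)
  expect_equal(t0$values[, "activity"], c(2, 0))
})

test_that("padding equalises lengths, preserves content and validity", {
  cfg <- preprocess_config()
  mk <- function(n, id) block_average(constant_series(1, n * 20,
                                                      interval_s = 1,
                                                      id = id), cfg)
  ts <- list(mk(100, "A"), mk(250, "B"), mk(8640, "C"))
  padded <- pad_batch(ts, cfg)
  expect_true(all(vapply(padded, function(t) nrow(t$values), integer(1)) ==
                    8640L))
  expect_equal(vapply(padded, function(t) t$valid_length, integer(1)),
               c(100L, 250L, 8640L))
  # zero padding conserves channel sums
  expect_equal(sum(padded[[1]]$values), sum(ts[[1]]$values))
  # rows beyond valid_length equal the pad value
  expect_true(all(padded[[1]]$values[101:8640, ] == cfg$pad_value))
  # single tensor is unchanged
  expect_identical(pad_batch(ts[3], cfg)[[1]], ts[[3]])

  cfg_front <- preprocess_config(pad_side = "front")
  pf <- pad_batch(ts[1:2], cfg_front)
  expect_true(all(pf[[1]]$values[1:150, ] == cfg$pad_value))
  expect_equal(pf[[1]]$values[151:250, ], ts[[1]]$values)
})

test_that("block averaging commutes with zero padding on complete data", {
  cfg <- preprocess_config(block_window = 5)
  set.seed(31)
  for (rep in 1:10) {
    n_blocks <- sample(2:8, 1)
    n <- n_blocks * 5L
    s <- constant_series(0, n)
    s$activity <- runif(n); s$angle <- rnorm(n); s$spin <- runif(n)
    target_blocks <- n_blocks + sample(1:4, 1)
    # route 1: block-average, then pad to the target length
    t1 <- block_average(s, cfg)
    fake <- t1; fake$valid_length <- as.integer(target_blocks)
    fake$values <- rbind(t1$values,
                         matrix(0, target_blocks - n_blocks, 3,
                                dimnames = list(NULL, colnames(t1$values))))
    padded <- pad_batch(list(t1, fake), cfg)[[1]]
    # route 2: zero-pad the raw series, then block-average
    s2 <- constant_series(0, target_blocks * 5L)
    s2$activity <- c(s$activity, rep(0, (target_blocks - n_blocks) * 5L))
    s2$angle <- c(s$angle, rep(0, (target_blocks - n_blocks) * 5L))
    s2$spin <- c(s$spin, rep(0, (target_blocks - n_blocks) * 5L))
    t2 <- block_average(s2, cfg)
    expect_equal(unname(padded$values), unname(t2$values))
  }
})

test_that("stratified floor split reproduces worked partition examples", {
  labels <- stats::setNames(c(rep(1L, 21), rep(0L, 23)),
                            sprintf("P%02d", 1:44))
  sp <- split_dataset(labels, ratios = c(0.7, 0.2, 0.1), seed = 7L)
  tab <- table(factor(unclass(sp), c("train", "validation", "test")),
               labels[names(sp)])
  expect_equal(unname(tab[, "1"]), c(14L, 4L, 3L))
  expect_equal(unname(tab[, "0"]), c(16L, 4L, 3L))
  expect_equal(unname(rowSums(tab)), c(30L, 8L, 6L))

  labels2 <- stats::setNames(rep(c(0L, 1L), each = 10),
                             sprintf("Q%02d", 1:20))
  sp2 <- split_dataset(labels2, ratios = c(0.5, 0.5), seed = 1L)
  tab2 <- table(unclass(sp2), labels2[names(sp2)])
  expect_true(all(tab2 == 5L))

  # balanced-training split reachable only via the explicit override
  sp3 <- split_dataset(labels, counts = list(death = c(15L, 0L, 6L),
                                             stable = c(15L, 0L, 8L)),
                       seed = 2L)
  tab3 <- table(factor(unclass(sp3), c("train", "validation", "test")),
                labels[names(sp3)])
  expect_equal(unname(tab3[, "1"]), c(15L, 0L, 6L))
  expect_equal(unname(tab3[, "0"]), c(15L, 0L, 8L))
})

test_that("splits are disjoint, exhaustive and follow the floor formula", {
  set.seed(12)
  for (i in 1:25) {
    n1 <- sample(2:40, 1); n0 <- sample(2:40, 1)
    r <- runif(3); r <- r / sum(r)
    labels <- stats::setNames(c(rep(1L, n1), rep(0L, n0)),
                              sprintf("R%03d", seq_len(n1 + n0)))
    sp <- suppressWarnings(split_dataset(labels, ratios = r,
                                         seed = sample.int(1e6, 1)))
    expect_setequal(names(sp), names(labels))
    for (cls in c(0L, 1L)) {
      nc <- if (cls == 1L) n1 else n0
      parts <- table(factor(unclass(sp)[labels[names(sp)] == cls],
                            c("train", "validation", "test")))
      expect_equal(unname(parts["train"]), floor(r[1] * nc))
      expect_equal(unname(parts["validation"]), floor(r[2] * nc))
      expect_equal(unname(parts["test"]),
                   nc - floor(r[1] * nc) - floor(r[2] * nc))
    }
  }
})

test_that("processed tensors export as a long CSV", {
  cfg <- preprocess_config(block_window = 2)
  s <- constant_series(1, 6, id = "W01")
  t1 <- block_average(s, cfg, label = 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tensors_csv(list(t1), path)
  df <- utils::read.csv(path)
  expect_named(df, c("patient_id", "timestep", "activity", "angle", "spin"))
  expect_equal(nrow(df), 3L)
  expect_equal(df$activity, c(1, 1, 1))
})

test_that("the composed chain yields the expected padded length", {
  p <- cohort_sim_params(n_patients = 6L, p_death = 0.5,
                         sampling_interval_s = 600,
                         stay_days_range = c(3L, 4L),
                         offwrist_rate_per_day = 0.5, seed = 9L)
  co <- simulate_cohort(p)
  cfg <- preprocess_config(horizon_h = 48, block_window = 20)
  proc <- preprocess_cohort(co, cfg)
  expected_len <- ceiling(48 * 3600 / 600 / 20)
  for (t in proc$tensors) expect_equal(nrow(t$values), expected_len)
  st <- stack_tensors(proc$tensors)
  expect_equal(dim(st$x), c(length(proc$tensors), expected_len, 3L))
})
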