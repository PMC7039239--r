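test_that("half_split obeys the odd-count rule per subject", {
  data10 <- array(rnorm(10 * 5 * 6), dim = c(10, 5, 6))
  w10 <- raw_windows(data10, subject_ids = rep(c("A", "B"), each = 5))
  expect_error(half_split(w10), NA)
  # 10 and 11 windows for one subject
  data21 <- array(rnorm(21 * 5 * 6), dim = c(21, 5, 6))
  w21 <- raw_windows(data21, subject_ids = rep(c("A", "B"), c(10, 11)))
  sp <- half_split(w21, seed = 1)
  expect_equal(sum(sp$train$info$subject_id == "A"), 5)
  expect_equal(sum(sp$test$info$subject_id == "A"), 5)
  expect_equal(sum(sp$train$info$subject_id == "B"), 6)
  expect_equal(sum(sp$test$info$subject_id == "B"), 5)
  # determinism and partition property
  sp2 <- half_split(w21, seed = 1)
  expect_identical(sp$train$info, sp2$train$info)
  expect_equal(n_windows(sp$train) + n_windows(sp$test), 21)
  # every subject in both partitions
  expect_setequal(unique(sp$train$info$subject_id), c("A", "B"))
  expect_setequal(unique(sp$test$info$subject_id), c("A", "B"))
  one <- raw_windows(array(0, c(3, 5, 6)), subject_ids = c("A", "A", "B"))
  expect_error(half_split(one), ">= 2 windows")
})

test_that("kfold_splits is a stratified partition", {
  data <- array(rnorm(200 * 5 * 6), dim = c(200, 5, 6))
  w <- raw_windows(data, subject_ids = rep(c("A", "B"), each = 100))
  folds <- kfold_splits(w, k = 10, seed = 2)
  expect_length(folds, 10)
  test_sizes <- vapply(folds, function(f) n_windows(f$test), 1L)
  expect_true(all(test_sizes == 20))
  for (f in folds) {
    expect_equal(sum(f$test$info$subject_id == "A"), 10)
    expect_equal(n_windows(f$train) + n_windows(f$test), 200)
  }
  # each window in exactly one test fold: reconstruct fold ids
  seen <- integer(200)
  for (f in folds) {
    # identify windows by their stored random content
    key <- apply(f$test$data[, 1, , drop = FALSE], 1, paste, collapse = ",")
    all_key <- apply(w$data[, 1, , drop = FALSE], 1, paste, collapse = ",")
    seen[match(key, all_key)] <- seen[match(key, all_key)] + 1L
  }
  expect_true(all(seen == 1L))
  expect_identical(lapply(kfold_splits(w, 10, seed = 2), function(f)
    f$test$info), lapply(folds, function(f) f$test$info))
  expect_error(kfold_splits(w, k = 1), "k must be")
  small <- raw_windows(array(0, c(5, 5, 6)), subject_ids = rep("A", 5))
  expect_error(kfold_splits(small, k = 10), ">= 10 windows")
})

test_that("cmc_curve matches hand-computed examples", {
  # perfect classifier
  s <- diag(3)
  expect_equal(cmc_curve(s, 1:3)$matching_rate, c(1, 1, 1))
  # C = 4, true-class ranks (1, 2, 1)
  s <- rbind(c(0.6, 0.2, 0.1, 0.1),
             c(0.5, 0.3, 0.1, 0.1),
             c(0.1, 0.1, 0.7, 0.1))
  cmc <- cmc_curve(s, c(1, 2, 3))
  expect_equal(cmc$matching_rate, c(2 / 3, 1, 1, 1))
  # terminal value is always 1
  set.seed(3)
  r <- matrix(runif(20), 5, 4)
  expect_equal(cmc_curve(r, c(1, 2, 3, 4, 1))$matching_rate[4], 1)
  expect_error(cmc_curve(s, c(1, 2, 9)), "class set")
  expect_error(cmc_curve(s[0, , drop = FALSE], integer(0)), "one query")
})

test_that("mAP is the mean reciprocal rank, in percent", {
  s <- diag(3)
  expect_equal(mean_average_precision(s, 1:3), 100)
  expect_equal(mean_average_precision(rbind(c(0.4, 0.6)), 1), 50)
  # ranks (1, 2, 4)
  s <- rbind(c(0.9, 0.05, 0.03, 0.02),
             c(0.3, 0.25, 0.4, 0.05),
             c(0.3, 0.25, 0.35, 0.1))
  expect_equal(mean_average_precision(s, c(1, 1, 4)),
               100 * (1 + 1 / 2 + 1 / 4) / 3, tolerance = 1e-9)
})

test_that("gallery mAP ranks windows of the same subject first", {
  s <- rbind(c(0.96, 0.02, 0.02), c(0.9, 0.06, 0.04),
             c(0.03, 0.95, 0.02), c(0.05, 0.9, 0.05),
             c(0.02, 0.03, 0.95), c(0.04, 0.04, 0.92))
  truths <- c(1, 1, 2, 2, 3, 3)
  expect_equal(mean_average_precision(s, truths, method = "gallery"), 100)
})

test_that("cmc and mAP match brute force on random score matrices", {
  set.seed(17)
  for (i in 1:50) {
    C <- sample(2:8, 1)
    n <- sample(1:20, 1)
    scores <- matrix(runif(n * C), n, C)
    if (i %% 3 == 0) scores[1, ] <- 0.5  # exercise tie-breaking
    truths <- sample(C, n, replace = TRUE)
    expect_equal(cmc_curve(scores, truths)$matching_rate,
                 oracle_cmc(scores, truths))
    expect_equal(mean_average_precision(scores, truths),
                 oracle_map(scores, truths))
  }
})

test_that("confusion_matrix tallies truth vs prediction", {
  s <- diag(4)
  expect_equal(unname(confusion_matrix(s, 1:4)), diag(4L))
  # 2 classes, truths (1,1,2), predictions (1,2,2)
  s <- rbind(c(0.8, 0.2), c(0.3, 0.7), c(0.4, 0.6))
  cm <- confusion_matrix(s, c(1, 1, 2))
  expect_equal(unname(cm), rbind(c(1L, 1L), c(0L, 1L)))
  expect_equal(unname(rowSums(cm)), c(2L, 1L))
  expect_equal(sum(diag(cm)) / sum(cm),
               cmc_curve(s, c(1, 1, 2))$matching_rate[1])
})

test_that("cohort filters restrict by gender, age group and setup", {
  w <- hybrid_windows(seed = 1)
  expect_equal(length(unique(w$info$subject_id)), 86)
  # no fields set: identity
  expect_equal(n_windows(cohort_filter_windows(w, cohort_filter())),
               n_windows(w))
  expect_equal(n_windows(cohort_filter_windows(w, NULL)), n_windows(w))
  females <- cohort_filter_windows(w, cohort_filter(gender = "female"))
  expect_equal(length(unique(females$info$subject_id)), 37)
  g2 <- cohort_filter_windows(w, cohort_filter(age_group = "G2"))
  expect_equal(length(unique(g2$info$subject_id)), 48)
  ab <- cohort_filter_windows(w, cohort_filter(setup = c("A", "B")))
  expect_equal(length(unique(ab$info$subject_id)), 60)
  # all six groups partition the cohort
  sizes <- vapply(age_groups()$group, function(g) {
    length(unique(cohort_filter_windows(w,
      cohort_filter(age_group = g))$info$subject_id))
  }, 1L)
  expect_equal(unname(sizes), c(3L, 48L, 9L, 10L, 9L, 7L))
  # an impossible filter errors
  kids <- cohort_filter(age_group = "G1", setup = "C")
  expect_error(cohort_filter_windows(g2, cohort_filter(age_group = "G1")),
               "empty cohort")
})

test_that("run_experiment on the separable fixture recovers identity", {
  streams <- tiny_streams(n_subjects = 5, duration_s = 40, seed = 2)
  cfg <- model_config(n_units = 32, epochs = 8, seed = 1)
  report <- run_experiment(streams, "step", "half_split", cfg, seed = 7)
  expect_s3_class(report, "eval_report")
  expect_gte(report$rank_k$rank1, 95)
  rk <- unlist(report$rank_k)
  expect_true(all(diff(rk) >= 0))
  # mAP (mean reciprocal rank) dominates rank-1 on every report
  expect_gte(report$map_percent, report$rank_k$rank1 - 1e-9)
  expect_equal(report$cmc$matching_rate[report$n_classes], 1)
  expect_equal(sum(report$confusion), report$n_test)
})

test_that("the k-fold protocol yields one full report per fold", {
  streams <- tiny_streams(n_subjects = 3, duration_s = 30, seed = 3)
  cfg <- model_config(n_units = 8, epochs = 1, seed = 1)
  reports <- run_experiment(streams, "step", "kfold", cfg, seed = 5, k = 10)
  expect_length(reports, 10)
  for (r in reports) {
    expect_s3_class(r, "eval_report")
    expect_length(r$cmc$matching_rate, 3)
    expect_equal(r$cmc$matching_rate[3], 1)
    expect_gte(r$map_percent, r$rank_k$rank1 - 1e-9)
  }
})

test_that("report serialization writes valid JSON and CSV", {
  streams <- tiny_streams(n_subjects = 3, duration_s = 20, seed = 4)
  cfg <- model_config(n_units = 8, epochs = 1, seed = 1)
  report <- run_experiment(streams, "step", "half_split", cfg, seed = 1)
  dir <- withr::local_tempdir()
  write_report(report, file.path(dir, "report.json"))
  back <- jsonlite::read_json(file.path(dir, "report.json"),
                              simplifyVector = TRUE)
  expect_equal(back$protocol, "half_split")
  expect_equal(back$map_percent, report$map_percent)
  expect_length(back$cmc, 3)
  write_cmc_csv(report, file.path(dir, "cmc.csv"))
  cmc <- read.csv(file.path(dir, "cmc.csv"))
  expect_equal(cmc$matching_rate, report$cmc$matching_rate)
  w <- segment_corpus(streams, "step")
  write_confusion_csv(report, file.path(dir, "confusion.csv"), windows = w)
  cm <- read.csv(file.path(dir, "confusion.csv"), row.names = 1)
  expect_equal(nrow(cm), 3)
  expect_true(all(grepl("^\\([MF], \\d+, [ABC]\\)$", rownames(cm))))
})
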