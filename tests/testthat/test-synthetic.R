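test_that("make_cohort reproduces the requested composition", {
  cohort <- make_cohort(86, male_fraction = 49 / 86,
                        setup_mix = c(A = 40, B = 20, C = 26), seed = 11)
  expect_length(cohort, 86)
  genders <- vapply(cohort, `[[`, "", "gender")
  setups <- vapply(cohort, `[[`, "", "setup")
  ages <- vapply(cohort, `[[`, 1L, "age_years")
  expect_equal(sum(genders == "male"), 49)
  expect_equal(sum(genders == "female"), 37)
  expect_equal(unname(table(setups)[c("A", "B", "C")]), c(40L, 20L, 26L),
               ignore_attr = TRUE)
  expect_true(all(ages >= 17 & ages <= 72))
  ids <- vapply(cohort, `[[`, "", "subject_id")
  expect_equal(anyDuplicated(ids), 0L)
  freqs <- vapply(cohort, `[[`, 1.0, "step_freq_hz")
  expect_true(all(freqs >= 1 & freqs <= 2))
  # signatures differ pairwise with probability 1
  expect_equal(anyDuplicated(freqs), 0L)
})

test_that("make_cohort handles the empty case, determinism and errors", {
  expect_identical(make_cohort(0), list())
  expect_identical(make_cohort(12, seed = 5), make_cohort(12, seed = 5))
  expect_error(make_cohort(-1), "non-negative")
  expect_error(make_cohort(10, setup_mix = c(A = 4, B = 4, C = 4)),
               "setup_mix")
  expect_error(make_cohort(10, age_group_counts = c(G1 = 9)),
               "age_group_counts")
})

test_that("cohort age statistics track the target moments over many seeds", {
  n_rep <- 1000
  means <- numeric(n_rep)
  sds <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    ages <- vapply(make_cohort(86, seed = i), `[[`, 1L, "age_years")
    means[i] <- mean(ages)
    sds[i] <- sd(ages)
  }
  expect_lt(abs(mean(means) - 33.8), 1.0)
  expect_lt(abs(mean(sds) - 14.8), 2.0)
})

test_that("age_group_counts pins subjects into the requested decade bins", {
  cohort <- hybrid_cohort(seed = 3)
  ages <- vapply(cohort, `[[`, 1L, "age_years")
  g <- age_groups()
  counts <- vapply(seq_len(nrow(g)), function(i) {
    sum(ages >= g$lower[i] & ages <= g$upper[i])
  }, 1L)
  expect_equal(counts, c(3L, 48L, 9L, 10L, 9L, 7L))
})

test_that("simulate_recording yields the requested frame count", {
  p <- make_cohort(1, seed = 4)[[1]]
  s <- simulate_recording(p, duration_s = 10, rate_hz = 75, seed = 1)
  expect_equal(nrow(s$samples), 750)
  expect_equal(ncol(s$samples), 6)
  expect_true(all(is.finite(s$samples)))
  expect_error(simulate_recording(p, duration_s = 0), "duration_s")
  expect_error(simulate_recording(p, duration_s = 5, rate_hz = -1),
               "rate_hz")
})

test_that("zero amplitudes and zero noise give a constant baseline", {
  p <- pure_profile(amp = 0)
  p$baseline <- c(0, 0, 9.81, 0, 0, 0)
  s <- simulate_recording(p, duration_s = 2, rate_hz = 75, seed = 1)
  for (c in 1:6) {
    expect_equal(s$samples[, c], rep(p$baseline[c], 150))
  }
})

test_that("a 1.5 Hz noise-free tone peaks at autocorrelation lag 50", {
  p <- pure_profile(step_freq_hz = 1.5, asymmetry = 0)
  s <- simulate_recording(p, duration_s = 20, rate_hz = 75, seed = 1)
  expect_equal(oracle_dominant_lag(s$samples[, "acc_x"]), 50L)
})

test_that("streams are stride-periodic and step-asymmetric without noise", {
  for (f in c(1.0, 1.5)) {
    p <- pure_profile(step_freq_hz = f, asymmetry = 0.3,
                      amp = c(1, 0.4, 0.2, 0.1))
    s <- simulate_recording(p, duration_s = 20, rate_hz = 75, seed = 1)
    stride_lag <- as.integer(2 / f * 75)
    step_lag <- stride_lag %/% 2L
    n <- nrow(s$samples)
    head_rows <- 1:(n - stride_lag)
    expect_equal(s$samples[head_rows + stride_lag, ],
                 s$samples[head_rows, ], tolerance = 1e-8)
    expect_gt(max(abs(s$samples[1:(n - step_lag) + step_lag, 1] -
                        s$samples[1:(n - step_lag), 1])), 0.01)
  }
})

test_that("identical (profile, duration, rate, seed) give identical streams", {
  p <- make_cohort(1, seed = 9)[[1]]
  s1 <- simulate_recording(p, 5, 75, seed = 123)
  s2 <- simulate_recording(p, 5, 75, seed = 123)
  expect_identical(s1$samples, s2$samples)
  s3 <- simulate_recording(p, 5, 75, seed = 124)
  expect_false(identical(s1$samples, s3$samples))
})

test_that("inject_perturbation: magnitude 0 is the identity", {
  p <- make_cohort(1, seed = 2)[[1]]
  s <- simulate_recording(p, 5, 75, seed = 1)
  expect_identical(inject_perturbation(s, "surface", 0)$samples, s$samples)
  expect_identical(inject_perturbation(s, "faked-gait", 0)$samples,
                   s$samples)
  expect_error(inject_perturbation(s, "rain", 0.1), "unknown perturbation")
})

test_that("surface perturbation strictly increases per-channel variance", {
  p <- make_cohort(1, seed = 6)[[1]]
  s <- simulate_recording(p, 10, 75, seed = 1)
  pert <- inject_perturbation(s, "surface", 0.2, seed = 7)
  expect_equal(dim(pert$samples), dim(s$samples))
  for (c in 1:6) {
    expect_gt(var(pert$samples[, c]), var(s$samples[, c]))
  }
  expect_equal(pert$condition, "surface")
})

test_that("faked-gait shifts the dominant autocorrelation lag", {
  p <- pure_profile(step_freq_hz = 1.5, asymmetry = 0)
  s <- simulate_recording(p, 20, 75, seed = 1)
  lag0 <- oracle_dominant_lag(s$samples[, 1])
  pert <- inject_perturbation(s, "faked-gait", 0.2, seed = 3)
  expect_equal(nrow(pert$samples), nrow(s$samples))
  lag1 <- oracle_dominant_lag(pert$samples[, 1])
  expect_false(lag1 == lag0)
  expect_equal(pert$condition, "faked-gait")
})

test_that("stream CSV + JSON round-trips", {
  p <- make_cohort(1, seed = 8)[[1]]
  s <- simulate_recording(p, 3, 75, seed = 1)
  prefix <- file.path(withr::local_tempdir(), "stream1")
  write_stream(s, prefix)
  back <- read_stream(prefix)
  expect_equal(back$samples, s$samples, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$subject$subject_id, p$subject_id)
  expect_equal(back$subject$gender, p$gender)
  expect_equal(back$rate_hz, 75)
})
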