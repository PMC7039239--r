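# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# A noise-free pure-signature profile with controllable frequency/asymmetry.
pure_profile <- function(step_freq_hz = 1.5, asymmetry = 0,
                         amp = c(1, 0, 0, 0), subject_id = "P1") {
  amps <- matrix(0, 6, length(amp))
  for (c in 1:6) amps[c, ] <- amp
  subject_profile(subject_id = subject_id, gender = "male", age_years = 30,
                  setup = "A", step_freq_hz = step_freq_hz,
                  harmonic_amps = amps,
                  harmonic_phases = matrix(0, 6, length(amp)),
                  asymmetry = asymmetry, noise_sd = rep(0, 6),
                  baseline = rep(0, 6))
}

# Small separable corpus: n subjects with evenly spaced stepping
# frequencies, short recordings — cheap enough for module-level training
# tests.
tiny_streams <- function(n_subjects = 3, duration_s = 20, seed = 1) {
  fixture_streams(n_subjects = n_subjects, duration_s = duration_s,
                  seed = seed)
}

# Build a gait_windows container directly from a (n x L x 6) array.
raw_windows <- function(data, subject_ids = NULL, kind = "step",
                        gender = "male", age_years = 30, setup = "A") {
  n <- dim(data)[1]
  if (is.null(subject_ids)) subject_ids <- rep("S1", n)
  info <- data.frame(subject_id = subject_ids, kind = kind,
                     start_frame = 0L, gender = gender,
                     age_years = age_years, setup = setup,
                     condition = "baseline", stringsAsFactors = FALSE)
  gaitreid:::new_gait_windows(data, info, kind, dim(data)[2], 75)
}

# The Table-5-style hybrid cohort: 86 subjects, 49:37 male:female, setups
# 40/20/26, age-group counts 3/48/9/10/9/7.
hybrid_cohort <- function(seed = 1) {
  make_cohort(86, male_fraction = 49 / 86,
              setup_mix = c(A = 40, B = 20, C = 26), seed = seed,
              age_group_counts = c(G1 = 3, G2 = 48, G3 = 9, G4 = 10,
                                   G5 = 9, G6 = 7))
}

# Short streams (few windows each) for the whole hybrid cohort; cheap
# because each recording is only a few seconds long.
hybrid_windows <- function(seed = 1, duration_s = 4) {
  cohort <- hybrid_cohort(seed)
  streams <- simulate_cohort(cohort, duration_s = duration_s, seed = seed)
  segment_corpus(streams, "step")
}

expect_same_windows <- function(a, b) {
  expect_equal(a$data, b$data)
  expect_equal(a$info, b$info)
}
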