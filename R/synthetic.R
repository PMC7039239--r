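# Synthetic cohorts and quasi-periodic 6D inertial walking signals.
#
# Every subject carries a harmonic gait signature: a stepping frequency in
# [1, 2] Hz, K harmonic amplitudes/phases per channel, and a half-frequency
# asymmetry term that makes the two steps of one stride distinguishable.

.K_HARMONICS <- 4L
.AGE_RANGE <- c(17, 72)
.GRAVITY <- 9.81

# Channel amplitude scales: accelerations in m/s^2, angular velocities in
# rad/s, roughly matching chest-worn MEMS output during walking.
.CHANNEL_SCALE <- c(2.0, 2.0, 2.0, 0.8, 0.8, 0.8)

#' Construct a subject profile
#'
#' A `subject_profile` bundles the demographic metadata and the harmonic gait
#' signature that [simulate_recording()] turns into a 6-channel inertial
#' stream. Usually created in bulk by [make_cohort()].
#'
#' @param subject_id opaque identifier string.
#' @param gender `"male"` or `"female"`.
#' @param age_years integer age, >= 0.
#' @param setup acquisition setup label, one of `"A"`, `"B"`, `"C"`.
#' @param step_freq_hz stepping frequency in Hz; normal walk stays in
#'   `[1, 2]` Hz and values outside that band are rejected.
#' @param harmonic_amps 6 x K matrix of harmonic amplitudes per channel
#'   (rows follow [imu_channels()]).
#' @param harmonic_phases 6 x K matrix of phases in `[0, 2*pi)`.
#' @param asymmetry in `[0, 1)`; scales the half-frequency component whose
#'   period is one stride (two steps), so consecutive steps differ.
#' @param noise_sd length-6 vector of per-channel Gaussian noise SDs.
#' @param baseline length-6 vector of channel offsets; the default puts
#'   gravity on `acc_z` (chest-mounted sensor frame).
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, gender, age_years, setup,
                            step_freq_hz, harmonic_amps, harmonic_phases,
                            asymmetry, noise_sd,
                            baseline = c(0, 0, .GRAVITY, 0, 0, 0)) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  gender <- match.arg(gender, c("male", "female"))
  setup <- match.arg(setup, c("A", "B", "C"))
  check_scalar_number(age_years, "age_years", lower = 0)
  check_scalar_number(step_freq_hz, "step_freq_hz", lower = 1, upper = 2)
  check_scalar_number(asymmetry, "asymmetry", lower = 0, upper = 1,
                      strict_upper = TRUE)
  harmonic_amps <- as.matrix(harmonic_amps)
  harmonic_phases <- as.matrix(harmonic_phases)
  if (!identical(dim(harmonic_amps), dim(harmonic_phases))) {
    stop_invalid("harmonic_amps and harmonic_phases must have identical shape")
  }
  if (nrow(harmonic_amps) != 6L) {
    stop_invalid("harmonic signature needs all 6 channels (got %d rows)",
                 nrow(harmonic_amps))
  }
  if (length(noise_sd) != 6L || any(noise_sd < 0)) {
    stop_invalid("noise_sd must be 6 non-negative values")
  }
  if (length(baseline) != 6L || any(!is.finite(baseline))) {
    stop_invalid("baseline must be 6 finite values")
  }
  structure(
    list(subject_id = subject_id, gender = gender,
         age_years = as.integer(age_years), setup = setup,
         step_freq_hz = step_freq_hz,
         harmonic_amps = harmonic_amps, harmonic_phases = harmonic_phases,
         asymmetry = asymmetry, noise_sd = as.numeric(noise_sd),
         baseline = as.numeric(baseline)),
    class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile %s: %s, %d y, setup %s, f=%.3f Hz, K=%d>\n",
              x$subject_id, x$gender, x$age_years, x$setup,
              x$step_freq_hz, ncol(x$harmonic_amps)))
  invisible(x)
}

#' Age-group definitions used for cohort restriction
#'
#' Six decade bins: G1 10-19 y through G6 60-79 y, bounds inclusive.
#'
#' @return data.frame with columns `group`, `lower`, `upper`.
#' @export
age_groups <- function() {
  data.frame(group = paste0("G", 1:6),
             lower = c(10L, 20L, 30L, 40L, 50L, 60L),
             upper = c(19L, 29L, 39L, 49L, 59L, 79L))
}

# Calibrate the underlying (mu, sigma) of a normal truncated to `range` so
# that the truncated distribution's mean/SD approach the targets. Left
# truncation near the target mean makes an exact match impossible for the
# default cohort (best attainable mean ~34.3 at SD 14.8); the deterministic
# Nelder-Mead fit below lands within the documented tolerance. Results are
# memoised per target tuple.
.calibration_cache <- new.env(parent = emptyenv())

truncnorm_calibrate <- function(mean_target, sd_target, range = .AGE_RANGE) {
  key <- paste(mean_target, sd_target, range[1], range[2], sep = "|")
  if (!is.null(.calibration_cache[[key]])) {
    return(.calibration_cache[[key]])
  }
  moments <- function(mu, s) {
    al <- (range[1] - mu) / s
    be <- (range[2] - mu) / s
    Z <- stats::pnorm(be) - stats::pnorm(al)
    if (!is.finite(Z) || Z < 1e-12) return(c(NA_real_, NA_real_))
    m <- mu + s * (stats::dnorm(al) - stats::dnorm(be)) / Z
    v <- s^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / Z -
                  ((stats::dnorm(al) - stats::dnorm(be)) / Z)^2)
    c(m, if (is.finite(v) && v > 0) sqrt(v) else NA_real_)
  }
  obj <- function(p) {
    mm <- moments(p[1], exp(p[2]))
    if (any(is.na(mm))) return(1e9)
    (mm[1] - mean_target)^2 + (mm[2] - sd_target)^2
  }
  fit <- stats::optim(c(mean_target, log(sd_target)), obj,
                      control = list(maxit = 2000, reltol = 1e-12))
  out <- list(mu = fit$par[1], sigma = exp(fit$par[2]), range = range)
  .calibration_cache[[key]] <- out
  out
}

# Inverse-CDF sampler for the truncated normal (deterministic given RNG
# state; no rejection loop).
truncnorm_sample <- function(n, cal) {
  al <- (cal$range[1] - cal$mu) / cal$sigma
  be <- (cal$range[2] - cal$mu) / cal$sigma
  u <- stats::runif(n)
  p <- stats::pnorm(al) + u * (stats::pnorm(be) - stats::pnorm(al))
  cal$mu + cal$sigma * stats::qnorm(p)
}

# Draw one subject's harmonic signature. Amplitudes decay with harmonic
# order k; the dominant amplitude sets the 5% noise floor.
draw_signature <- function(k_harmonics = .K_HARMONICS,
                           noise_frac = 0.05) {
  amps <- matrix(0, nrow = 6L, ncol = k_harmonics)
  phases <- matrix(stats::runif(6L * k_harmonics, 0, 2 * pi),
                   nrow = 6L, ncol = k_harmonics)
  for (c in 1:6) {
    a1 <- .CHANNEL_SCALE[c] * stats::runif(1, 0.5, 1.5)
    amps[c, 1] <- a1
    if (k_harmonics > 1L) {
      for (k in 2:k_harmonics) {
        amps[c, k] <- a1 * stats::runif(1, 0.15, 0.6) / (k - 1)
      }
    }
  }
  list(step_freq_hz = stats::runif(1, 1.0, 2.0),
       harmonic_amps = amps, harmonic_phases = phases,
       asymmetry = stats::runif(1, 0.05, 0.35),
       noise_sd = noise_frac * amps[, 1])
}

#' Generate a synthetic cohort of subject profiles
#'
#' Draws `n_subjects` profiles with demographic composition under the
#' caller's control: a male fraction, target age mean/SD realised through a
#' moment-calibrated truncated normal on `[17, 72]` years, and a fixed count
#' of subjects per acquisition setup. Alternatively `age_group_counts` pins
#' the exact number of subjects per decade age group (see [age_groups()]),
#' ages then drawn uniformly inside each group.
#'
#' Each profile receives an individual harmonic gait signature (stepping
#' frequency uniform in `[1, 2]` Hz, K = 4 harmonic amplitudes and phases per
#' channel, a stride-asymmetry coefficient, and a noise floor at 5% of the
#' dominant amplitude), so any two subjects differ with probability 1.
#'
#' @param n_subjects number of subjects (>= 0).
#' @param male_fraction fraction of males in `[0, 1]`; male count is
#'   `round(male_fraction * n_subjects)`.
#' @param age_mean_sd length-2 numeric, target mean and SD of age in years.
#' @param setup_mix named integer vector over setups `A`, `B`, `C` summing to
#'   `n_subjects`; `NULL` allocates proportionally to the reference 40:20:26
#'   composition.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @param age_group_counts optional named counts over `G1`..`G6` summing to
#'   `n_subjects`, overriding `age_mean_sd`.
#' @param noise_frac per-channel noise SD as a fraction of the dominant
#'   harmonic amplitude (default 0.05).
#' @return list of [subject_profile()] objects.
#' @examples
#' cohort <- make_cohort(10, seed = 1)
#' table(vapply(cohort, `[[`, "", "gender"))
#' @export
make_cohort <- function(n_subjects,
                        male_fraction = 49 / 86,
                        age_mean_sd = c(33.8, 14.8),
                        setup_mix = NULL,
                        seed = 1L,
                        age_group_counts = NULL,
                        noise_frac = 0.05) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L ||
      n_subjects < 0 || n_subjects != round(n_subjects)) {
    stop_invalid("n_subjects must be a non-negative integer")
  }
  n_subjects <- as.integer(n_subjects)
  check_scalar_number(male_fraction, "male_fraction", lower = 0, upper = 1)
  if (n_subjects == 0L) return(list())

  if (is.null(setup_mix)) {
    base <- c(A = 40, B = 20, C = 26) / 86
    setup_mix <- floor(base * n_subjects)
    rem <- n_subjects - sum(setup_mix)
    if (rem > 0) {
      extra <- order(base * n_subjects - setup_mix, decreasing = TRUE)[seq_len(rem)]
      setup_mix[extra] <- setup_mix[extra] + 1
    }
  }
  setup_mix <- setup_mix[c("A", "B", "C")]
  setup_mix[is.na(setup_mix)] <- 0
  names(setup_mix) <- c("A", "B", "C")
  if (sum(setup_mix) != n_subjects) {
    stop_invalid("setup_mix counts sum to %d, expected n_subjects = %d",
                 sum(setup_mix), n_subjects)
  }
  if (!is.null(age_group_counts)) {
    groups <- age_groups()
    age_group_counts <- age_group_counts[groups$group]
    age_group_counts[is.na(age_group_counts)] <- 0
    if (sum(age_group_counts) != n_subjects) {
      stop_invalid("age_group_counts sum to %d, expected %d",
                   sum(age_group_counts), n_subjects)
    }
  }

  with_seed(seed, {
    n_male <- round(male_fraction * n_subjects)
    genders <- sample(rep(c("male", "female"), c(n_male, n_subjects - n_male)))
    setups <- sample(rep(c("A", "B", "C"), setup_mix))
    ages <- if (is.null(age_group_counts)) {
      cal <- truncnorm_calibrate(age_mean_sd[1], age_mean_sd[2])
      round(truncnorm_sample(n_subjects, cal))
    } else {
      groups <- age_groups()
      lo <- pmax(groups$lower, .AGE_RANGE[1])
      hi <- pmin(groups$upper, .AGE_RANGE[2])
      a <- unlist(lapply(seq_len(nrow(groups)), function(g) {
        if (age_group_counts[g] == 0) return(integer(0))
        round(stats::runif(age_group_counts[g], lo[g] - 0.499, hi[g] + 0.499))
      }))
      sample(a)
    }
    width <- max(3L, nchar(as.character(n_subjects)))
    lapply(seq_len(n_subjects), function(i) {
      sig <- draw_signature(noise_frac = noise_frac)
      subject_profile(
        subject_id = sprintf(paste0("S%0", width, "d"), i),
        gender = genders[i], age_years = ages[i], setup = setups[i],
        step_freq_hz = sig$step_freq_hz,
        harmonic_amps = sig$harmonic_amps,
        harmonic_phases = sig$harmonic_phases,
        asymmetry = sig$asymmetry, noise_sd = sig$noise_sd)
    })
  })
}

#' Construct an IMU stream object
#'
#' @param subject a [subject_profile()].
#' @param rate_hz sampling rate in Hz (> 0).
#' @param samples numeric matrix `(n_frames x 6)`, channel order per
#'   [imu_channels()]; all values finite.
#' @param condition free-text acquisition tag (surface type or
#'   `"faked-gait"`).
#' @return object of class `imu_stream`.
#' @export
imu_stream <- function(subject, rate_hz, samples, condition = "baseline") {
  stopifnot(inherits(subject, "subject_profile"))
  check_scalar_number(rate_hz, "rate_hz", lower = 0, strict_lower = TRUE)
  samples <- as.matrix(samples)
  if (ncol(samples) != 6L) {
    stop_invalid("samples must have 6 channels (got %d)", ncol(samples))
  }
  if (!all(is.finite(samples))) {
    stop_invalid("samples contain non-finite values")
  }
  colnames(samples) <- imu_channels()
  structure(list(subject = subject, rate_hz = rate_hz, samples = samples,
                 condition = condition),
            class = "imu_stream")
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream %s: %d frames @ %g Hz (%.1f s), condition '%s'>\n",
              x$subject$subject_id, nrow(x$samples), x$rate_hz,
              nrow(x$samples) / x$rate_hz, x$condition))
  invisible(x)
}

#' Simulate a 6-channel inertial walking recording
#'
#' Synthesises the quasi-periodic chest IMU signal of one subject walking at
#' their stepping frequency f. Per channel c the sample at time t is
#' \deqn{s_c(t) = b_c + \sum_{k=1}^{K} A_{c,k} \cos(2\pi k f t + \phi_{c,k})
#'   + \alpha A_{c,1} \cos(\pi f t) + \epsilon_c(t)}
#' with baseline \eqn{b_c}, asymmetry \eqn{\alpha} and Gaussian noise
#' \eqn{\epsilon_c}. The asymmetry term has period `2/f` — one stride — so
#' stride-length windows carry information that single steps do not.
#'
#' @param profile a [subject_profile()].
#' @param duration_s recording length in seconds (> 0).
#' @param rate_hz sampling rate in Hz (default 75).
#' @param seed integer seed for the noise draws.
#' @param condition tag stored on the stream.
#' @return an [imu_stream()] with `round(duration_s * rate_hz)` frames.
#' @examples
#' p <- make_cohort(1, seed = 3)[[1]]
#' s <- simulate_recording(p, duration_s = 10, rate_hz = 75, seed = 1)
#' nrow(s$samples)  # 750
#' @export
simulate_recording <- function(profile, duration_s, rate_hz = 75,
                               seed = 1L, condition = "baseline") {
  stopifnot(inherits(profile, "subject_profile"))
  check_scalar_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_scalar_number(rate_hz, "rate_hz", lower = 0, strict_lower = TRUE)
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  f <- profile$step_freq_hz
  K <- ncol(profile$harmonic_amps)
  samples <- with_seed(seed, {
    out <- matrix(0, nrow = n, ncol = 6L)
    for (c in 1:6) {
      s <- rep(profile$baseline[c], n)
      for (k in seq_len(K)) {
        s <- s + profile$harmonic_amps[c, k] *
          cos(2 * pi * k * f * t + profile$harmonic_phases[c, k])
      }
      s <- s + profile$asymmetry * profile$harmonic_amps[c, 1] *
        cos(pi * f * t)
      if (profile$noise_sd[c] > 0) {
        s <- s + stats::rnorm(n, sd = profile$noise_sd[c])
      }
      out[, c] <- s
    }
    out
  })
  log_info("simulate: subject %s, %d frames @ %g Hz", profile$subject_id,
           n, rate_hz)
  imu_stream(profile, rate_hz, samples, condition)
}

#' Simulate recordings for a whole cohort
#'
#' One stream per subject, with per-subject seeds derived from `seed`.
#'
#' @param cohort list of [subject_profile()] objects.
#' @param duration_s per-subject recording length in seconds (default 90).
#' @param rate_hz sampling rate in Hz.
#' @param seed integer global seed.
#' @return list of [imu_stream()] objects.
#' @export
simulate_cohort <- function(cohort, duration_s = 90, rate_hz = 75,
                            seed = 1L) {
  streams <- lapply(cohort, function(p) {
    simulate_recording(p, duration_s, rate_hz,
                       seed = derive_seed(seed, paste0("sim:", p$subject_id)))
  })
  log_info("simulate_cohort: %d subjects -> %d streams", length(cohort),
           length(streams))
  streams
}

#' Perturb a recording with surface change or gait forgery
#'
#' Two perturbation families emulate the acquisition variations of walking
#' on different surfaces and of subjects deliberately faking their gait:
#' * `surface`: per-channel amplitude rescaling about the channel mean plus
#'   extra Gaussian noise, both proportional to `magnitude`.
#' * `faked-gait`: a global tempo change plus segment-wise phase jitter,
#'   applied by resampling the signal along a warped time axis; the output
#'   keeps the input's length.
#'
#' `magnitude = 0` returns the input stream unchanged.
#'
#' @param stream an [imu_stream()].
#' @param kind `"surface"` or `"faked-gait"`.
#' @param magnitude non-negative perturbation strength (0.1-0.3 typical).
#' @param seed integer seed.
#' @return a perturbed [imu_stream()] of identical dimensions.
#' @export
inject_perturbation <- function(stream, kind, magnitude, seed = 1L) {
  stopifnot(inherits(stream, "imu_stream"))
  if (!is.character(kind) || length(kind) != 1L ||
      !kind %in% c("surface", "faked-gait")) {
    stop_invalid("unknown perturbation kind '%s' (use 'surface' or 'faked-gait')",
                 paste(kind, collapse = ","))
  }
  check_scalar_number(magnitude, "magnitude", lower = 0)
  if (magnitude == 0) return(stream)
  x <- stream$samples
  n <- nrow(x)
  out <- with_seed(seed, {
    if (kind == "surface") {
      gain <- 1 + magnitude * stats::runif(6L, 0.5, 1)
      y <- x
      for (c in 1:6) {
        mu <- mean(x[, c])
        y[, c] <- mu + gain[c] * (x[, c] - mu) +
          stats::rnorm(n, sd = magnitude * stats::sd(x[, c]))
      }
      y
    } else {
      # Gait forgery: one tempo factor for the whole stream (frequency
      # scales by `tempo`), plus independent phase offsets per ~2 s segment.
      t_orig <- (seq_len(n) - 1) / stream$rate_hz
      tempo <- 1 + magnitude * sample(c(-1, 1), 1L) * stats::runif(1, 0.5, 1)
      seg_len <- max(1L, round(2 * stream$rate_hz))
      seg_id <- (seq_len(n) - 1) %/% seg_len
      jitter <- stats::runif(max(seg_id) + 1L, -0.25, 0.25) * magnitude
      t_warp <- t_orig * tempo + jitter[seg_id + 1L]
      t_warp <- pmin(pmax(t_warp, 0), t_orig[n])
      y <- x
      for (c in 1:6) {
        y[, c] <- stats::approx(t_orig, x[, c], xout = t_warp,
                                rule = 2)$y
      }
      y
    }
  })
  log_info("perturb: %s magnitude %.3g on %s", kind, magnitude,
           stream$subject$subject_id)
  imu_stream(stream$subject, stream$rate_hz, out,
             condition = if (kind == "surface") "surface" else "faked-gait")
}

#' Write a stream as CSV plus JSON sidecar
#'
#' The CSV has header `t,acc_x,acc_y,acc_z,gyro_x,gyro_y,gyro_z`; the sidecar
#' `<prefix>.json` records subject id, gender, age, setup, sampling rate and
#' condition.
#'
#' @param stream an [imu_stream()].
#' @param prefix path prefix; writes `<prefix>.csv` and `<prefix>.json`.
#' @return the CSV path, invisibly.
#' @export
write_stream <- function(stream, prefix) {
  stopifnot(inherits(stream, "imu_stream"))
  df <- data.frame(t = (seq_len(nrow(stream$samples)) - 1) / stream$rate_hz,
                   stream$samples)
  csv <- paste0(prefix, ".csv")
  utils::write.csv(df, csv, row.names = FALSE)
  meta <- list(subject_id = stream$subject$subject_id,
               gender = stream$subject$gender,
               age_years = stream$subject$age_years,
               setup = stream$subject$setup,
               rate_hz = stream$rate_hz,
               condition = stream$condition)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(csv)
}

#' Read a stream written by [write_stream()]
#'
#' Rebuilds an [imu_stream()] from `<prefix>.csv` and `<prefix>.json`. The
#' harmonic signature is not serialized, so the embedded profile carries a
#' placeholder signature alongside the true metadata.
#'
#' @param prefix path prefix used when writing.
#' @return an [imu_stream()].
#' @export
read_stream <- function(prefix) {
  csv <- paste0(prefix, ".csv")
  js <- paste0(prefix, ".json")
  if (!file.exists(csv) || !file.exists(js)) {
    stop_invalid("missing stream files for prefix '%s'", prefix)
  }
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  df <- utils::read.csv(csv)
  prof <- subject_profile(
    subject_id = meta$subject_id, gender = meta$gender,
    age_years = meta$age_years, setup = meta$setup,
    step_freq_hz = 1.5,
    harmonic_amps = matrix(0, 6, 1), harmonic_phases = matrix(0, 6, 1),
    asymmetry = 0, noise_sd = rep(0, 6))
  imu_stream(prof, meta$rate_hz, as.matrix(df[, imu_channels()]),
             condition = meta$condition)
}
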