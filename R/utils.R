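#' @keywords internal
"_PACKAGE"

# Modulus for derived seeds: largest prime < 2^31 so every derived seed is a
# valid R integer.
.SEED_MOD <- 2147483647

#' Derive a stage-specific seed from a global seed
#'
#' One global experiment seed fans out to independent per-stage seeds so that
#' reconfiguring one pipeline stage (say, the segmentation hop) does not
#' perturb the random draws of another. The derivation is a small polynomial
#' rolling hash of the stage name folded together with the global seed,
#' reduced modulo a prime below 2^31.
#'
#' @param seed integer global seed.
#' @param stage character scalar naming the pipeline stage.
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "simulate")
#' derive_seed(1, "train")
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L, nchar(stage) > 0L)
  seed <- as.double(seed) %% .SEED_MOD
  h <- 17
  for (b in utf8ToInt(stage)) {
    h <- (h * 31 + b) %% .SEED_MOD
  }
  h <- (h * 2654435 + seed + 1) %% .SEED_MOD
  as.integer(h %% (.SEED_MOD - 2) + 1)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded package internals never disturb user-level randomness.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Toggle pipeline stage logging
#'
#' Every pipeline stage reports its input/output cardinalities (streams,
#' windows, classes) through [message()] when logging is enabled via
#' `options(gaitreid.verbose = TRUE)` or this helper.
#'
#' @param on logical; enable or disable logging.
#' @return the previous setting, invisibly.
#' @export
gaitreid_verbose <- function(on = TRUE) {
  old <- getOption("gaitreid.verbose", FALSE)
  options(gaitreid.verbose = isTRUE(on))
  invisible(old)
}

log_info <- function(fmt, ...) {
  if (isTRUE(getOption("gaitreid.verbose", FALSE))) {
    message(sprintf(paste0("[gaitreid] ", fmt), ...))
  }
  invisible(NULL)
}

stop_invalid <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("'%s' must be a single finite number", name)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_invalid("'%s' = %g is outside its valid range %s%g, %g%s", name, x,
                 if (strict_lower) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]")
  }
  invisible(x)
}

#' IMU channel names
#'
#' Fixed channel order used throughout the package: triaxial acceleration in
#' m/s^2 followed by triaxial angular velocity in rad/s.
#'
#' @return character vector of the six channel names.
#' @export
imu_channels <- function() {
  c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
}
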