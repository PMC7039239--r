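# Robust per-channel scaling: subtract the median, divide by the
# interquartile range. Fit on training windows only; raw signals otherwise
# untouched (no smoothing, filtering or gravity removal).

#' Fit a robust scaler on training windows
#'
#' Pools all frames of all training windows per channel and computes the
#' median and the interquartile range IQR = Q3 - Q1 with linear-interpolation
#' (type 7) quantiles. A zero IQR on a degenerate channel is replaced by
#' `epsilon` so the transform never divides by zero.
#'
#' @param train_windows a `gait_windows` object (training partition only).
#' @param epsilon substitute for a zero IQR (default 1e-9).
#' @return object of class `scaler_params` with fields `median`, `iqr`
#'   (length-6 each) and `epsilon`.
#' @examples
#' p <- make_cohort(1, seed = 5)[[1]]
#' w <- segment_stream(simulate_recording(p, 10, 75, seed = 1), "step")
#' fit_scaler(w)
#' @export
fit_scaler <- function(train_windows, epsilon = 1e-9) {
  stopifnot(inherits(train_windows, "gait_windows"))
  if (n_windows(train_windows) < 1L) {
    stop_invalid("fit_scaler needs at least one training window")
  }
  check_scalar_number(epsilon, "epsilon", lower = 0, strict_lower = TRUE)
  med <- numeric(6L)
  iqr <- numeric(6L)
  for (c in 1:6) {
    v <- as.vector(train_windows$data[, , c])
    med[c] <- stats::median(v)
    q <- stats::quantile(v, probs = c(0.25, 0.75), names = FALSE, type = 7)
    iqr[c] <- q[2] - q[1]
  }
  iqr[iqr == 0] <- epsilon
  names(med) <- names(iqr) <- imu_channels()
  log_info("fit_scaler: pooled %d windows x %d frames",
           n_windows(train_windows), train_windows$window_len)
  structure(list(median = med, iqr = iqr, epsilon = epsilon),
            class = "scaler_params")
}

#' @export
print.scaler_params <- function(x, ...) {
  cat("<scaler_params>\n")
  print(rbind(median = x$median, iqr = x$iqr))
  invisible(x)
}

#' Apply a fitted robust scaler to windows
#'
#' Per channel c, every value x becomes `(x - median_c) / iqr_c`. Shapes and
#' labels are unchanged.
#'
#' @param params a `scaler_params` object from [fit_scaler()].
#' @param windows a `gait_windows` object.
#' @return a scaled `gait_windows` object.
#' @export
apply_scaler <- function(params, windows) {
  stopifnot(inherits(params, "scaler_params"),
            inherits(windows, "gait_windows"))
  if (dim(windows$data)[3] != length(params$median)) {
    stop_invalid("channel count mismatch: scaler has %d, windows have %d",
                 length(params$median), dim(windows$data)[3])
  }
  data <- windows$data
  for (c in 1:6) {
    data[, , c] <- (data[, , c] - params$median[c]) / params$iqr[c]
  }
  new_gait_windows(data, windows$info, windows$kind, windows$window_len,
                   windows$rate_hz)
}

#' Serialize scaler parameters to JSON
#'
#' @param params a `scaler_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scaler <- function(params, path) {
  stopifnot(inherits(params, "scaler_params"))
  jsonlite::write_json(
    list(median = unname(params$median), iqr = unname(params$iqr),
         epsilon = params$epsilon),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read scaler parameters written by [write_scaler()]
#'
#' @param path JSON file path.
#' @return a `scaler_params` object.
#' @export
read_scaler <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  med <- as.numeric(x$median)
  iqr <- as.numeric(x$iqr)
  names(med) <- names(iqr) <- imu_channels()
  structure(list(median = med, iqr = iqr, epsilon = x$epsilon),
            class = "scaler_params")
}
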