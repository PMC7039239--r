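# Fixed-grid step/stride windowing of continuous 6D streams.
#
# At a 75 Hz sampling rate and a normal stepping frequency of 1-2 Hz, 100
# samples span roughly one step and 200 samples roughly one stride, so
# windows are cut blindly on a fixed grid with no heel-strike detection.

.WINDOW_LEN <- c(step = 100L, stride = 200L)

#' Window length for a segmentation kind
#'
#' @param kind `"step"` (100 samples) or `"stride"` (200 samples).
#' @return integer window length.
#' @export
window_length <- function(kind = c("step", "stride")) {
  .WINDOW_LEN[[match.arg(kind)]]
}

new_gait_windows <- function(data, info, kind, window_len, rate_hz) {
  stopifnot(length(dim(data)) == 3L, dim(data)[2] == window_len,
            dim(data)[3] == 6L, nrow(info) == dim(data)[1])
  structure(list(data = data, info = info, kind = kind,
                 window_len = as.integer(window_len), rate_hz = rate_hz),
            class = "gait_windows")
}

#' Number of windows in a `gait_windows` container
#' @param windows a `gait_windows` object.
#' @return integer count.
#' @export
n_windows <- function(windows) {
  stopifnot(inherits(windows, "gait_windows"))
  dim(windows$data)[1]
}

#' @export
print.gait_windows <- function(x, ...) {
  cat(sprintf("<gait_windows: %d %s windows (%d x 6), %d subjects>\n",
              n_windows(x), x$kind, x$window_len,
              length(unique(x$info$subject_id))))
  invisible(x)
}

#' Subset windows by index
#'
#' @param x a `gait_windows` object.
#' @param i integer or logical index over windows.
#' @param ... ignored.
#' @return a `gait_windows` object holding the selected windows.
#' @export
`[.gait_windows` <- function(x, i, ...) {
  data <- x$data[i, , , drop = FALSE]
  info <- x$info[i, , drop = FALSE]
  rownames(info) <- NULL
  new_gait_windows(data, info, x$kind, x$window_len, x$rate_hz)
}

#' Extract one window's sample matrix
#'
#' @param windows a `gait_windows` object.
#' @param i window index.
#' @return numeric matrix `(window_len x 6)`.
#' @export
window_matrix <- function(windows, i) {
  stopifnot(inherits(windows, "gait_windows"), length(i) == 1L,
            i >= 1, i <= n_windows(windows))
  m <- windows$data[i, , ]
  dim(m) <- c(windows$window_len, 6L)
  colnames(m) <- imu_channels()
  m
}

#' Concatenate window containers
#'
#' @param ... `gait_windows` objects of one kind and sampling rate.
#' @return a single combined `gait_windows` object.
#' @export
combine_windows <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "gait_windows")) {
    parts <- parts[[1]]
  }
  parts <- Filter(function(w) n_windows(w) > 0L, parts)
  stopifnot(length(parts) >= 1L)
  kind <- parts[[1]]$kind
  L <- parts[[1]]$window_len
  rate <- parts[[1]]$rate_hz
  for (w in parts) {
    if (!identical(w$kind, kind) || w$rate_hz != rate) {
      stop_invalid("cannot combine windows of mixed kind or sampling rate")
    }
  }
  n_tot <- sum(vapply(parts, n_windows, 1L))
  data <- array(0, dim = c(n_tot, L, 6L))
  at <- 0L
  for (w in parts) {
    nw <- n_windows(w)
    data[at + seq_len(nw), , ] <- w$data
    at <- at + nw
  }
  info <- do.call(rbind, lapply(parts, `[[`, "info"))
  rownames(info) <- NULL
  new_gait_windows(data, info, kind, L, rate)
}

# Window count under fixed-grid enumeration with trailing partials dropped.
count_windows <- function(n_frames, L, hop) {
  if (n_frames < L) 0L else as.integer((n_frames - L) %/% hop + 1L)
}

#' Segment a stream into fixed-length gait windows
#'
#' Windows are enumerated at start frames `0, hop, 2*hop, ...` (0-based,
#' half-open ranges `[start, start + L)`); a trailing partial window is
#' dropped. `L` is 100 samples for steps and 200 for strides.
#'
#' @param stream an [imu_stream()].
#' @param kind `"step"` or `"stride"`.
#' @param hop integer hop between window starts (>= 1); defaults to the
#'   window length, i.e. non-overlapping tiling.
#' @return a `gait_windows` container; possibly with zero windows when the
#'   stream is shorter than one window.
#' @examples
#' p <- make_cohort(1, seed = 2)[[1]]
#' s <- simulate_recording(p, duration_s = 10, rate_hz = 75, seed = 1)
#' n_windows(segment_stream(s, "step"))  # floor(750 / 100) = 7
#' @export
segment_stream <- function(stream, kind = c("step", "stride"), hop = NULL) {
  stopifnot(inherits(stream, "imu_stream"))
  kind <- match.arg(kind)
  L <- .WINDOW_LEN[[kind]]
  if (is.null(hop)) hop <- L
  if (!is.numeric(hop) || length(hop) != 1L || hop < 1 ||
      hop != round(hop)) {
    stop_invalid("hop must be a positive integer (got %s)",
                 paste(hop, collapse = ","))
  }
  hop <- as.integer(hop)
  n <- nrow(stream$samples)
  if (n == 0L) stop_invalid("cannot segment an empty stream")
  k <- count_windows(n, L, hop)
  data <- array(0, dim = c(k, L, 6L))
  starts <- integer(k)
  if (k > 0L) {
    for (j in seq_len(k)) {
      s0 <- (j - 1L) * hop
      starts[j] <- s0
      data[j, , ] <- stream$samples[s0 + seq_len(L), ]
    }
  }
  prof <- stream$subject
  info <- data.frame(
    subject_id = rep(prof$subject_id, k),
    kind = rep(kind, k),
    start_frame = starts,
    gender = rep(prof$gender, k),
    age_years = rep(prof$age_years, k),
    setup = rep(prof$setup, k),
    condition = rep(stream$condition, k),
    stringsAsFactors = FALSE)
  log_info("segment: %s -> %d %s windows (hop %d)", prof$subject_id, k,
           kind, hop)
  new_gait_windows(data, info, kind, L, stream$rate_hz)
}

#' Segment a list of streams into one window container
#'
#' @param streams list of [imu_stream()] objects sharing one sampling rate.
#' @inheritParams segment_stream
#' @return a combined `gait_windows` container.
#' @export
segment_corpus <- function(streams, kind = c("step", "stride"), hop = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(streams) >= 1L)
  rates <- vapply(streams, `[[`, 1.0, "rate_hz")
  if (length(unique(rates)) != 1L) {
    stop_invalid("streams have mixed sampling rates: %s",
                 paste(unique(rates), collapse = ", "))
  }
  out <- combine_windows(lapply(streams, segment_stream, kind = kind,
                                hop = hop))
  log_info("segment_corpus: %d streams -> %d %s windows", length(streams),
           n_windows(out), kind)
  out
}

#' Frame and window census of a corpus
#'
#' Counts total frames and the step and stride windows obtainable from each
#' stream without materialising the windows. With `hop_step = hop_stride / 2`
#' and every stream length a multiple of 200, steps are exactly twice the
#' strides.
#'
#' @param streams list of [imu_stream()] objects sharing one sampling rate.
#' @param hop_step hop for step windows (default 100, non-overlapping).
#' @param hop_stride hop for stride windows (default 200, non-overlapping).
#' @return list with `n_frames_total`, `n_steps`, `n_strides`.
#' @export
window_census <- function(streams, hop_step = 100L, hop_stride = 200L) {
  stopifnot(length(streams) >= 1L)
  rates <- vapply(streams, `[[`, 1.0, "rate_hz")
  if (length(unique(rates)) != 1L) {
    stop_invalid("streams have mixed sampling rates: %s",
                 paste(unique(rates), collapse = ", "))
  }
  if (hop_step < 1L || hop_stride < 1L) stop_invalid("hops must be >= 1")
  lens <- vapply(streams, function(s) nrow(s$samples), 1L)
  res <- list(
    n_frames_total = sum(as.double(lens)),
    n_steps = sum(vapply(lens, count_windows, 1L, L = .WINDOW_LEN[["step"]],
                         hop = as.integer(hop_step))),
    n_strides = sum(vapply(lens, count_windows, 1L,
                           L = .WINDOW_LEN[["stride"]],
                           hop = as.integer(hop_stride))))
  log_info("census: %d streams, %.0f frames, %d steps, %d strides",
           length(streams), res$n_frames_total, res$n_steps, res$n_strides)
  res
}

#' Write a window container to disk
#'
#' Stores the window array as a flat little-endian double binary file plus a
#' CSV manifest (one row per window: index, subject, kind, start frame,
#' gender, age, setup, condition) and a JSON header with the array shape.
#'
#' @param windows a `gait_windows` object.
#' @param prefix path prefix; writes `<prefix>.bin`, `<prefix>.csv`,
#'   `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_windows <- function(windows, prefix) {
  stopifnot(inherits(windows, "gait_windows"))
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(windows$data), con, size = 8L, endian = "little")
  manifest <- cbind(window = seq_len(n_windows(windows)), windows$info)
  utils::write.csv(manifest, paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(shape = dim(windows$data), kind = windows$kind,
         window_len = windows$window_len, rate_hz = windows$rate_hz),
    paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' Read a window container written by [write_windows()]
#'
#' @param prefix path prefix used when writing.
#' @return a `gait_windows` object.
#' @export
read_windows <- function(prefix) {
  hdr <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  shape <- as.integer(hdr$shape)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "double", n = prod(shape), size = 8L,
                  endian = "little")
  data <- array(vals, dim = shape)
  manifest <- utils::read.csv(paste0(prefix, ".csv"),
                              stringsAsFactors = FALSE)
  info <- manifest[, setdiff(names(manifest), "window"), drop = FALSE]
  new_gait_windows(data, info, hdr$kind, hdr$window_len, hdr$rate_hz)
}
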