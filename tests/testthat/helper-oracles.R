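# Independent oracles. These deliberately avoid the package's vectorized
# code paths: scalar loops and exhaustive enumeration only.

# GRU step evaluated entry by entry with explicit loops over hidden and
# input indices — no matrix products, no vectorized arithmetic.
oracle_gru_step <- function(params, x_t, h_prev) {
  H <- params$n_hidden
  D <- params$n_input
  sig <- function(v) 1 / (1 + exp(-v))
  r <- numeric(H)
  z <- numeric(H)
  cand <- numeric(H)
  h <- numeric(H)
  for (i in seq_len(H)) {
    ar <- params$b_r[i]
    az <- params$b_z[i]
    for (j in seq_len(D)) {
      ar <- ar + params$W_xr[i, j] * x_t[j]
      az <- az + params$W_xz[i, j] * x_t[j]
    }
    for (j in seq_len(H)) {
      ar <- ar + params$W_hr[i, j] * h_prev[j]
      az <- az + params$W_hz[i, j] * h_prev[j]
    }
    r[i] <- sig(ar)
    z[i] <- sig(az)
  }
  for (i in seq_len(H)) {
    ac <- params$b_h[i]
    for (j in seq_len(D)) {
      ac <- ac + params$W_xh[i, j] * x_t[j]
    }
    for (j in seq_len(H)) {
      ac <- ac + params$W_hh[i, j] * (r[j] * h_prev[j])
    }
    cand[i] <- tanh(ac)
    h[i] <- z[i] * h_prev[i] + (1 - z[i]) * cand[i]
  }
  list(r_t = r, z_t = z, h_cand = cand, h_t = h)
}

# Rank of the true class by exhaustive counting: walk every other class and
# count strictly-greater scores, breaking ties toward lower class index.
oracle_rank <- function(scores_row, true_idx) {
  rank <- 1L
  for (j in seq_along(scores_row)) {
    if (j == true_idx) next
    if (scores_row[j] > scores_row[true_idx] ||
        (scores_row[j] == scores_row[true_idx] && j < true_idx)) {
      rank <- rank + 1L
    }
  }
  rank
}

oracle_cmc <- function(scores, truths) {
  C <- ncol(scores)
  ranks <- vapply(seq_len(nrow(scores)),
                  function(q) oracle_rank(scores[q, ], truths[q]), 1L)
  vapply(seq_len(C), function(k) mean(ranks <= k), 1.0)
}

oracle_map <- function(scores, truths) {
  ranks <- vapply(seq_len(nrow(scores)),
                  function(q) oracle_rank(scores[q, ], truths[q]), 1L)
  100 * mean(1 / ranks)
}

# Explicit autocorrelation scan: lag (in samples) maximising the centered
# autocorrelation over lags 1..max_lag.
oracle_dominant_lag <- function(x, max_lag = 200L) {
  x <- x - mean(x)
  n <- length(x)
  best_lag <- 1L
  best_val <- -Inf
  for (lag in seq_len(max_lag)) {
    v <- sum(x[1:(n - lag)] * x[(lag + 1):n]) / (n - lag)
    if (v > best_val) {
      best_val <- v
      best_lag <- lag
    }
  }
  best_lag
}

# Brute-force window enumeration for the segmentation count formula.
oracle_window_count <- function(n_frames, L, hop) {
  count <- 0L
  start <- 0L
  while (start + L <= n_frames) {
    count <- count + 1L
    start <- start + hop
  }
  count
}
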