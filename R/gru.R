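# Reference gated-recurrent-unit cell.
#
# The cell computes, with sigmoid gates and elementwise products:
#   r_t = sigm(W_xr x_t + W_hr h_{t-1} + b_r)        (reset gate)
#   z_t = sigm(W_xz x_t + W_hz h_{t-1} + b_z)        (update gate)
#   h~_t = tanh(W_xh x_t + W_hh (r_t * h_{t-1}) + b_h)  (candidate)
#   h_t = z_t * h_{t-1} + (1 - z_t) * h~_t           (convex update)
#
# This exported cell is the verification reference; the trainable network in
# network.R uses a batched layout and is tied to this cell by equivalence
# tests.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Construct GRU cell parameters
#'
#' Nine arrays: three input-to-gate matrices (`hidden x input`), three
#' recurrent matrices (`hidden x hidden`) and three bias vectors (`hidden`),
#' for the reset gate (`r`), update gate (`z`) and candidate activation
#' (`h`).
#'
#' @param W_xr,W_xz,W_xh input weight matrices, `hidden x input`.
#' @param W_hr,W_hz,W_hh recurrent weight matrices, `hidden x hidden`.
#' @param b_r,b_z,b_h bias vectors of length `hidden`.
#' @return object of class `gru_cell_params`.
#' @seealso [random_gru_cell()] for seeded random initialization.
#' @export
gru_cell_params <- function(W_xr, W_xz, W_xh, W_hr, W_hz, W_hh,
                            b_r, b_z, b_h) {
  mats <- list(W_xr = W_xr, W_xz = W_xz, W_xh = W_xh,
               W_hr = W_hr, W_hz = W_hz, W_hh = W_hh)
  mats <- lapply(mats, as.matrix)
  vecs <- list(b_r = as.numeric(b_r), b_z = as.numeric(b_z),
               b_h = as.numeric(b_h))
  H <- nrow(mats$W_xr)
  D <- ncol(mats$W_xr)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    want_cols <- if (grepl("^W_x", nm)) D else H
    if (nrow(m) != H || ncol(m) != want_cols) {
      stop_invalid("'%s' must be %d x %d (got %d x %d)", nm, H, want_cols,
                   nrow(m), ncol(m))
    }
    if (!all(is.finite(m))) stop_invalid("'%s' has non-finite entries", nm)
  }
  for (nm in names(vecs)) {
    if (length(vecs[[nm]]) != H || !all(is.finite(vecs[[nm]]))) {
      stop_invalid("'%s' must be %d finite values", nm, H)
    }
  }
  structure(c(mats, vecs, list(n_hidden = H, n_input = D)),
            class = "gru_cell_params")
}

#' Random fan-in-scaled GRU cell
#'
#' All weights uniform on `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`, biases zero;
#' deterministic under a fixed seed.
#'
#' @param n_input input dimension.
#' @param n_hidden hidden dimension.
#' @param seed integer seed.
#' @return a [gru_cell_params()] object.
#' @export
random_gru_cell <- function(n_input, n_hidden, seed = 1L) {
  with_seed(seed, {
    rnd <- function(nr, nc, fan) {
      matrix(stats::runif(nr * nc, -1 / sqrt(fan), 1 / sqrt(fan)), nr, nc)
    }
    gru_cell_params(
      W_xr = rnd(n_hidden, n_input, n_input),
      W_xz = rnd(n_hidden, n_input, n_input),
      W_xh = rnd(n_hidden, n_input, n_input),
      W_hr = rnd(n_hidden, n_hidden, n_hidden),
      W_hz = rnd(n_hidden, n_hidden, n_hidden),
      W_hh = rnd(n_hidden, n_hidden, n_hidden),
      b_r = numeric(n_hidden), b_z = numeric(n_hidden),
      b_h = numeric(n_hidden))
  })
}

#' One GRU timestep with full gate trace
#'
#' Evaluates the reset gate, update gate, candidate activation and new hidden
#' state for one input vector, returning every intermediate quantity for
#' testability.
#'
#' @param params a [gru_cell_params()] object.
#' @param x_t input vector of length `n_input`.
#' @param h_prev previous hidden state, length `n_hidden`.
#' @param activation candidate nonlinearity, `"tanh"` (default) or `"relu"`.
#' @return object of class `gru_step_trace` with fields `x_t`, `h_prev`,
#'   `r_t`, `z_t` (both in `(0,1)`), `h_cand` (in `(-1,1)` for tanh) and
#'   `h_t = z_t * h_prev + (1 - z_t) * h_cand`.
#' @examples
#' cell <- random_gru_cell(3, 2, seed = 7)
#' tr <- gru_cell_step(cell, c(0.1, -0.2, 0.3), c(0, 0))
#' tr$h_t
#' @export
gru_cell_step <- function(params, x_t, h_prev,
                          activation = c("tanh", "relu")) {
  stopifnot(inherits(params, "gru_cell_params"))
  activation <- match.arg(activation)
  x_t <- as.numeric(x_t)
  h_prev <- as.numeric(h_prev)
  if (length(x_t) != params$n_input) {
    stop_invalid("x_t has length %d, expected %d", length(x_t),
                 params$n_input)
  }
  if (length(h_prev) != params$n_hidden) {
    stop_invalid("h_prev has length %d, expected %d", length(h_prev),
                 params$n_hidden)
  }
  if (!all(is.finite(x_t)) || !all(is.finite(h_prev))) {
    stop_invalid("non-finite inputs to gru_cell_step")
  }
  r_t <- sigmoid(drop(params$W_xr %*% x_t + params$W_hr %*% h_prev) +
                   params$b_r)
  z_t <- sigmoid(drop(params$W_xz %*% x_t + params$W_hz %*% h_prev) +
                   params$b_z)
  a_c <- drop(params$W_xh %*% x_t + params$W_hh %*% (r_t * h_prev)) +
    params$b_h
  h_cand <- if (activation == "tanh") tanh(a_c) else pmax(a_c, 0)
  h_t <- z_t * h_prev + (1 - z_t) * h_cand
  structure(list(x_t = x_t, h_prev = h_prev, r_t = r_t, z_t = z_t,
                 h_cand = h_cand, h_t = h_t),
            class = "gru_step_trace")
}

#' Run a GRU cell over a whole sequence
#'
#' Iterates [gru_cell_step()] from `h_0 = 0`, collecting hidden states.
#'
#' @inheritParams gru_cell_step
#' @param x matrix `(T x n_input)`, one row per timestep.
#' @param h0 initial hidden state (default zeros).
#' @return matrix `(T x n_hidden)` of hidden states.
#' @export
gru_sequence <- function(params, x, h0 = NULL,
                         activation = c("tanh", "relu")) {
  stopifnot(inherits(params, "gru_cell_params"))
  activation <- match.arg(activation)
  x <- as.matrix(x)
  h <- if (is.null(h0)) numeric(params$n_hidden) else as.numeric(h0)
  out <- matrix(0, nrow(x), params$n_hidden)
  for (t in seq_len(nrow(x))) {
    h <- gru_cell_step(params, x[t, ], h, activation)$h_t
    out[t, ] <- h
  }
  out
}

#' Build a random bidirectional GRU stack
#'
#' A stack is a list of layers; each layer holds a `forward` and a `backward`
#' [gru_cell_params()]. Layer 1 consumes the 6-channel input, deeper layers
#' consume the previous layer's `2 * n_units` feature sequence.
#'
#' @param n_input input dimension of layer 1.
#' @param n_units hidden units per direction.
#' @param n_layers number of stacked bidirectional layers.
#' @param seed integer seed.
#' @return list of layers, class `gru_stack`.
#' @export
random_gru_stack <- function(n_input = 6L, n_units = 512L, n_layers = 2L,
                             seed = 1L) {
  layers <- vector("list", n_layers)
  d <- n_input
  for (l in seq_len(n_layers)) {
    layers[[l]] <- list(
      forward = random_gru_cell(d, n_units,
                                seed = derive_seed(seed, sprintf("L%d.f", l))),
      backward = random_gru_cell(d, n_units,
                                 seed = derive_seed(seed, sprintf("L%d.b", l))))
    d <- 2L * n_units
  }
  structure(layers, class = "gru_stack")
}

#' Bidirectional forward pass over one window
#'
#' Runs every layer's forward cell over t = 1..T and its backward cell over
#' the time-reversed window, concatenating the two hidden sequences per
#' timestep, so a layer with `n` units emits `2n` features per timestep.
#' Layer 2 consumes layer 1's output sequence. This is the per-window
#' reference path built on [gru_cell_step()]; training uses an equivalent
#' batched implementation.
#'
#' @param stack a `gru_stack` (list of layers with `forward`/`backward`
#'   cells).
#' @param window numeric matrix `(window_len x n_input)`, a scaled gait
#'   window.
#' @param config optional `model_config`; when given, the window length is
#'   checked against `config$window_len` and the candidate activation is
#'   taken from `config$activation`.
#' @return feature matrix `(window_len x 2 * n_units)`.
#' @export
bidirectional_forward <- function(stack, window, config = NULL) {
  window <- as.matrix(window)
  activation <- "tanh"
  if (!is.null(config)) {
    if (nrow(window) != config$window_len) {
      stop_invalid("window has %d timesteps, config expects %d",
                   nrow(window), config$window_len)
    }
    activation <- config$activation
  }
  x <- window
  for (layer in stack) {
    h_fwd <- gru_sequence(layer$forward, x, activation = activation)
    h_bwd <- gru_sequence(layer$backward, x[rev(seq_len(nrow(x))), ,
                                            drop = FALSE],
                          activation = activation)
    x <- cbind(h_fwd, h_bwd[rev(seq_len(nrow(x))), , drop = FALSE])
  }
  x
}
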