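# Trainable bidirectional GRU classifier with a time-distributed softmax
# head, written against base matrix algebra (BLAS) with explicit
# backpropagation through time and Adam updates.
#
# Parameters live in a flat named list. Per layer l and direction d
# ("f"/"b"): "l<l>.<d>.Wx" (D x 3H), "l<l>.<d>.Wh" (H x 3H), "l<l>.<d>.b"
# (3H), gate blocks ordered reset | update | candidate; plus "head.W"
# (F x C) and "head.b" (C). The batched cell is algebraically identical to
# gru_cell_step() and equivalence is asserted by tests via as_gru_stack().

#' Model configuration
#'
#' Hyperparameters of the recurrent classifier. The defaults are the tuned
#' operating point: 512 units per layer, 2 bidirectional layers, tanh
#' candidate activation, dropout 0.5 after each recurrent layer, Adam with
#' learning rate 0.001, batch size 32, 30 epochs.
#'
#' @param n_units hidden units per direction per layer.
#' @param n_layers number of stacked recurrent layers.
#' @param bidirectional run each layer in both time directions and
#'   concatenate (feature dimension `2 * n_units`).
#' @param activation candidate nonlinearity, `"tanh"` or `"relu"`.
#' @param dropout dropout rate in `[0, 1)` applied after each recurrent
#'   layer at training time only.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs training epochs (0 = return the untrained network).
#' @param n_classes number of subjects; usually inferred from the training
#'   windows.
#' @param window_len expected window length, 100 (step) or 200 (stride).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @param aggregate how per-timestep posteriors become one window score:
#'   `"mean"` (arithmetic mean, default) or `"vote"` (per-timestep argmax
#'   tally).
#' @return object of class `model_config`.
#' @export
model_config <- function(n_units = 512L, n_layers = 2L, bidirectional = TRUE,
                         activation = c("tanh", "relu"), dropout = 0.5,
                         learning_rate = 0.001, batch_size = 32L,
                         epochs = 30L, n_classes = NULL, window_len = 100L,
                         seed = 1L, aggregate = c("mean", "vote")) {
  activation <- match.arg(activation)
  aggregate <- match.arg(aggregate)
  check_scalar_number(n_units, "n_units", lower = 1)
  check_scalar_number(n_layers, "n_layers", lower = 1)
  check_scalar_number(dropout, "dropout", lower = 0, upper = 1,
                      strict_upper = TRUE)
  check_scalar_number(learning_rate, "learning_rate", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(batch_size, "batch_size", lower = 1)
  check_scalar_number(epochs, "epochs", lower = 0)
  if (!window_len %in% c(100L, 200L)) {
    stop_invalid("window_len must be 100 (step) or 200 (stride), got %s",
                 window_len)
  }
  if (!is.null(n_classes)) check_scalar_number(n_classes, "n_classes",
                                               lower = 2)
  structure(list(n_units = as.integer(n_units),
                 n_layers = as.integer(n_layers),
                 bidirectional = isTRUE(bidirectional),
                 activation = activation, dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 n_classes = if (is.null(n_classes)) NULL
                             else as.integer(n_classes),
                 window_len = as.integer(window_len),
                 seed = as.integer(seed), aggregate = aggregate),
            class = "model_config")
}

directions <- function(config) {
  if (config$bidirectional) c("f", "b") else "f"
}

uniform_init <- function(nr, nc, fan) {
  matrix(stats::runif(nr * nc, -1 / sqrt(fan), 1 / sqrt(fan)), nr, nc)
}

# Initialize the flat parameter list; caller provides RNG scope.
init_params <- function(config, n_input, n_classes) {
  params <- list()
  d <- n_input
  H <- config$n_units
  for (l in seq_len(config$n_layers)) {
    for (dir in directions(config)) {
      key <- sprintf("l%d.%s", l, dir)
      params[[paste0(key, ".Wx")]] <- uniform_init(d, 3L * H, d)
      params[[paste0(key, ".Wh")]] <- uniform_init(H, 3L * H, H)
      params[[paste0(key, ".b")]] <- numeric(3L * H)
    }
    d <- H * length(directions(config))
  }
  params[["head.W"]] <- uniform_init(d, n_classes, d)
  params[["head.b"]] <- numeric(n_classes)
  params
}

# Batched GRU forward over one direction. X: list of T matrices (B x D),
# already in the direction's time order. Returns hidden list plus caches.
gru_dir_forward <- function(Wx, Wh, b, X, activation, keep_cache = TRUE) {
  Tn <- length(X)
  B <- nrow(X[[1]])
  H <- nrow(Wh)
  bigX <- do.call(rbind, X)
  XP <- bigX %*% Wx
  ir <- seq_len(H)
  iz <- H + ir
  ic <- 2L * H + ir
  Wh_rz <- Wh[, c(ir, iz), drop = FALSE]
  Wh_c <- Wh[, ic, drop = FALSE]
  h <- matrix(0, B, H)
  Hs <- vector("list", Tn)
  cache <- if (keep_cache) {
    list(r = vector("list", Tn), z = vector("list", Tn),
         cand = vector("list", Tn), hprev = vector("list", Tn))
  }
  br <- b[ir]; bz <- b[iz]; bc <- b[ic]
  for (t in seq_len(Tn)) {
    rows <- (t - 1L) * B + seq_len(B)
    xp <- XP[rows, , drop = FALSE]
    hp <- h %*% Wh_rz
    r <- sigmoid(xp[, ir, drop = FALSE] + hp[, ir, drop = FALSE] +
                   rep(br, each = B))
    z <- sigmoid(xp[, iz, drop = FALSE] + hp[, iz, drop = FALSE] +
                   rep(bz, each = B))
    a_c <- xp[, ic, drop = FALSE] + (r * h) %*% Wh_c + rep(bc, each = B)
    cand <- if (activation == "tanh") tanh(a_c) else pmax(a_c, 0)
    if (keep_cache) {
      cache$r[[t]] <- r
      cache$z[[t]] <- z
      cache$cand[[t]] <- cand
      cache$hprev[[t]] <- h
    }
    h <- z * h + (1 - z) * cand
    Hs[[t]] <- h
  }
  list(H = Hs, cache = cache, bigX = bigX)
}

# Backpropagation through time for one direction. dH: list of T gradients
# (B x H) w.r.t. the direction's hidden outputs (direction time order).
# Returns parameter gradients and dX (list of T, B x D).
gru_dir_backward <- function(Wx, Wh, dH, fwd, activation) {
  Tn <- length(dH)
  B <- nrow(dH[[1]])
  H <- nrow(Wh)
  ir <- seq_len(H)
  iz <- H + ir
  ic <- 2L * H + ir
  Wh_r <- Wh[, ir, drop = FALSE]
  Wh_z <- Wh[, iz, drop = FALSE]
  Wh_c <- Wh[, ic, drop = FALSE]
  dWh <- matrix(0, H, 3L * H)
  bigdA <- matrix(0, Tn * B, 3L * H)
  dh_next <- matrix(0, B, H)
  cache <- fwd$cache
  for (t in rev(seq_len(Tn))) {
    dh <- dH[[t]] + dh_next
    r <- cache$r[[t]]; z <- cache$z[[t]]
    cand <- cache$cand[[t]]; hprev <- cache$hprev[[t]]
    dz <- dh * (hprev - cand)
    da_z <- dz * z * (1 - z)
    dc <- dh * (1 - z)
    da_c <- if (activation == "tanh") dc * (1 - cand^2) else dc * (cand > 0)
    drh <- da_c %*% t(Wh_c)
    dr <- drh * hprev
    da_r <- dr * r * (1 - r)
    dh_next <- dh * z + drh * r + da_r %*% t(Wh_r) + da_z %*% t(Wh_z)
    dWh[, ir] <- dWh[, ir] + crossprod(hprev, da_r)
    dWh[, iz] <- dWh[, iz] + crossprod(hprev, da_z)
    dWh[, ic] <- dWh[, ic] + crossprod(r * hprev, da_c)
    rows <- (t - 1L) * B + seq_len(B)
    bigdA[rows, ir] <- da_r
    bigdA[rows, iz] <- da_z
    bigdA[rows, ic] <- da_c
  }
  dWx <- crossprod(fwd$bigX, bigdA)
  db <- colSums(bigdA)
  bigdX <- bigdA %*% t(Wx)
  dX <- lapply(seq_len(Tn), function(t) {
    bigdX[(t - 1L) * B + seq_len(B), , drop = FALSE]
  })
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

rev_time <- function(X) X[rev(seq_along(X))]

# Full network forward. X: list of T (B x D) input matrices. Training mode
# applies inverted dropout after each recurrent layer and keeps all caches.
network_forward <- function(params, config, X, training = FALSE) {
  layers <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    lay <- list()
    outs <- list()
    for (dir in directions(config)) {
      key <- sprintf("l%d.%s", l, dir)
      Xin <- if (dir == "f") X else rev_time(X)
      fwd <- gru_dir_forward(params[[paste0(key, ".Wx")]],
                             params[[paste0(key, ".Wh")]],
                             params[[paste0(key, ".b")]],
                             Xin, config$activation, keep_cache = training)
      lay[[dir]] <- fwd
      outs[[dir]] <- if (dir == "f") fwd$H else rev_time(fwd$H)
    }
    X <- if (config$bidirectional) {
      Map(cbind, outs[["f"]], outs[["b"]])
    } else {
      outs[["f"]]
    }
    if (training && config$dropout > 0) {
      keep <- 1 - config$dropout
      lay$mask <- lapply(X, function(m) {
        (matrix(stats::runif(length(m)), nrow(m), ncol(m)) < keep) / keep
      })
      X <- Map(`*`, X, lay$mask)
    }
    lay$out <- X
    layers[[l]] <- lay
  }
  Tn <- length(X)
  B <- nrow(X[[1]])
  bigH <- do.call(rbind, X)
  logits <- bigH %*% params[["head.W"]] +
    rep(params[["head.b"]], each = Tn * B)
  P <- exp(logits - apply(logits, 1L, max))
  P <- P / rowSums(P)
  list(layers = layers, bigH = bigH, P = P, Tn = Tn, B = B)
}

# Loss and full gradient for one minibatch. y: integer class per window.
network_backward <- function(params, config, X, y, fw) {
  Tn <- fw$Tn
  B <- fw$B
  n_out <- Tn * B
  ybig <- rep(y, times = Tn)
  idx <- cbind(seq_len(n_out), ybig)
  loss <- -mean(log(pmax(fw$P[idx], 1e-300)))
  acc <- mean(max.col(fw$P, ties.method = "first") == ybig)
  dlogits <- fw$P
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / n_out
  grads <- list()
  grads[["head.W"]] <- crossprod(fw$bigH, dlogits)
  grads[["head.b"]] <- colSums(dlogits)
  bigdH <- dlogits %*% t(params[["head.W"]])
  dX <- lapply(seq_len(Tn), function(t) {
    bigdH[(t - 1L) * B + seq_len(B), , drop = FALSE]
  })
  H <- config$n_units
  for (l in rev(seq_len(config$n_layers))) {
    lay <- fw$layers[[l]]
    if (!is.null(lay$mask)) dX <- Map(`*`, dX, lay$mask)
    dX_next <- NULL
    for (dir in directions(config)) {
      key <- sprintf("l%d.%s", l, dir)
      dH_dir <- if (!config$bidirectional) {
        dX
      } else if (dir == "f") {
        lapply(dX, function(m) m[, seq_len(H), drop = FALSE])
      } else {
        rev_time(lapply(dX, function(m) m[, H + seq_len(H), drop = FALSE]))
      }
      bk <- gru_dir_backward(params[[paste0(key, ".Wx")]],
                             params[[paste0(key, ".Wh")]],
                             dH_dir, lay[[dir]], config$activation)
      grads[[paste0(key, ".Wx")]] <- bk$dWx
      grads[[paste0(key, ".Wh")]] <- bk$dWh
      grads[[paste0(key, ".b")]] <- bk$db
      dX_dir <- if (dir == "f") bk$dX else rev_time(bk$dX)
      dX_next <- if (is.null(dX_next)) dX_dir else Map(`+`, dX_next, dX_dir)
    }
    dX <- dX_next
  }
  list(loss = loss, acc = acc, grads = grads)
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

windows_to_tlist <- function(data, idx, Tn) {
  lapply(seq_len(Tn), function(t) {
    m <- data[idx, t, ]
    if (length(idx) == 1L) m <- matrix(m, nrow = 1L)
    m
  })
}

#' Train the bidirectional GRU re-identification classifier
#'
#' Trains a stacked (bidirectional) GRU with a time-distributed dense softmax
#' head on scaled gait windows. The target at every timestep is the window's
#' subject; the loss is the mean categorical cross-entropy over all timesteps
#' of all windows in a minibatch, minimised with Adam. Dropout is applied
#' after each recurrent layer at training time only. Training is
#' deterministic given `config$seed` (single-threaded BLAS assumed).
#'
#' @param config a [model_config()]; `n_classes` and `window_len` are checked
#'   against, or inferred from, the training windows.
#' @param train_windows a scaled `gait_windows` object with at least one
#'   window for each of at least two subjects.
#' @return object of class `gait_gru_model`: parameters, resolved config,
#'   the ordered class-label vector, and a per-epoch training history
#'   (`loss`, `acc`).
#' @examples
#' \donttest{
#' cohort <- make_cohort(3, seed = 1)
#' streams <- simulate_cohort(cohort, duration_s = 20, seed = 1)
#' w <- segment_corpus(streams, "step")
#' sc <- fit_scaler(w)
#' cfg <- model_config(n_units = 8, epochs = 2, seed = 1)
#' m <- train_classifier(cfg, apply_scaler(sc, w))
#' m$history$loss
#' }
#' @export
train_classifier <- function(config, train_windows) {
  stopifnot(inherits(config, "model_config"),
            inherits(train_windows, "gait_windows"))
  classes <- sort(unique(train_windows$info$subject_id))
  C <- length(classes)
  if (C < 2L) {
    stop_invalid("training needs at least 2 classes (got %d)", C)
  }
  if (!is.null(config$n_classes) && config$n_classes != C) {
    stop_invalid("config$n_classes = %d but training data has %d subjects",
                 config$n_classes, C)
  }
  config$n_classes <- C
  if (train_windows$window_len != config$window_len) {
    config$window_len <- train_windows$window_len
  }
  counts <- table(train_windows$info$subject_id)
  if (any(counts < 1L)) stop_invalid("every class needs at least one window")
  N <- n_windows(train_windows)
  Tn <- config$window_len
  y <- match(train_windows$info$subject_id, classes)
  n_input <- dim(train_windows$data)[3]
  log_info("train: %d windows, %d classes, %d timesteps", N, C, Tn)

  with_seed(config$seed, {
    params <- init_params(config, n_input, C)
    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          acc = numeric(0))
    step <- 0L
    for (epoch in seq_len(config$epochs)) {
      order <- sample.int(N)
      losses <- c()
      accs <- c()
      for (b0 in seq(1L, N, by = config$batch_size)) {
        idx <- order[b0:min(b0 + config$batch_size - 1L, N)]
        X <- windows_to_tlist(train_windows$data, idx, Tn)
        fw <- network_forward(params, config, X, training = TRUE)
        bk <- network_backward(params, config, X, y[idx], fw)
        step <- step + 1L
        upd <- adam_step(params, bk$grads, state, config$learning_rate,
                         step)
        params <- upd$params
        state <- upd$state
        losses <- c(losses, bk$loss)
        accs <- c(accs, bk$acc)
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = mean(losses),
                                  acc = mean(accs)))
      log_info("epoch %d/%d: loss %.4f, acc %.4f", epoch, config$epochs,
               mean(losses), mean(accs))
    }
    structure(list(params = params, config = config, classes = classes,
                   n_input = n_input, history = history),
              class = "gait_gru_model")
  })
}

#' @export
print.gait_gru_model <- function(x, ...) {
  cat(sprintf(paste0("<gait_gru_model: %d classes, %d x %d-unit %s layers,",
                     " window %d, %d epochs trained>\n"),
              length(x$classes), x$config$n_layers, x$config$n_units,
              if (x$config$bidirectional) "bidirectional" else "forward",
              x$config$window_len, nrow(x$history)))
  invisible(x)
}

#' Export a trained model's recurrent layers as a reference cell stack
#'
#' Converts the batched parameter layout into [gru_cell_params()] objects so
#' the training path can be checked against [bidirectional_forward()].
#'
#' @param model a `gait_gru_model`.
#' @return a `gru_stack` (list of layers with `forward`/`backward` cells).
#' @export
as_gru_stack <- function(model) {
  stopifnot(inherits(model, "gait_gru_model"))
  H <- model$config$n_units
  ir <- seq_len(H)
  to_cell <- function(key) {
    Wx <- model$params[[paste0(key, ".Wx")]]
    Wh <- model$params[[paste0(key, ".Wh")]]
    b <- model$params[[paste0(key, ".b")]]
    gru_cell_params(
      W_xr = t(Wx[, ir, drop = FALSE]),
      W_xz = t(Wx[, H + ir, drop = FALSE]),
      W_xh = t(Wx[, 2L * H + ir, drop = FALSE]),
      W_hr = t(Wh[, ir, drop = FALSE]),
      W_hz = t(Wh[, H + ir, drop = FALSE]),
      W_hh = t(Wh[, 2L * H + ir, drop = FALSE]),
      b_r = b[ir], b_z = b[H + ir], b_h = b[2L * H + ir])
  }
  layers <- lapply(seq_len(model$config$n_layers), function(l) {
    lay <- list(forward = to_cell(sprintf("l%d.f", l)))
    if (model$config$bidirectional) {
      lay$backward <- to_cell(sprintf("l%d.b", l))
    }
    lay
  })
  structure(layers, class = "gru_stack")
}

# Batched inference: per-timestep posteriors for a set of windows.
# Returns list(scores = N x C aggregated, preds = argmax, per_timestep =
# optional list of T x C matrices).
predict_scores <- function(model, windows, batch_size = 64L,
                           keep_per_timestep = FALSE) {
  stopifnot(inherits(model, "gait_gru_model"),
            inherits(windows, "gait_windows"))
  config <- model$config
  if (windows$window_len != config$window_len) {
    stop_invalid("window length %d does not match model's %d",
                 windows$window_len, config$window_len)
  }
  N <- n_windows(windows)
  C <- config$n_classes
  Tn <- config$window_len
  scores <- matrix(0, N, C, dimnames = list(NULL, model$classes))
  per_t <- if (keep_per_timestep) vector("list", N)
  for (b0 in seq(1L, N, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, N)
    X <- windows_to_tlist(windows$data, idx, Tn)
    fw <- network_forward(model$params, config, X, training = FALSE)
    B <- length(idx)
    for (j in seq_along(idx)) {
      # rows of P for window j: one per timestep, stride B
      rows <- (seq_len(Tn) - 1L) * B + j
      Pj <- fw$P[rows, , drop = FALSE]
      if (keep_per_timestep) per_t[[idx[j]]] <- Pj
      scores[idx[j], ] <- if (config$aggregate == "vote") {
        tabulate(max.col(Pj, ties.method = "first"), C) / Tn
      } else {
        colMeans(Pj)
      }
    }
  }
  preds <- max.col(scores, ties.method = "first")
  log_info("predict: %d windows -> %d classes", N, C)
  list(scores = scores, preds = preds, per_timestep = per_t)
}

#' Predict one gait window
#'
#' Runs the trained network over a single scaled window and returns the
#' per-timestep class posteriors, the aggregated window score (arithmetic
#' mean of the per-timestep posteriors, or a normalised argmax vote when the
#' model was configured with `aggregate = "vote"`), and the predicted class
#' (argmax, ties broken toward the lowest class index).
#'
#' @param model a `gait_gru_model`.
#' @param window numeric matrix `(window_len x 6)` or a `gait_windows`
#'   object holding exactly one window.
#' @return object of class `prediction_result` with fields `per_timestep`
#'   (`window_len x n_classes`, rows summing to 1), `aggregated` (length
#'   `n_classes`, summing to 1) and `predicted_class` (label string).
#' @export
predict_window <- function(model, window) {
  stopifnot(inherits(model, "gait_gru_model"))
  if (inherits(window, "gait_windows")) {
    if (n_windows(window) != 1L) {
      stop_invalid("predict_window expects exactly one window (got %d)",
                   n_windows(window))
    }
    wmat <- window_matrix(window, 1L)
  } else {
    wmat <- as.matrix(window)
  }
  if (nrow(wmat) != model$config$window_len) {
    stop_invalid("window has %d timesteps, model expects %d", nrow(wmat),
                 model$config$window_len)
  }
  data <- array(wmat, dim = c(1L, nrow(wmat), ncol(wmat)))
  wobj <- new_gait_windows(
    data, data.frame(subject_id = "query", kind = "step", start_frame = 0L,
                     gender = NA, age_years = NA, setup = NA,
                     condition = NA),
    kind = if (nrow(wmat) == 200L) "stride" else "step",
    window_len = nrow(wmat), rate_hz = NA_real_)
  out <- predict_scores(model, wobj, keep_per_timestep = TRUE)
  structure(list(per_timestep = out$per_timestep[[1L]],
                 aggregated = out$scores[1L, ],
                 predicted_class = model$classes[out$preds[1L]]),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result: %d timesteps x %d classes, predicted %s>\n",
              nrow(x$per_timestep), ncol(x$per_timestep), x$predicted_class))
  invisible(x)
}

#' Save a trained model
#'
#' Writes the weights as a flat binary container plus a JSON snapshot of the
#' configuration, class labels and array shapes.
#'
#' @param model a `gait_gru_model`.
#' @param prefix path prefix; writes `<prefix>.bin` and `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_model <- function(model, prefix) {
  stopifnot(inherits(model, "gait_gru_model"))
  shapes <- lapply(model$params, function(p) {
    if (is.matrix(p)) dim(p) else length(p)
  })
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  for (nm in names(model$params)) {
    writeBin(as.vector(model$params[[nm]]), con, size = 8L,
             endian = "little")
  }
  jsonlite::write_json(
    list(config = unclass(model$config), classes = model$classes,
         n_input = model$n_input, shapes = shapes,
         param_order = names(model$params), history = model$history),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Load a model written by [write_model()]
#'
#' @param prefix path prefix used when writing.
#' @return a `gait_gru_model`.
#' @export
read_model <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  cfgl <- meta$config
  config <- model_config(
    n_units = cfgl$n_units, n_layers = cfgl$n_layers,
    bidirectional = cfgl$bidirectional, activation = cfgl$activation,
    dropout = cfgl$dropout, learning_rate = cfgl$learning_rate,
    batch_size = cfgl$batch_size, epochs = cfgl$epochs,
    n_classes = cfgl$n_classes, window_len = cfgl$window_len,
    seed = cfgl$seed, aggregate = cfgl$aggregate)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  params <- list()
  for (nm in meta$param_order) {
    shp <- meta$shapes[[nm]]
    n <- prod(shp)
    v <- readBin(con, "double", n = n, size = 8L, endian = "little")
    params[[nm]] <- if (length(shp) == 2L) matrix(v, shp[1], shp[2]) else v
  }
  structure(list(params = params, config = config, classes = meta$classes,
                 n_input = meta$n_input,
                 history = as.data.frame(meta$history)),
            class = "gait_gru_model")
}
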