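# Experiment configuration: YAML (or JSON) files with strict validation,
# defaults mirroring the tuned operating point, and a grid-sweep harness.

.CONFIG_SCHEMA <- list(
  simulation = c("n_subjects", "male_fraction", "age_mean", "age_sd",
                 "setup_A", "setup_B", "setup_C", "duration_s", "rate_hz",
                 "noise_frac"),
  segmentation = c("kind", "hop"),
  model = c("n_units", "n_layers", "bidirectional", "activation", "dropout",
            "learning_rate", "batch_size", "epochs", "aggregate"),
  evaluation = c("protocol", "k", "gender", "age_group", "setup"))

#' Default experiment configuration
#'
#' Nested blocks `simulation`, `segmentation`, `model`, `evaluation` plus a
#' global `seed`. Model defaults are the tuned operating point (512 units, 2
#' bidirectional layers, dropout 0.5, learning rate 0.001, batch size 32, 30
#' epochs); the simulation defaults describe a 10-subject 90 s fixture at
#' 75 Hz.
#'
#' @return object of class `experiment_config`.
#' @export
default_config <- function() {
  structure(list(
    simulation = list(n_subjects = 10L, male_fraction = 49 / 86,
                      age_mean = 33.8, age_sd = 14.8,
                      setup_A = NULL, setup_B = NULL, setup_C = NULL,
                      duration_s = 90, rate_hz = 75, noise_frac = 0.05),
    segmentation = list(kind = "step", hop = NULL),
    model = list(n_units = 512L, n_layers = 2L, bidirectional = TRUE,
                 activation = "tanh", dropout = 0.5, learning_rate = 0.001,
                 batch_size = 32L, epochs = 30L, aggregate = "mean"),
    evaluation = list(protocol = "half_split", k = 10L, gender = NULL,
                      age_group = NULL, setup = NULL),
    seed = 1L), class = "experiment_config")
}

validate_config <- function(cfg) {
  blocks <- c(names(.CONFIG_SCHEMA), "seed")
  bad <- setdiff(names(cfg), blocks)
  if (length(bad) > 0L) {
    stop_invalid("unknown config key '%s'", bad[1])
  }
  for (blk in names(.CONFIG_SCHEMA)) {
    bad <- setdiff(names(cfg[[blk]]), .CONFIG_SCHEMA[[blk]])
    if (length(bad) > 0L) {
      stop_invalid("unknown config key '%s.%s'", blk, bad[1])
    }
  }
  with(cfg$simulation, {
    check_scalar_number(n_subjects, "simulation.n_subjects", lower = 0)
    check_scalar_number(male_fraction, "simulation.male_fraction",
                        lower = 0, upper = 1)
    check_scalar_number(duration_s, "simulation.duration_s", lower = 0,
                        strict_lower = TRUE)
    check_scalar_number(rate_hz, "simulation.rate_hz", lower = 0,
                        strict_lower = TRUE)
  })
  if (!cfg$segmentation$kind %in% c("step", "stride")) {
    stop_invalid("config key 'segmentation.kind' must be step or stride")
  }
  if (!is.null(cfg$segmentation$hop)) {
    check_scalar_number(cfg$segmentation$hop, "segmentation.hop", lower = 1)
  }
  m <- cfg$model
  check_scalar_number(m$n_units, "model.n_units", lower = 1)
  check_scalar_number(m$n_layers, "model.n_layers", lower = 1)
  check_scalar_number(m$dropout, "model.dropout", lower = 0, upper = 1,
                      strict_upper = TRUE)
  check_scalar_number(m$learning_rate, "model.learning_rate", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(m$batch_size, "model.batch_size", lower = 1)
  check_scalar_number(m$epochs, "model.epochs", lower = 0)
  if (!m$activation %in% c("tanh", "relu")) {
    stop_invalid("config key 'model.activation' must be tanh or relu")
  }
  if (!m$aggregate %in% c("mean", "vote")) {
    stop_invalid("config key 'model.aggregate' must be mean or vote")
  }
  if (!cfg$evaluation$protocol %in% c("half_split", "kfold")) {
    stop_invalid("config key 'evaluation.protocol' must be half_split or kfold")
  }
  check_scalar_number(cfg$evaluation$k, "evaluation.k", lower = 2)
  check_scalar_number(cfg$seed, "seed")
  cfg
}

# Overlay user values onto the defaults, rejecting unknown keys.
merge_config <- function(user) {
  cfg <- default_config()
  if (length(user) == 0L) return(validate_config(cfg))
  blocks <- c(names(.CONFIG_SCHEMA), "seed")
  bad <- setdiff(names(user), blocks)
  if (length(bad) > 0L) stop_invalid("unknown config key '%s'", bad[1])
  for (blk in names(.CONFIG_SCHEMA)) {
    if (is.null(user[[blk]])) next
    bad <- setdiff(names(user[[blk]]), .CONFIG_SCHEMA[[blk]])
    if (length(bad) > 0L) {
      stop_invalid("unknown config key '%s.%s'", blk, bad[1])
    }
    for (key in names(user[[blk]])) {
      cfg[[blk]][[key]] <- user[[blk]][[key]]
    }
  }
  if (!is.null(user$seed)) cfg$seed <- user$seed
  validate_config(cfg)
}

#' Load an experiment configuration file
#'
#' Reads YAML (or JSON — every JSON file is valid YAML) with strict key
#' validation: unknown keys and out-of-range values are rejected with the
#' offending key named. Missing keys take their defaults; an empty file
#' yields [default_config()]. The resolved configuration is echoed to the
#' log.
#'
#' @param path configuration file path.
#' @return a validated `experiment_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file '%s' not found", path)
  user <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop_invalid("config parse failure in '%s': %s",
                                     path, conditionMessage(e)))
  if (is.null(user)) user <- list()
  cfg <- merge_config(user)
  log_info("config: %s", paste(deparse(unclass(cfg), control = NULL),
                               collapse = " "))
  cfg
}

#' Save an experiment configuration as YAML
#'
#' @param cfg an `experiment_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  drop_null <- function(x) {
    if (!is.list(x)) return(x)
    x <- lapply(x, drop_null)
    x[!vapply(x, is.null, TRUE)]
  }
  yaml::write_yaml(drop_null(unclass(cfg)), path)
  invisible(path)
}

# Build the pieces of a pipeline run from an experiment config.
config_model <- function(cfg, seed) {
  m <- cfg$model
  model_config(n_units = m$n_units, n_layers = m$n_layers,
               bidirectional = m$bidirectional, activation = m$activation,
               dropout = m$dropout, learning_rate = m$learning_rate,
               batch_size = m$batch_size, epochs = m$epochs,
               window_len = window_length(cfg$segmentation$kind),
               seed = seed, aggregate = m$aggregate)
}

config_filter <- function(cfg) {
  e <- cfg$evaluation
  if (is.null(e$gender) && is.null(e$age_group) && is.null(e$setup)) {
    return(NULL)
  }
  cohort_filter(gender = e$gender, age_group = e$age_group, setup = e$setup)
}

config_streams <- function(cfg) {
  s <- cfg$simulation
  setup_mix <- if (!is.null(s$setup_A) || !is.null(s$setup_B) ||
                   !is.null(s$setup_C)) {
    c(A = s$setup_A %||% 0, B = s$setup_B %||% 0, C = s$setup_C %||% 0)
  }
  cohort <- make_cohort(s$n_subjects, male_fraction = s$male_fraction,
                        age_mean_sd = c(s$age_mean, s$age_sd),
                        setup_mix = setup_mix,
                        seed = derive_seed(cfg$seed, "cohort"),
                        noise_frac = s$noise_frac)
  simulate_cohort(cohort, duration_s = s$duration_s, rate_hz = s$rate_hz,
                  seed = derive_seed(cfg$seed, "simulate"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the experiment described by a configuration
#'
#' Simulates the configured cohort and executes [run_experiment()] with the
#' configured segmentation, model, protocol and cohort restriction.
#'
#' @param cfg an `experiment_config` (see [load_config()],
#'   [default_config()]).
#' @param streams optional pre-simulated streams; simulated from the config
#'   when `NULL`.
#' @return an `eval_report` (or list of reports for the k-fold protocol).
#' @export
run_config <- function(cfg, streams = NULL) {
  cfg <- validate_config(cfg)
  if (is.null(streams)) streams <- config_streams(cfg)
  run_experiment(streams, kind = cfg$segmentation$kind,
                 protocol = cfg$evaluation$protocol,
                 config = config_model(cfg, derive_seed(cfg$seed, "train")),
                 filter = config_filter(cfg), seed = cfg$seed,
                 hop = cfg$segmentation$hop, k = cfg$evaluation$k)
}

#' Hyperparameter grid sweep
#'
#' Runs one experiment per point of the cartesian grid over a subset of
#' `n_units`, `dropout`, `learning_rate`, `epochs`, keeping everything else
#' at the base configuration, and tabulates rank-1 and mAP. An empty grid
#' runs the base configuration once.
#'
#' @param base an `experiment_config`.
#' @param grid named list mapping hyperparameter names to value vectors.
#' @param streams optional pre-simulated streams reused across grid points;
#'   simulated once from `base` when `NULL`.
#' @param csv optional path to write the result table.
#' @return data.frame with one row per grid point: the swept values,
#'   `rank1_percent` and `map_percent`.
#' @export
hyperparameter_sweep <- function(base, grid = list(), streams = NULL,
                                 csv = NULL) {
  base <- validate_config(base)
  allowed <- c("n_units", "dropout", "learning_rate", "epochs")
  bad <- setdiff(names(grid), allowed)
  if (length(bad) > 0L) {
    stop_invalid("unknown sweep key '%s' (allowed: %s)", bad[1],
                 paste(allowed, collapse = ", "))
  }
  if (is.null(streams)) streams <- config_streams(base)
  points <- if (length(grid) == 0L) {
    data.frame(row = 1L)[, FALSE, drop = FALSE]
  } else {
    expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  }
  n_pts <- max(1L, nrow(points))
  rows <- vector("list", n_pts)
  for (i in seq_len(n_pts)) {
    cfg <- base
    if (ncol(points) > 0L) {
      for (key in names(points)) cfg$model[[key]] <- points[i, key]
    }
    report <- run_config(cfg, streams = streams)
    if (!inherits(report, "eval_report")) report <- report[[1L]]
    rec <- as.list(if (ncol(points) > 0L) points[i, , drop = FALSE]
                   else data.frame()[1, , drop = FALSE])
    rec$rank1_percent <- report$rank_k$rank1
    rec$map_percent <- report$map_percent
    rows[[i]] <- as.data.frame(rec)
    log_info("sweep %d/%d: rank1 %.2f%%, mAP %.2f%%", i, n_pts,
             rec$rank1_percent, rec$map_percent)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
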