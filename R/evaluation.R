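# Closed-set re-identification metrics and experiment protocols.
#
# Ranking convention: for a query with aggregated score vector s and true
# class i, rank(i) = 1 + #{j : s_j > s_i} + #{j < i : s_j = s_i} — ties are
# broken by ascending class index, so ranks are deterministic.

#' Subject-wise half split
#'
#' Splits each subject's windows uniformly at random into a training and a
#' test half (the extra window goes to training when the count is odd), so
#' every subject is present in both partitions.
#'
#' @param windows a `gait_windows` object; every subject needs >= 2 windows.
#' @param seed integer seed; identical seeds give identical partitions.
#' @return list with `train` and `test` `gait_windows`.
#' @export
half_split <- function(windows, seed = 1L) {
  stopifnot(inherits(windows, "gait_windows"))
  ids <- windows$info$subject_id
  counts <- table(ids)
  if (any(counts < 2L)) {
    stop_invalid("half_split needs >= 2 windows per subject; %s has %d",
                 names(counts)[which.min(counts)], min(counts))
  }
  train_idx <- integer(0)
  with_seed(seed, {
    for (sub in sort(unique(ids))) {
      w <- which(ids == sub)
      n_tr <- ceiling(length(w) / 2)
      train_idx <- c(train_idx, sample(w, n_tr))
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(ids), train_idx)
  log_info("half_split: %d train / %d test windows over %d subjects",
           length(train_idx), length(test_idx), length(counts))
  list(train = windows[train_idx], test = windows[test_idx])
}

#' Subject-stratified k-fold splits
#'
#' Each subject's windows are spread across `k` folds as evenly as possible;
#' every window appears in exactly one test fold.
#'
#' @param windows a `gait_windows` object; every subject needs >= `k`
#'   windows.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return list of `k` lists, each with `train` and `test` `gait_windows`.
#' @export
kfold_splits <- function(windows, k = 10L, seed = 1L) {
  stopifnot(inherits(windows, "gait_windows"))
  if (!is.numeric(k) || length(k) != 1L || k < 2L || k != round(k)) {
    stop_invalid("k must be an integer >= 2")
  }
  k <- as.integer(k)
  ids <- windows$info$subject_id
  counts <- table(ids)
  if (any(counts < k)) {
    stop_invalid("kfold needs >= %d windows per subject; %s has %d", k,
                 names(counts)[which.min(counts)], min(counts))
  }
  fold <- integer(length(ids))
  with_seed(seed, {
    for (sub in sort(unique(ids))) {
      w <- which(ids == sub)
      fold[w] <- sample(rep_len(seq_len(k), length(w)))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = windows[fold != f], test = windows[fold == f])
  })
}

# Normalise (results, truths) into a score matrix and truth indices.
scores_and_truths <- function(results, truths) {
  scores <- if (is.matrix(results)) {
    results
  } else if (inherits(results, "prediction_result")) {
    matrix(results$aggregated, nrow = 1L,
           dimnames = list(NULL, names(results$aggregated)))
  } else if (is.list(results) &&
             all(vapply(results, inherits, TRUE, "prediction_result"))) {
    do.call(rbind, lapply(results, `[[`, "aggregated"))
  } else {
    stop_invalid("results must be a score matrix or prediction_result list")
  }
  if (nrow(scores) < 1L) stop_invalid("need at least one query")
  C <- ncol(scores)
  if (is.character(truths)) {
    if (is.null(colnames(scores))) {
      stop_invalid("label truths need a score matrix with class columns")
    }
    ti <- match(truths, colnames(scores))
  } else {
    ti <- as.integer(truths)
    ti[ti < 1L | ti > C] <- NA_integer_
  }
  if (length(ti) != nrow(scores)) {
    stop_invalid("results (%d) and truths (%d) differ in length",
                 nrow(scores), length(ti))
  }
  if (anyNA(ti)) {
    stop_invalid("some truth labels are outside the model's class set")
  }
  list(scores = scores, truths = ti)
}

# Rank of the true class per query under the tie-break convention.
query_ranks <- function(scores, truths) {
  vapply(seq_len(nrow(scores)), function(q) {
    s <- scores[q, ]
    st <- s[truths[q]]
    1L + sum(s > st) + sum(s == st & seq_along(s) < truths[q])
  }, 1L)
}

#' Cumulative matching characteristic curve
#'
#' For each rank k from 1 to the number of classes, the fraction of queries
#' whose true class is ranked within the top k by aggregated score.
#'
#' @param results score matrix `(n_queries x n_classes)` or a list of
#'   [predict_window()] results.
#' @param truths true class per query: integer indices or label strings
#'   matching the score matrix's column names.
#' @return object of class `cmc_curve` with fields `ranks` (1..C) and
#'   `matching_rate` (nondecreasing, ending at 1).
#' @examples
#' s <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.3, 0.6))
#' cmc_curve(s, c(1, 3))$matching_rate
#' @export
cmc_curve <- function(results, truths) {
  st <- scores_and_truths(results, truths)
  C <- ncol(st$scores)
  ranks <- query_ranks(st$scores, st$truths)
  structure(list(ranks = seq_len(C),
                 matching_rate = cumsum(tabulate(ranks, C)) / length(ranks)),
            class = "cmc_curve")
}

#' @export
print.cmc_curve <- function(x, ...) {
  ks <- unique(pmin(c(1L, 5L, 10L, 20L, max(x$ranks)), max(x$ranks)))
  cat("<cmc_curve>\n")
  print(stats::setNames(round(100 * x$matching_rate[ks], 2),
                        paste0("rank-", ks)))
  invisible(x)
}

#' Mean average precision
#'
#' In the closed-set identification setting each query has exactly one
#' relevant class, so average precision reduces to the reciprocal rank of
#' the true class and mAP to the mean reciprocal rank (`method =
#' "reciprocal"`, default), reported as a percentage. `method = "gallery"`
#' instead treats the other query windows as a retrieval gallery ranked by
#' cosine similarity of aggregated posteriors, with all windows of the
#' query's subject relevant — the instance-retrieval convention.
#'
#' @inheritParams cmc_curve
#' @param method `"reciprocal"` or `"gallery"`.
#' @return mAP as a percentage in `[0, 100]`.
#' @examples
#' s <- rbind(c(0.7, 0.3), c(0.4, 0.6), c(0.9, 0.1))
#' mean_average_precision(s, c(1, 1, 2))  # ranks 1, 2, 2 -> 66.67
#' @export
mean_average_precision <- function(results, truths,
                                   method = c("reciprocal", "gallery")) {
  method <- match.arg(method)
  st <- scores_and_truths(results, truths)
  if (method == "reciprocal") {
    ranks <- query_ranks(st$scores, st$truths)
    return(100 * mean(1 / ranks))
  }
  scores <- st$scores
  n <- nrow(scores)
  if (n < 2L) stop_invalid("gallery mAP needs at least two windows")
  norms <- sqrt(rowSums(scores^2))
  sim <- (scores %*% t(scores)) / outer(norms, norms)
  aps <- vapply(seq_len(n), function(q) {
    gal <- setdiff(seq_len(n), q)
    rel <- st$truths[gal] == st$truths[q]
    if (!any(rel)) return(NA_real_)
    ord <- gal[order(sim[q, gal], decreasing = TRUE)]
    hits <- st$truths[ord] == st$truths[q]
    mean(cumsum(hits)[hits] / which(hits))
  }, 1.0)
  100 * mean(aps, na.rm = TRUE)
}

#' Confusion matrix of predicted vs true classes
#'
#' Entry `(i, j)` counts queries of true class i predicted as class j; the
#' trace over the total is the rank-1 accuracy.
#'
#' @inheritParams cmc_curve
#' @return `C x C` integer matrix with class labels on both dimensions.
#' @export
confusion_matrix <- function(results, truths) {
  st <- scores_and_truths(results, truths)
  C <- ncol(st$scores)
  preds <- max.col(st$scores, ties.method = "first")
  cm <- matrix(0L, C, C)
  for (q in seq_along(preds)) {
    cm[st$truths[q], preds[q]] <- cm[st$truths[q], preds[q]] + 1L
  }
  labs <- colnames(st$scores)
  if (!is.null(labs)) dimnames(cm) <- list(truth = labs, predicted = labs)
  cm
}

#' Cohort restriction filter
#'
#' Unset fields match everything. Age groups are the decade bins of
#' [age_groups()] (G1 10-19 y ... G6 60-79 y, inclusive bounds).
#'
#' @param gender optional `"male"` or `"female"`.
#' @param age_group optional `"G1"`..`"G6"`.
#' @param setup optional subset of `c("A", "B", "C")`.
#' @return object of class `cohort_filter`.
#' @export
cohort_filter <- function(gender = NULL, age_group = NULL, setup = NULL) {
  if (!is.null(gender)) gender <- match.arg(gender, c("male", "female"))
  if (!is.null(age_group)) {
    age_group <- match.arg(age_group, age_groups()$group)
  }
  if (!is.null(setup)) {
    stopifnot(all(setup %in% c("A", "B", "C")))
  }
  structure(list(gender = gender, age_group = age_group, setup = setup),
            class = "cohort_filter")
}

filter_description <- function(filter) {
  if (is.null(filter)) return("none")
  parts <- c(
    if (!is.null(filter$gender)) paste0("gender=", filter$gender),
    if (!is.null(filter$age_group)) paste0("age_group=", filter$age_group),
    if (!is.null(filter$setup)) {
      paste0("setup=", paste(filter$setup, collapse = "+"))
    })
  if (length(parts) == 0L) "none" else paste(parts, collapse = ",")
}

#' Restrict windows to a sub-cohort
#'
#' Keeps the windows whose subject metadata satisfy every set field of the
#' filter. Restriction is applied before splitting and training, so a
#' restricted experiment retrains on the surviving subjects only.
#'
#' @param windows a `gait_windows` object with subject metadata.
#' @param filter a [cohort_filter()]; `NULL` keeps everything.
#' @return the filtered `gait_windows`.
#' @export
cohort_filter_windows <- function(windows, filter) {
  stopifnot(inherits(windows, "gait_windows"))
  if (is.null(filter)) return(windows)
  stopifnot(inherits(filter, "cohort_filter"))
  keep <- rep(TRUE, n_windows(windows))
  if (!is.null(filter$gender)) {
    keep <- keep & windows$info$gender == filter$gender
  }
  if (!is.null(filter$age_group)) {
    g <- age_groups()
    row <- g[g$group == filter$age_group, ]
    keep <- keep & windows$info$age_years >= row$lower &
      windows$info$age_years <= row$upper
  }
  if (!is.null(filter$setup)) {
    keep <- keep & windows$info$setup %in% filter$setup
  }
  if (!any(keep)) {
    stop_invalid("empty cohort after filter (%s)", filter_description(filter))
  }
  out <- windows[keep]
  log_info("filter (%s): %d -> %d windows, %d subjects",
           filter_description(filter), n_windows(windows), n_windows(out),
           length(unique(out$info$subject_id)))
  out
}

rank_k_table <- function(cmc, ks = c(1L, 5L, 10L, 20L)) {
  C <- length(cmc$matching_rate)
  ks <- ks[ks <= C]
  stats::setNames(round(100 * cmc$matching_rate[ks], 2),
                  paste0("rank", ks))
}

new_eval_report <- function(scores, truths, classes, protocol, kind, seed,
                            filter, n_train) {
  cmc <- cmc_curve(scores, truths)
  report <- list(
    protocol = protocol, kind = kind, seed = seed,
    filter = filter_description(filter),
    n_classes = length(classes), classes = classes,
    n_train = n_train, n_test = nrow(scores),
    rank_k = as.list(rank_k_table(cmc)),
    map_percent = round(mean_average_precision(scores, truths), 2),
    cmc = cmc,
    confusion = confusion_matrix(scores, truths))
  structure(report, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %s / %s, %d classes, %d test windows>\n",
              x$protocol, x$kind, x$n_classes, x$n_test))
  cat("  rank-k (%):",
      paste(names(x$rank_k), unlist(x$rank_k), sep = "=", collapse = " "),
      sprintf(" mAP=%0.2f%%\n", x$map_percent))
  invisible(x)
}

#' Run one end-to-end re-identification experiment
#'
#' Pipeline: segment the streams into windows of the requested kind, apply
#' the cohort restriction, split (subject-wise half split or stratified
#' k-fold), fit the robust scaler on the training partition only, train the
#' recurrent classifier, score the test windows, and compute CMC, rank-k,
#' mAP and the confusion matrix.
#'
#' @param streams list of [imu_stream()] objects, or an already segmented
#'   `gait_windows` object of the right kind.
#' @param kind `"step"` or `"stride"`.
#' @param protocol `"half_split"` or `"kfold"`.
#' @param config a [model_config()]; its `window_len` is overridden by the
#'   segmentation kind.
#' @param filter optional [cohort_filter()].
#' @param seed global experiment seed; stage seeds are derived from it.
#' @param hop segmentation hop (default: window length).
#' @param k folds for the k-fold protocol.
#' @return an `eval_report` for `half_split`; a list of `k` reports for
#'   `kfold`.
#' @export
run_experiment <- function(streams, kind = c("step", "stride"),
                           protocol = c("half_split", "kfold"),
                           config = model_config(), filter = NULL,
                           seed = 1L, hop = NULL, k = 10L) {
  kind <- match.arg(kind)
  protocol <- match.arg(protocol)
  windows <- if (inherits(streams, "gait_windows")) {
    if (!identical(streams$kind, kind)) {
      stop_invalid("pre-segmented windows are '%s', requested '%s'",
                   streams$kind, kind)
    }
    streams
  } else {
    segment_corpus(streams, kind, hop = hop)
  }
  windows <- cohort_filter_windows(windows, filter)
  config$window_len <- windows$window_len
  config$n_classes <- NULL
  config$seed <- derive_seed(seed, "train")

  run_split <- function(split) {
    scaler <- fit_scaler(split$train)
    train_sc <- apply_scaler(scaler, split$train)
    test_sc <- apply_scaler(scaler, split$test)
    model <- train_classifier(config, train_sc)
    out <- predict_scores(model, test_sc)
    truths <- match(test_sc$info$subject_id, model$classes)
    if (anyNA(truths)) {
      stop_invalid("test subjects missing from the training class set")
    }
    new_eval_report(out$scores, truths, model$classes, protocol, kind,
                    seed, filter, n_windows(split$train))
  }

  if (protocol == "half_split") {
    run_split(half_split(windows, seed = derive_seed(seed, "split")))
  } else {
    folds <- kfold_splits(windows, k = k,
                          seed = derive_seed(seed, "split"))
    lapply(folds, run_split)
  }
}

#' Write an evaluation report as JSON
#'
#' @param report an `eval_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  x <- list(protocol = report$protocol, kind = report$kind,
            seed = report$seed, filter = report$filter,
            n_classes = report$n_classes, n_train = report$n_train,
            n_test = report$n_test, rank_k = report$rank_k,
            map_percent = report$map_percent,
            cmc = report$cmc$matching_rate,
            confusion = unname(report$confusion))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export CMC curve points as CSV
#'
#' @param cmc a `cmc_curve` (or an `eval_report`, whose curve is taken).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cmc_csv <- function(cmc, path) {
  if (inherits(cmc, "eval_report")) cmc <- cmc$cmc
  stopifnot(inherits(cmc, "cmc_curve"))
  utils::write.csv(data.frame(rank = cmc$ranks,
                              matching_rate = cmc$matching_rate),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a confusion matrix as CSV with demographic axis labels
#'
#' Rows and columns are labelled `"(F, 22, A)"`-style — gender initial, age,
#' setup — when window metadata are supplied.
#'
#' @param report an `eval_report`.
#' @param windows optional `gait_windows` carrying the subjects' metadata.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(report, path, windows = NULL) {
  stopifnot(inherits(report, "eval_report"))
  cm <- report$confusion
  labs <- report$classes
  if (!is.null(windows)) {
    info <- windows$info[!duplicated(windows$info$subject_id), ]
    m <- match(report$classes, info$subject_id)
    ok <- !is.na(m)
    labs[ok] <- sprintf("(%s, %d, %s)",
                        toupper(substr(info$gender[m[ok]], 1, 1)),
                        info$age_years[m[ok]], info$setup[m[ok]])
  }
  df <- as.data.frame(cm)
  dimnames(df) <- list(labs, labs)
  utils::write.csv(df, path, row.names = TRUE)
  invisible(path)
}
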