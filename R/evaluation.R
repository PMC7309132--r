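#' Confusion matrix over the seven actions
#'
#' Cell `(a, b)` counts test trials of true class `a` predicted as `b`.
#'
#' @param predictions Tibble with `truth` and `pred` columns (one row per
#'   trial), as returned by the predict functions.
#' @param classes Class ordering; defaults to the full taxonomy.
#' @return A `har_confusion` object: integer matrix with class dimnames.
#' @export
confusion_matrix <- function(predictions, classes = futsal_actions()) {
  check_actions(predictions$truth, "truth")
  check_actions(predictions$pred, "pred")
  m <- table(factor(predictions$truth, classes),
             factor(predictions$pred, classes))
  m <- unclass(as.matrix(m))
  names(dimnames(m)) <- c("target", "output")
  structure(m, class = c("har_confusion", class(m)))
}

#' Confusion matrix as percent of all trials
#' @param cm A `har_confusion`.
#' @return Numeric matrix summing to 100.
#' @export
confusion_percent <- function(cm) 100 * unclass(cm) / sum(cm)

#' Per-class one-vs-rest evaluation metrics
#'
#' For each class, the trial-level TP/TN/FP/FN are derived one-vs-rest and
#' the four metrics computed in percent: accuracy `(TP+TN)/total`,
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and the F1 score
#' `2PR/(P+R)`. Precision is `NA` ("absent") when the class was never
#' predicted (`TP+FP = 0`), and likewise recall when the class never
#' occurs; an F1 with zero TP is 0.
#'
#' @param cm A `har_confusion` from [confusion_matrix()].
#' @return A tibble `action`, `tp`, `tn`, `fp`, `fn`, `accuracy`,
#'   `precision`, `recall`, `f1` (metrics in percent).
#' @export
classwise_metrics <- function(cm) {
  m <- unclass(cm)
  total <- sum(m)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- total - tp - fp - fn
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(tp > 0,
               2 * precision * recall / (precision + recall),
               0)
  tibble::tibble(action = rownames(m),
                 tp = as.numeric(tp), tn = as.numeric(tn),
                 fp = as.numeric(fp), fn = as.numeric(fn),
                 accuracy = unname(100 * (tp + tn) / total),
                 precision = unname(100 * precision),
                 recall = unname(100 * recall),
                 f1 = unname(100 * f1))
}

#' Macro ("Total" row) aggregation of per-class metrics
#'
#' The unweighted mean over classes of each metric; an absent (`NA`)
#' precision or recall contributes zero, consistent with the reference
#' report's total rows.
#'
#' @param metrics Per-class metrics tibble from [classwise_metrics()] (or
#'   any tibble with `accuracy`, `precision`, `recall`, `f1` columns).
#' @return One-row tibble with the four macro metrics.
#' @export
macro_aggregate <- function(metrics) {
  agg <- function(x) mean(ifelse(is.na(x), 0, x))
  tibble::tibble(accuracy = agg(metrics$accuracy),
                 precision = agg(metrics$precision),
                 recall = agg(metrics$recall),
                 f1 = agg(metrics$f1))
}

fit_and_predict <- function(method, train_frame, test_frame,
                            train_seq, test_seq, seed,
                            ann_args = list(), lstm_args = list(),
                            dbmm_args = list()) {
  switch(method,
    ann = {
      model <- do.call(fit_ann, c(list(train_frame), ann_args,
                                  if (is.null(ann_args$seed))
                                    list(seed = derive_seed(seed, "ann"))))
      classify_trials_framewise(model, test_frame)
    },
    lstm = {
      model <- do.call(fit_lstm, c(list(train_seq), lstm_args,
                                   if (is.null(lstm_args$seed))
                                     list(seed = derive_seed(seed, "lstm"))))
      predict(model, test_seq)
    },
    dbmm = {
      model <- do.call(fit_dbmm, c(list(train_frame), dbmm_args,
                                   if (is.null(dbmm_args$seed))
                                     list(seed = seed)))
      predict(model, test_frame)
    },
    stop("unknown method '", method, "'", call. = FALSE))
}

#' Repeated stratified 70/30 benchmark
#'
#' Repeats the full evaluation protocol: a fresh stratified trial-level
#' 70/30 split per repeat (seeded), training of every requested method on
#' the training fold and evaluation on the test fold. Per-class metrics
#' and confusion-matrix cells are aggregated as mean and standard
#' deviation over the repeats.
#'
#' @param features Normalised features tibble (see [normalize_emg()]).
#' @param methods Any of `"ann"`, `"lstm"`, `"dbmm"`.
#' @param repeats Number of repeated splits.
#' @param base_seed Top-level seed; per-repeat and per-method sub-seeds are
#'   derived deterministically from it.
#' @param mask Feature mask (see [assemble_dataset()]).
#' @param train_frac Training fraction of the split.
#' @param ann_args,lstm_args,dbmm_args Extra arguments for the fitters.
#' @return A `benchmark_report`: list with `summary` (per method x class
#'   mean/sd metrics plus a `"total"` macro row), `confusion` (per method,
#'   `mean` and `sd` matrices), `per_repeat` (tibble of macro metrics per
#'   repeat), `seeds`, `repeats`, `methods`.
#' @export
repeated_benchmark <- function(features,
                               methods = c("ann", "lstm", "dbmm"),
                               repeats = 30, base_seed = 1, mask = "all",
                               train_frac = 0.7,
                               ann_args = list(), lstm_args = list(),
                               dbmm_args = list()) {
  frame_ds <- assemble_dataset(features, "frame", mask)
  seq_ds <- if ("lstm" %in% methods) {
    assemble_dataset(features, "sequence", mask)
  } else NULL
  seeds <- vapply(seq_len(repeats), function(r)
    derive_seed(base_seed, "split", r), 0)
  per_class <- list(); per_repeat <- list(); cms <- list()
  for (r in seq_len(repeats)) {
    sp <- train_test_split(frame_ds, train_frac = train_frac,
                           seed = seeds[r])
    train_ids <- unique(sp$train$trial_id)
    if (!is.null(seq_ds)) {
      tr_seq <- seq_ds[seq_ds$trial_id %in% train_ids, ]
      te_seq <- seq_ds[!seq_ds$trial_id %in% train_ids, ]
      attr(tr_seq, "layout") <- "sequence"; attr(te_seq, "layout") <- "sequence"
    } else tr_seq <- te_seq <- NULL
    for (mth in methods) {
      pred <- fit_and_predict(mth, sp$train, sp$test, tr_seq, te_seq,
                              seed = derive_seed(base_seed, "benchmark", r),
                              ann_args = ann_args, lstm_args = lstm_args,
                              dbmm_args = dbmm_args)
      cm <- confusion_matrix(pred)
      met <- classwise_metrics(cm)
      per_class[[length(per_class) + 1]] <-
        dplyr::mutate(met, method = mth, rep = r)
      per_repeat[[length(per_repeat) + 1]] <-
        dplyr::mutate(macro_aggregate(met), method = mth, rep = r)
      cms[[mth]] <- c(cms[[mth]], list(unclass(cm)))
    }
  }
  per_class <- dplyr::bind_rows(per_class)
  per_repeat <- dplyr::bind_rows(per_repeat)
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  class_summary <- dplyr::summarise(
    dplyr::group_by(per_class, .data$method, .data$action),
    dplyr::across(c("accuracy", "precision", "recall", "f1"),
                  list(mean = ~mean(.x, na.rm = TRUE), sd = ~sd0(.x[!is.na(.x)])),
                  .names = "{.col}_{.fn}"),
    .groups = "drop")
  total_summary <- dplyr::summarise(
    dplyr::group_by(per_repeat, .data$method),
    dplyr::across(c("accuracy", "precision", "recall", "f1"),
                  list(mean = ~mean(.x), sd = ~sd0(.x)),
                  .names = "{.col}_{.fn}"),
    .groups = "drop")
  total_summary$action <- "total"
  summary <- dplyr::bind_rows(class_summary, total_summary)
  confusion <- lapply(cms, function(lst) {
    arr <- simplify2array(lst)
    list(mean = apply(arr, c(1, 2), mean),
         sd = if (length(lst) > 1) apply(arr, c(1, 2), stats::sd)
              else array(0, dim(lst[[1]]), dimnames = dimnames(lst[[1]])))
  })
  structure(list(summary = summary, confusion = confusion,
                 per_repeat = per_repeat, per_class = per_class,
                 seeds = seeds, repeats = repeats, methods = methods,
                 mask = mask),
            class = "benchmark_report")
}

#' @export
tidy.benchmark_report <- function(x, ...) x$summary

#' @export
glance.benchmark_report <- function(x, ...) {
  tot <- x$summary[x$summary$action == "total", ]
  tibble::tibble(method = tot$method, repeats = x$repeats, mask = x$mask,
                 accuracy = tot$accuracy_mean, precision = tot$precision_mean,
                 recall = tot$recall_mean, f1 = tot$f1_mean)
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %d repeat(s), mask '%s'\n",
              x$repeats, x$mask))
  print(as.data.frame(glance(x)), row.names = FALSE)
  invisible(x)
}

#' Feature-ablation study
#'
#' Runs the benchmark once per feature mask (EMG alone, EMG plus each
#' kinematic feature, and all nine features) with a single method, and
#' collects the macro metrics per mask.
#'
#' @param features Normalised features tibble (all nine feature columns).
#' @param method One of `"ann"`, `"lstm"`, `"dbmm"`.
#' @param masks Feature masks to evaluate.
#' @param repeats Repeats per mask.
#' @param base_seed Top-level seed (shared across masks so splits match).
#' @param ... Passed to [repeated_benchmark()].
#' @return A tibble of macro metrics per mask, with the full reports in
#'   the `report` list-column.
#' @export
feature_ablation <- function(features, method = "lstm",
                             masks = c("emg", "emg+v", "emg+d", "emg+o", "all"),
                             repeats = 1, base_seed = 1, ...) {
  rows <- lapply(masks, function(mk) {
    rep <- repeated_benchmark(features, methods = method, repeats = repeats,
                              base_seed = base_seed, mask = mk, ...)
    dplyr::mutate(glance(rep), mask = mk, report = list(rep))
  })
  dplyr::bind_rows(rows)
}

# ------------------------------------------------------------------- plotting

#' @describeIn confusion_matrix Heatmap of the (percent) confusion matrix.
#' @param object A `har_confusion`.
#' @param ... Unused.
#' @export
autoplot.har_confusion <- function(object, ...) {
  df <- tibble::as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(df) <- c("target", "output", "n")
  df$pct <- 100 * df$n / sum(df$n)
  lab <- futsal_action_labels()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$output, y = .data$target,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_x_discrete(labels = lab) +
    ggplot2::scale_y_discrete(labels = lab, limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Output class", y = "Target class",
                  fill = "% of trials") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn repeated_benchmark Per-class F1 (mean over repeats) by method.
#' @param object A `benchmark_report`.
#' @param metric Which metric column to plot.
#' @param ... Unused.
#' @export
autoplot.benchmark_report <- function(object, metric = "f1", ...) {
  df <- object$summary[object$summary$action != "total", ]
  col <- paste0(metric, "_mean")
  sdc <- paste0(metric, "_sd")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$action, y = .data[[col]],
                                   fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[col]] - .data[[sdc]],
                                        ymax = .data[[col]] + .data[[sdc]]),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.25) +
    ggplot2::scale_x_discrete(labels = futsal_action_labels()) +
    ggplot2::labs(x = NULL, y = paste(toupper(metric), "(%)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
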