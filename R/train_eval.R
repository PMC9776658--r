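#' Clip-grouped k-fold splits
#'
#' Partitions sample records into k cross-validation folds such that all
#' windows of one source clip land in the same fold (no temporal leakage
#' between train and test). Each fold's test set is filled up to
#' `floor(N/k)` records, class-stratified and greedy-balanced; records of
#' clips that cannot fit under the cap are excluded from testing but remain
#' available for training (with N not divisible by k a few records are never
#' tested, mirroring floor division). Within each fold the non-test records
#' are split ~90/10 into training and validation, again grouped by clip.
#'
#' @param records Data frame of sample records with columns `clip_id` and
#'   `label` (see [enumerate_windows()]).
#' @param k Number of folds (default 3).
#' @param seed Integer seed making the assignment deterministic.
#' @return List of k fold splits, each with `fold_index`, `test_ids`,
#'   `train_ids`, `val_ids` (row indices into `records`).
#' @export
#' @examples
#' recs <- data.frame(clip_id = paste0("c", 1:6),
#'                    label = rep(fall_phases(), length.out = 6))
#' folds <- make_folds(recs, k = 3, seed = 1)
#' lengths(lapply(folds, `[[`, "test_ids"))
make_folds <- function(records, k = 3L, seed = 1L) {
  n <- nrow(records)
  if (n < k) stop_input("need at least k records to make k folds")
  target <- n %/% k
  clips <- unique(records[, c("clip_id", "label")])
  clip_sizes <- table(records$clip_id)
  fold_of <- stats::setNames(rep(NA_integer_, nrow(clips)), clips$clip_id)
  test_count <- integer(k)
  with_local_seed(seed, {
    for (lab in unique(clips$label)) {
      ids <- clips$clip_id[clips$label == lab]
      ids <- ids[sample.int(length(ids))]
      for (id in ids) {
        sz <- clip_sizes[[id]]
        ok <- which(test_count + sz <= target)
        if (length(ok) == 0) next  # cannot fit under the cap: never tested
        f <- ok[which.min(test_count[ok])]
        fold_of[id] <- f
        test_count[f] <- test_count[f] + sz
      }
    }
  })
  row_fold <- fold_of[records$clip_id]
  lapply(seq_len(k), function(f) {
    test_ids <- which(!is.na(row_fold) & row_fold == f)
    rest_ids <- setdiff(seq_len(n), test_ids)
    rest_clips <- unique(records$clip_id[rest_ids])
    val_ids <- integer(0)
    with_local_seed(seed + f, {
      rest_clips <- rest_clips[sample.int(length(rest_clips))]
    })
    n_val_target <- round(0.1 * length(rest_ids))
    for (id in rest_clips) {
      if (length(val_ids) >= n_val_target) break
      val_ids <- c(val_ids, rest_ids[records$clip_id[rest_ids] == id])
    }
    list(fold_index = f,
         test_ids = test_ids,
         train_ids = setdiff(rest_ids, val_ids),
         val_ids = val_ids)
  })
}

#' Confusion-matrix classification metrics
#'
#' One-vs-rest metrics from a square confusion matrix of counts (rows =
#' true class, columns = predicted class). For each class c, TP is the
#' diagonal entry, FN the rest of row c, FP the rest of column c and TN the
#' remainder; then accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity =
#' TP/(TP+FN), specificity = TN/(TN+FP) and precision = TP/(TP+FP), all
#' reported as percentages. Macro values average over classes; a class whose
#' ratio has a zero denominator yields NaN and is excluded from the macro
#' mean with a warning.
#'
#' @param confusion Square numeric matrix of nonnegative counts.
#' @return List with `per_class` (data frame), `macro` (named vector of the
#'   four percentages), `overall_accuracy` (trace/total, %) and the
#'   confusion matrix.
#' @export
#' @examples
#' compute_metrics(diag(c(10, 10, 10, 10)))$macro
compute_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop_input("confusion matrix must be square")
  if (any(confusion < 0)) stop_input("negative counts")
  total <- sum(confusion)
  k <- nrow(confusion)
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- total - tp - fn - fp
  ratio <- function(num, den) ifelse(den > 0, num / den, NaN)
  per_class <- data.frame(
    class = if (!is.null(rownames(confusion))) rownames(confusion)
            else as.character(seq_len(k)),
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = 100 * (tp + tn) / total,
    sensitivity = 100 * ratio(tp, tp + fn),
    specificity = 100 * ratio(tn, tn + fp),
    precision = 100 * ratio(tp, tp + fp),
    row.names = NULL, stringsAsFactors = FALSE)
  macro_of <- function(v, what) {
    if (any(is.nan(v))) {
      warning("undefined ", what, " for ",
              sum(is.nan(v)), " class(es); excluded from macro mean",
              call. = FALSE)
      v <- v[!is.nan(v)]
    }
    mean(v)
  }
  macro <- c(accuracy = macro_of(per_class$accuracy, "accuracy"),
             sensitivity = macro_of(per_class$sensitivity, "sensitivity"),
             specificity = macro_of(per_class$specificity, "specificity"),
             precision = macro_of(per_class$precision, "precision"))
  list(per_class = per_class, macro = macro,
       overall_accuracy = 100 * sum(tp) / total,
       confusion = confusion)
}

#' Confusion matrix from label/prediction pairs
#'
#' @param truth,pred Factors (or vectors coercible to factors) on the same
#'   level set.
#' @param levels Class levels defining the matrix order.
#' @return Square count matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(truth, pred, levels = fall_phases()) {
  t <- factor(truth, levels = levels)
  p <- factor(pred, levels = levels)
  if (any(is.na(t)) || any(is.na(p)))
    stop_input("labels outside the given level set")
  as.matrix(table(truth = t, pred = p))
}

#' Information density of a model
#'
#' Accuracy (in percent) divided by the learnable parameter count in
#' millions — a measure of parameter efficiency; higher is better.
#'
#' @param accuracy_pct Accuracy percentage (0-100).
#' @param params_millions Parameter count in millions (> 0).
#' @return Numeric score.
#' @export
#' @examples
#' information_density(99.03, 1.5)  # 66.02
information_density <- function(accuracy_pct, params_millions) {
  if (any(params_millions <= 0)) stop_input("params_millions must be > 0")
  accuracy_pct / params_millions
}

roc_points_by_class <- function(truth, probs, levels) {
  out <- list()
  for (ci in seq_along(levels)) {
    resp <- as.integer(truth == levels[ci])
    if (length(unique(resp)) < 2) next
    r <- pROC::roc(response = resp, predictor = probs[, ci],
                   quiet = TRUE, direction = "<")
    ord <- order(1 - r$specificities, r$sensitivities)
    out[[levels[ci]]] <- list(
      points = data.frame(fpr = (1 - r$specificities)[ord],
                          tpr = r$sensitivities[ord]),
      auc = as.numeric(pROC::auc(r)))
  }
  out
}

#' Cross-validated training and evaluation
#'
#' Runs the full evaluation protocol on a prepared dataset: clip-grouped
#' k-fold splits, one freshly initialized four-stream network trained per
#' fold (Adam, L2, best-validation checkpoint), metrics from the test-fold
#' confusion matrix, one-vs-rest ROC points per class, and mean +- sd of the
#' four macro metrics across the folds run.
#'
#' @param dataset List with `samples` (list of fused-stack arrays) and
#'   `records` (data frame with `clip_id` and `label`), as produced by
#'   [prepare_samples()].
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()]; its seed drives fold assignment,
#'   weight initialization and shuffling.
#' @param k Number of folds.
#' @param folds_to_run Integer subset of folds to train (default all k);
#'   useful for single-fold runs.
#' @return A `fall4s_metrics` report: per-fold metrics, confusion matrices,
#'   ROC points, summary (mean +- sd), and the information density of the
#'   model at the mean macro accuracy.
#' @export
run_cv <- function(dataset, model_cfg = model_config(),
                   train_cfg = train_config(), k = 3L,
                   folds_to_run = NULL) {
  records <- dataset$records
  samples <- dataset$samples
  stopifnot(length(samples) == nrow(records))
  classes <- PHASES
  folds <- make_folds(records, k = k, seed = train_cfg$seed)
  if (is.null(folds_to_run)) folds_to_run <- seq_len(k)
  graph <- build_model(model_cfg)
  fold_results <- list()
  for (f in folds_to_run) {
    fold <- folds[[f]]
    train_lab <- records$label[fold$train_ids]
    if (!all(classes %in% train_lab))
      stop_config("fold ", f, " is missing class(es) ",
                  paste(setdiff(classes, unique(train_lab)), collapse = ", "),
                  " in its training set")
    test_lab <- records$label[fold$test_ids]
    if (!all(classes %in% test_lab))
      stop_config("fold ", f, " is missing class(es) ",
                  paste(setdiff(classes, unique(test_lab)), collapse = ", "),
                  " in its test set")
    net <- init_network(model_cfg, seed = train_cfg$seed + 100L * f)
    fit <- train_network(net,
                         samples[fold$train_ids],
                         factor(train_lab, levels = classes),
                         samples[fold$val_ids],
                         records$label[fold$val_ids],
                         cfg = train_cfg)
    probs <- predict_network(fit$net, samples[fold$test_ids])
    pred <- classes[max.col(probs)]
    truth <- records$label[fold$test_ids]
    cm <- confusion_matrix(truth, pred, levels = classes)
    m <- compute_metrics(cm)
    fold_results[[as.character(f)]] <- list(
      fold_index = f, metrics = m,
      roc = roc_points_by_class(truth, probs, classes),
      history = fit$history,
      truth = truth, pred = pred, probs = probs)
  }
  macro_mat <- do.call(rbind,
                       lapply(fold_results, function(fr) fr$metrics$macro))
  summary <- data.frame(
    metric = colnames(macro_mat),
    mean = colMeans(macro_mat),
    sd = if (nrow(macro_mat) > 1) apply(macro_mat, 2, sd) else NA_real_,
    row.names = NULL)
  structure(list(folds = fold_results, summary = summary,
                 information_density = information_density(
                   summary$mean[summary$metric == "accuracy"],
                   count_parameters(graph) / 1e6),
                 params_millions = params_millions(graph),
                 n_samples = nrow(records)),
            class = "fall4s_metrics")
}

#' @export
print.fall4s_metrics <- function(x, ...) {
  cat(sprintf("Cross-validated metrics over %d fold(s), %d samples:\n",
              length(x$folds), x$n_samples))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %6.2f%%%s\n", s$metric[i], s$mean[i],
                if (is.na(s$sd[i])) "" else sprintf(" +- %.2f", s$sd[i])))
  }
  cat(sprintf("  information density: %.3f (%%/M params at %.1f M)\n",
              x$information_density, x$params_millions))
  invisible(x)
}

#' Export per-fold metrics as CSV
#'
#' @param report A `fall4s_metrics` report.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  rows <- do.call(rbind, lapply(report$folds, function(fr) {
    data.frame(fold = fr$fold_index, t(fr$metrics$macro))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Plot one-vs-rest ROC curves to a PNG
#'
#' @param report A `fall4s_metrics` report.
#' @param path PNG output path.
#' @return `path`, invisibly.
#' @export
plot_roc <- function(report, path) {
  grDevices::png(path, width = 640, height = 640)
  on.exit(grDevices::dev.off())
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "gray",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = "One-vs-rest ROC (test folds)")
  cols <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a")
  legend_items <- character(0); legend_cols <- character(0)
  for (fr in report$folds) {
    for (ci in seq_along(fr$roc)) {
      cls <- names(fr$roc)[ci]
      pts <- fr$roc[[ci]]$points
      graphics::lines(pts$fpr, pts$tpr, col = cols[match(cls, PHASES)])
      lab <- sprintf("%s (AUC %.3f, fold %d)", cls, fr$roc[[ci]]$auc,
                     fr$fold_index)
      legend_items <- c(legend_items, lab)
      legend_cols <- c(legend_cols, cols[match(cls, PHASES)])
    }
  }
  graphics::legend("bottomright", legend = legend_items, col = legend_cols,
                   lwd = 1, cex = 0.7)
  invisible(path)
}

#' Class bookkeeping of the Le2i-derived evaluation corpus
#'
#' Published per-class counts of manually cut phase videos and the 16-frame
#' overlapping sequences generated from them (overlap factor 5) in the
#' reference evaluation corpus. Useful as arithmetic inputs: the video
#' column sums to 455, the sequence column to 6392, and a 3-fold split
#' tests floor(6392/3) = 2130 sequences per fold.
#'
#' @return Data frame with columns `class`, `videos`, `sequences`.
#' @export
le2i_class_counts <- function() {
  data.frame(class = PHASES,
             videos = c(128L, 104L, 103L, 120L),
             sequences = c(1498L, 1464L, 1793L, 1637L),
             stringsAsFactors = FALSE)
}
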