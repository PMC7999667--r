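#' Confusion counts at a probability threshold
#'
#' An instance is predicted positive iff its probability is strictly
#' greater than `threshold` (default 0.5); a probability of exactly 0.5 is
#' therefore predicted negative.  The tie rule is pinned because it
#' changes counts whenever a classifier emits exact 0.5 probabilities
#' (k-NN with an even split does).
#'
#' @param labels integer vector of true labels (1 positive, 0 negative).
#' @param probabilities numeric vector in `[0, 1]`, parallel to `labels`.
#' @param threshold decision threshold.
#' @return named integer vector with elements `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(labels, probabilities, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("empty label vector")
  if (length(labels) != length(probabilities)) {
    stop("labels and probabilities differ in length")
  }
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE)) {
    stop("probabilities outside [0, 1]")
  }
  pred <- as.integer(probabilities > threshold)
  c(TP = sum(pred == 1L & labels == 1L),
    FP = sum(pred == 1L & labels == 0L),
    TN = sum(pred == 0L & labels == 0L),
    FN = sum(pred == 0L & labels == 1L))
}

#' Threshold classification metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)` and precision `TP/(TP+FP)`.  A metric whose
#' denominator is zero is returned as `NA` (flagged undefined), never as a
#' silent 0, so that averaging across folds can exclude it explicitly.
#'
#' @param counts named vector with `TP`, `FP`, `TN`, `FN` (as from
#'   [confusion_counts()]).
#' @return named numeric vector `acc`, `sens`, `spec`, `prec` with
#'   attribute `undefined` listing flagged metrics.
#' @export
classification_metrics <- function(counts) {
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(counts)))
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  total <- tp + fp + tn + fn
  if (total == 0L) stop("no evaluated instances")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- c(acc = (tp + tn) / total,
           sens = safe_div(tp, tp + fn),
           spec = safe_div(tn, tn + fp),
           prec = safe_div(tp, tp + fp))
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' ROC curve and AUC
#'
#' The AUC is computed as the Mann-Whitney concordance probability: the
#' probability that a randomly chosen positive receives a higher score
#' than a randomly chosen negative, with ties counted 1/2 (midrank
#' formula).  ROC points traverse the decision threshold from above the
#' largest score (FPR = TPR = 0) down to below the smallest (FPR = TPR =
#' 1).
#'
#' @inheritParams confusion_counts
#' @return list with `auc` (scalar) and `roc_points` (data frame with
#'   columns `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(labels, probabilities) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(probabilities))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC requires both classes present")
  }
  r <- rank(probabilities)  # midranks handle ties as 1/2
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thresholds <- c(Inf, sort(unique(probabilities), decreasing = TRUE))
  pts <- t(vapply(thresholds, function(t) {
    pred <- probabilities >= t
    c(fpr = sum(pred & labels == 0L) / n_neg,
      tpr = sum(pred & labels == 1L) / n_pos)
  }, c(fpr = 0, tpr = 0)))
  list(auc = auc,
       roc_points = data.frame(threshold = thresholds,
                               fpr = pts[, "fpr"], tpr = pts[, "tpr"]))
}

#' Stratified fold assignment
#'
#' Assigns each instance to one of `n_folds` folds so that folds partition
#' the data and each class is spread as evenly as possible (per-class fold
#' counts differ by at most one instance).
#'
#' @param labels integer class labels.
#' @param n_folds number of folds.
#' @param seed RNG seed for the within-class shuffle.
#' @return integer vector of fold ids in `1..n_folds`.
#' @export
stratified_folds <- function(labels, n_folds = 5L, seed = 1L) {
  labels <- as.integer(labels)
  if (any(table(labels) < n_folds)) {
    stop("every class must have at least n_folds = ", n_folds, " instances")
  }
  fold <- integer(length(labels))
  with_local_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

.metric_names <- c("acc", "sens", "spec", "prec", "auc")

# Aggregate a per-fold metric table into mean and 95% CI half-widths
# (normal approximation 1.96 * SD / sqrt(n)); undefined (NA) fold values
# are excluded from that metric's aggregation with a warning.
aggregate_folds <- function(per_fold) {
  mean_v <- ci_v <- stats::setNames(rep(NA_real_, length(.metric_names)),
                                    .metric_names)
  for (m in .metric_names) {
    v <- per_fold[[m]]
    if (anyNA(v)) {
      warning("metric '", m, "' undefined in ", sum(is.na(v)),
              " fold(s); excluded from its mean", call. = FALSE)
      v <- v[!is.na(v)]
    }
    if (length(v) > 0L) {
      mean_v[m] <- mean(v)
      ci_v[m] <- if (length(v) > 1L) 1.96 * sd(v) / sqrt(length(v)) else 0
    }
  }
  list(mean = mean_v, ci95 = ci_v)
}

#' Stratified k-fold cross-validation of one classifier configuration
#'
#' Encodes the dataset once (PseAAC features depend only on the sequence,
#' never on the labels, so pre-encoding leaks nothing), partitions it into
#' stratified folds, and for each fold fits the model on the remaining
#' folds and evaluates on the held-out fold at the 0.5 threshold.  Fold
#' means are reported with 95% confidence half-widths
#' (1.96 * SD / sqrt(n_folds)); the raw per-fold values are kept so any
#' other interval construction can be applied downstream.
#'
#' @param dataset a `labeled_dataset`.
#' @param config a [model_config()].
#' @param n_folds number of folds (default 5).
#' @param seed master seed; fold assignment and per-fold model seeds are
#'   derived from it.
#' @param table,params PseAAC encoding settings.
#' @return object of class `eval_report`: list with `per_fold` (data
#'   frame), `mean`, `ci95`, `protocol`, `seeds`, `roc_points` (from the
#'   pooled out-of-fold predictions) and `pooled_auc`.
#' @export
cross_validate <- function(dataset, config, n_folds = 5L, seed = 1L,
                           table = load_property_table(),
                           params = pseaac_params()) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  keep <- nchar(dataset$peptides$sequence) >= params$lambda + 1L
  if (any(!keep)) {
    message(sum(!keep), " peptide(s) too short to encode; excluded")
  }
  feats <- pseaac_encode_batch(dataset$peptides[keep, , drop = FALSE],
                               table = table, params = params)
  labels <- dataset$labels[keep]
  fold <- stratified_folds(labels, n_folds, seed = seed)
  oof <- rep(NA_real_, length(labels))
  per_fold <- vector("list", n_folds)
  fold_seeds <- seed + seq_len(n_folds)
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    model <- fit_model(config, feats[tr, , drop = FALSE], labels[tr],
                       seed = fold_seeds[k])
    p <- predict_proba(model, feats[!tr, , drop = FALSE])
    oof[!tr] <- p
    mets <- classification_metrics(confusion_counts(labels[!tr], p))
    per_fold[[k]] <- data.frame(fold = k, t(mets),
                                auc = roc_auc(labels[!tr], p)$auc)
  }
  per_fold <- do.call(rbind, per_fold)
  agg <- aggregate_folds(per_fold)
  pooled <- roc_auc(labels, oof)
  structure(list(per_fold = per_fold, mean = agg$mean, ci95 = agg$ci95,
                 protocol = sprintf("stratified %d-fold cross-validation",
                                    n_folds),
                 seeds = fold_seeds, roc_points = pooled$roc_points,
                 pooled_auc = pooled$auc, n = length(labels)),
            class = "eval_report")
}

#' Repeated train-on-one / test-on-another evaluation
#'
#' Fits the configured model on the full training dataset and evaluates it
#' on a second dataset, repeating the fit/predict cycle `n_repeats` times
#' with fresh seeds (families without training randomness simply repeat
#' the same value).  Sequence overlap between the two datasets is computed
#' and reported, since shared sequences would inflate the apparent
#' generalization.
#'
#' @param train_ds,test_ds `labeled_dataset` objects.
#' @param config a [model_config()].
#' @param n_repeats number of independent fit/predict repeats.
#' @param seed master seed; repeat seeds are derived from it.
#' @inheritParams cross_validate
#' @return an `eval_report` with one `per_fold` row per repeat and an
#'   `overlap` element (fraction of test sequences present in training).
#' @export
cross_dataset_eval <- function(train_ds, test_ds, config, n_repeats = 5L,
                               seed = 1L, table = load_property_table(),
                               params = pseaac_params()) {
  stopifnot(inherits(train_ds, "labeled_dataset"),
            inherits(test_ds, "labeled_dataset"))
  overlap <- mean(test_ds$peptides$sequence %in% train_ds$peptides$sequence)
  if (overlap > 0) {
    warning(sprintf("%.1f%% of test sequences also occur in training",
                    100 * overlap), call. = FALSE)
  }
  enc <- function(ds) {
    keep <- nchar(ds$peptides$sequence) >= params$lambda + 1L
    list(x = pseaac_encode_batch(ds$peptides[keep, , drop = FALSE],
                                 table = table, params = params),
         y = ds$labels[keep])
  }
  tr <- enc(train_ds)
  te <- enc(test_ds)
  rep_seeds <- seed + seq_len(n_repeats)
  per_rep <- vector("list", n_repeats)
  last_roc <- NULL
  for (r in seq_len(n_repeats)) {
    model <- fit_model(config, tr$x, tr$y, seed = rep_seeds[r])
    p <- predict_proba(model, te$x)
    mets <- classification_metrics(confusion_counts(te$y, p))
    rr <- roc_auc(te$y, p)
    last_roc <- rr$roc_points
    per_rep[[r]] <- data.frame(fold = r, t(mets), auc = rr$auc)
  }
  per_rep <- do.call(rbind, per_rep)
  agg <- aggregate_folds(per_rep)
  structure(list(per_fold = per_rep, mean = agg$mean, ci95 = agg$ci95,
                 protocol = sprintf(
                   "train '%s' / test '%s', %d repeats", train_ds$name,
                   test_ds$name, n_repeats),
                 seeds = rep_seeds, roc_points = last_roc,
                 overlap = overlap, n = length(te$y)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report:", x$protocol, sprintf("(n = %d)\n", x$n))
  for (m in .metric_names) {
    if (!is.na(x$mean[m])) {
      cat(sprintf("  %-5s %.4f +/- %.4f\n", m, x$mean[m], x$ci95[m]))
    }
  }
  if (!is.null(x$overlap)) {
    cat(sprintf("  train/test sequence overlap: %.1f%%\n", 100 * x$overlap))
  }
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the report as JSON and, optionally, the per-fold metrics and ROC
#' points as flat CSV files.
#'
#' @param report an `eval_report`.
#' @param path output JSON path.
#' @param csv_prefix if non-`NULL`, also write `<csv_prefix>_folds.csv`
#'   and `<csv_prefix>_roc.csv`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, csv_prefix = NULL) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(
    list(protocol = report$protocol, n = report$n,
         mean = as.list(report$mean), ci95 = as.list(report$ci95),
         per_fold = report$per_fold, seeds = report$seeds,
         overlap = report$overlap),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(csv_prefix)) {
    write.table(report$per_fold, paste0(csv_prefix, "_folds.csv"),
                sep = ",", row.names = FALSE, quote = FALSE)
    write.table(report$roc_points, paste0(csv_prefix, "_roc.csv"),
                sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
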