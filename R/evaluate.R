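#' Confusion-matrix metric panel
#'
#' Builds the full two-class report from counts, with MCS as the positive
#' condition: sensitivity (rate of MCS correctly classified), specificity
#' (rate of UWS correctly classified), false positive/negative rates,
#' per-class precisions, accuracy, F1 (harmonic mean of sensitivity and
#' MCS precision, the Dice coefficient) and the Matthews Correlation
#' Coefficient. MCC is defined as 0 (flagged `mcc_defined = FALSE`) when any
#' confusion-matrix marginal is zero.
#'
#' @param tp,fn,fp,tn non-negative counts (positive condition = MCS: `tp` are
#'   MCS called MCS, `tn` UWS called UWS, `fp` UWS called MCS, `fn` MCS
#'   called UWS).
#' @return A one-row tibble of class `classification_report` with the counts
#'   and all derived rates (proportions in `[0, 1]`).
#' @export
#' @examples
#' classification_report(tp = 15, fn = 1, fp = 1, tn = 13)
classification_report <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop_hrvci("hrvci_error_bad_argument", "counts must be non-negative integers.")
  }
  n <- tp + fn + fp + tn
  if (n < 1) stop_hrvci("hrvci_error_bad_argument", "empty confusion matrix.")
  div <- function(num, den) if (den > 0) num / den else NA_real_
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc_defined <- all(marg > 0)
  mcc <- if (mcc_defined) {
    (tp * tn - fp * fn) / sqrt(prod(marg))
  } else {
    0
  }
  out <- tibble(
    tp = tp, fn = fn, fp = fp, tn = tn, n = n,
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    fpr = div(fp, fp + tn),
    fnr = div(fn, fn + tp),
    precision_mcs = div(tp, tp + fp),
    precision_uws = div(tn, tn + fn),
    accuracy = (tp + tn) / n,
    f1 = div(2 * tp, 2 * tp + fp + fn),
    mcc = mcc,
    mcc_defined = mcc_defined
  )
  class(out) <- c("classification_report", class(out))
  out
}

#' Evaluate predicted against true diagnoses
#'
#' @param truth true class labels.
#' @param predicted predicted class labels, same length.
#' @param positive the positive-condition label (default `"MCS"`; everything
#'   else is treated as the negative class).
#' @return A [classification_report()].
#' @export
evaluate_classifier <- function(truth, predicted, positive = "MCS") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop_hrvci("hrvci_error_bad_argument", "`truth` and `predicted` lengths differ.")
  }
  if (!length(truth)) stop_hrvci("hrvci_error_bad_argument", "empty label vectors.")
  labs <- unique(c(truth, predicted))
  if (!positive %in% labs) {
    stop_hrvci("hrvci_error_bad_argument",
               sprintf("positive label `%s` absent from the data.", positive))
  }
  if (length(labs) > 2L) {
    stop_hrvci("hrvci_error_bad_argument",
               sprintf("expected 2 labels, found: %s.", paste(labs, collapse = ", ")))
  }
  is_pos_t <- truth == positive
  is_pos_p <- predicted == positive
  classification_report(
    tp = sum(is_pos_t & is_pos_p),
    fn = sum(is_pos_t & !is_pos_p),
    fp = sum(!is_pos_t & is_pos_p),
    tn = sum(!is_pos_t & !is_pos_p)
  )
}

#' Metric panel in display layout
#'
#' Long-format report in the conventional row order (true-positive rate,
#' true-negative rate, FNR, FPR, per-class precision, accuracy, F1, MCC) with
#' both the unrounded value and the printed form (integer percents; MCC to
#' two decimals).
#'
#' @param report a [classification_report()].
#' @return A tibble: `metric`, `value` (unrounded, percent scale except MCC),
#'   `printed`.
#' @export
report_table <- function(report) {
  if (!inherits(report, "classification_report")) {
    stop_hrvci("hrvci_error_bad_argument", "`report` must be a classification_report.")
  }
  pct <- function(x) 100 * x
  metrics <- c(
    "True positive (MCS) rate (%)" = pct(report$sensitivity),
    "True negative (UWS) rate (%)" = pct(report$specificity),
    "False negative rate (%)" = pct(report$fnr),
    "False positive rate (%)" = pct(report$fpr),
    "Precision MCS classification (%)" = pct(report$precision_mcs),
    "Precision UWS classification (%)" = pct(report$precision_uws),
    "Accuracy (%)" = pct(report$accuracy),
    "F1-score (%)" = pct(report$f1),
    "Matthews Correlation Coefficient [-1:1]" = report$mcc
  )
  printed <- c(sprintf("%.0f", metrics[1:8]), sprintf("%.2f", metrics[9]))
  tibble(metric = names(metrics), value = unname(metrics), printed = printed)
}

#' Tidy a classification report
#' @param x a [classification_report()].
#' @param ... unused.
#' @return Long tibble of `metric`, `value` proportions.
#' @export
tidy.classification_report <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::select(as_tibble(x), -"mcc_defined"),
    dplyr::everything(), names_to = "metric", values_to = "value"
  )
}

#' Stratified k-fold cross-validation of the One-R classifier
#'
#' Splits the cohort into `k` folds of equal size (within one), fits One-R on
#' each training set and predicts the held-out fold, so every record is
#' tested exactly once. With `stratified = TRUE` (default) class proportions
#' are balanced across folds. The pooled (micro-averaged) confusion matrix
#' across folds gives the reported metric panel. Fully reproducible given
#' `seed`.
#'
#' @inheritParams fit_oner
#' @param k number of folds (default 10).
#' @param stratified balance class proportions across folds (default TRUE).
#' @param seed integer seed for the fold assignment (required).
#' @return An object of class `oner_cv`: `pooled` ([classification_report()]),
#'   `predictions` (row per record: `fold`, `truth`, `predicted`),
#'   `fold_models` (list of per-fold `oner_model`s), `k`, `seed`.
#' @export
cross_validate <- function(data, k = 10L, stratified = TRUE, seed,
                           features = c("ci_s", "ci_l"), outcome = "diagnosis",
                           min_bucket = 6L) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop_hrvci("hrvci_error_bad_argument", "`k` must be >= 2.")
  n <- nrow(data)
  if (k > n) {
    stop_hrvci("hrvci_error_bad_argument",
               sprintf("k (%d) exceeds the cohort size (%d).", k, n))
  }
  if (missing(seed) || is.null(seed)) {
    stop_hrvci("hrvci_error_bad_argument", "`seed` is required for reproducible folds.")
  }
  y <- as.character(data[[outcome]])
  fold <- integer(n)
  with_seed_if(seed, {
    if (stratified) {
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
      # rotate fold ids so fold sizes stay equal within 1 overall
      sizes <- tabulate(fold, k)
      while (max(sizes) - min(sizes) > 1L) {
        from <- which.max(sizes); to <- which.min(sizes)
        mv <- which(fold == from)[1]
        fold[mv] <- to
        sizes <- tabulate(fold, k)
      }
    } else {
      fold <- rep_len(seq_len(k), n)[sample.int(n)]
    }
  })
  preds <- character(n)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- fit_oner(data[!test, , drop = FALSE], features = features,
                    outcome = outcome, min_bucket = min_bucket)
    models[[f]] <- fit
    preds[test] <- predict(fit, data[test, , drop = FALSE])
  }
  out <- list(
    pooled = evaluate_classifier(y, preds),
    predictions = tibble(fold = fold, truth = y, predicted = preds),
    fold_models = models,
    k = k, seed = seed, stratified = stratified
  )
  class(out) <- "oner_cv"
  out
}

#' @export
print.oner_cv <- function(x, ...) {
  cat(sprintf("<oner_cv> %d-fold%s cross-validation (seed %s)\n", x$k,
              if (x$stratified) " stratified" else "", format(x$seed)))
  cat(sprintf("  pooled accuracy: %.1f%%  (tp %d, fn %d, fp %d, tn %d)\n",
              100 * x$pooled$accuracy, x$pooled$tp, x$pooled$fn,
              x$pooled$fp, x$pooled$tn))
  invisible(x)
}

#' Tidy cross-validation results
#' @param x an `oner_cv`.
#' @param ... unused.
#' @return One row per fold: `fold`, `n_test`, `accuracy`, `attribute`.
#' @export
tidy.oner_cv <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$predictions, .data$fold),
    n_test = dplyr::n(),
    accuracy = mean(.data$truth == .data$predicted),
    .groups = "drop"
  ) |>
    dplyr::mutate(attribute = vapply(x$fold_models, `[[`, "", "attribute"))
}

#' Glance at cross-validation results
#' @param x an `oner_cv`.
#' @param ... unused.
#' @return The pooled metric panel as a one-row tibble.
#' @export
glance.oner_cv <- function(x, ...) {
  as_tibble(x$pooled)
}
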