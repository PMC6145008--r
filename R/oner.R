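#' One-R discretization of a single attribute
#'
#' Sorts the values and grows bins greedily: a bin keeps absorbing instances
#' until some class holds at least `min_bucket` members of it; the bin then
#' continues to extend while the next instance either shares the current
#' boundary value or belongs to the bin's majority class (the rule-induction
#' behaviour of the reference One-R implementation, which keeps a pure class
#' run in one bin). Adjacent bins with the same majority label are merged and
#' boundaries are placed at midpoints between the adjacent distinct values
#' across each surviving bin edge. Majority ties inside a bin are broken
#' toward the first class in factor-level (or sorted) order.
#'
#' @param values numeric attribute values.
#' @param labels class labels, same length as `values`.
#' @param min_bucket minimum majority-class count before a bin may close
#'   (default 6, the reference implementation's default).
#' @return A list: `boundaries` (strictly increasing split points),
#'   `bin_labels` (one more label than boundaries), `error` (training
#'   misclassifications under bin majority labels), `n`.
#' @export
#' @examples
#' discretize_attribute(c(3, 3.5, 4, 5, 5.5, 6),
#'                      c("U", "U", "U", "M", "M", "M"), min_bucket = 3)
discretize_attribute <- function(values, labels, min_bucket = 6L) {
  if (length(values) != length(labels)) {
    stop_hrvci("hrvci_error_bad_argument", "`values` and `labels` lengths differ.")
  }
  if (anyNA(values) || anyNA(labels)) {
    stop_hrvci("hrvci_error_bad_argument", "missing values in attribute or labels.")
  }
  min_bucket <- as.integer(min_bucket)
  if (is.na(min_bucket) || min_bucket < 1L) {
    stop_hrvci("hrvci_error_bad_argument", "`min_bucket` must be an integer >= 1.")
  }
  n <- length(values)
  if (n < min_bucket) {
    stop_hrvci("hrvci_error_bad_argument",
               sprintf("fewer values (%d) than min_bucket (%d).", n, min_bucket))
  }
  classes <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  lab <- as.character(labels)
  ord <- order(values)
  v <- as.numeric(values)[ord]
  l <- lab[ord]

  starts <- integer(0); ends <- integer(0); bin_lab <- character(0)
  i <- 1L
  while (i <= n) {
    cnt <- stats::setNames(integer(length(classes)), classes)
    j <- i
    repeat {
      cnt[l[j]] <- cnt[l[j]] + 1L
      if (j == n) break
      if (max(cnt) >= min_bucket) {
        maj <- classes[which.max(cnt)]
        if (v[j + 1L] != v[j] && l[j + 1L] != maj) break
      }
      j <- j + 1L
    }
    starts <- c(starts, i); ends <- c(ends, j)
    bin_lab <- c(bin_lab, classes[which.max(cnt)])
    i <- j + 1L
  }
  # merge adjacent bins sharing the majority label
  keep <- c(TRUE, bin_lab[-1] != bin_lab[-length(bin_lab)])
  m_starts <- starts[keep]
  m_ends <- c(m_starts[-1] - 1L, n)
  m_ends <- vapply(seq_along(m_starts), function(k) {
    if (k < length(m_starts)) m_starts[k + 1L] - 1L else n
  }, integer(1))
  m_lab <- bin_lab[keep]
  boundaries <- if (length(m_starts) > 1L) {
    vapply(seq_len(length(m_starts) - 1L), function(k) {
      (v[m_ends[k]] + v[m_starts[k + 1L]]) / 2
    }, numeric(1))
  } else {
    numeric(0)
  }
  err <- sum(vapply(seq_along(m_starts), function(k) {
    seg <- l[m_starts[k]:m_ends[k]]
    sum(seg != m_lab[k])
  }, integer(1)))
  list(boundaries = boundaries, bin_labels = m_lab, error = err, n = n)
}

#' Fit a One-R single-attribute rule
#'
#' Discretizes each candidate feature with [discretize_attribute()] and keeps
#' the rule with the minimum training error — a one-level decision tree. Ties
#' between features are broken by their order in `features` (recorded in the
#' model). A single-class cohort yields a degenerate constant model, flagged
#' with a warning.
#'
#' @param data a data frame with the feature columns and the outcome column.
#' @param features character vector of candidate feature names (default
#'   `c("ci_s", "ci_l")`).
#' @param outcome name of the class column (default `"diagnosis"`).
#' @param min_bucket discretization parameter (default 6).
#' @return An object of class `oner_model`: `attribute`, `boundaries`,
#'   `bin_labels`, `training_error`, `feature_errors`, `min_bucket`, `n`,
#'   `classes`, `degenerate`.
#' @export
fit_oner <- function(data, features = c("ci_s", "ci_l"), outcome = "diagnosis",
                     min_bucket = 6L) {
  if (!length(features)) stop_hrvci("hrvci_error_bad_argument", "`features` is empty.")
  missing_cols <- setdiff(c(features, outcome), names(data))
  if (length(missing_cols)) {
    stop_hrvci("hrvci_error_bad_argument",
               sprintf("missing column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  y <- data[[outcome]]
  classes <- if (is.factor(y)) levels(y) else sort(unique(as.character(y)))
  if (length(classes) < 2L) {
    warn_hrvci("hrvci_warning_degenerate",
               "single-class data: returning a degenerate constant model.")
    model <- list(attribute = features[1], boundaries = numeric(0),
                  bin_labels = as.character(classes[1]), training_error = 0L,
                  feature_errors = stats::setNames(rep(0L, length(features)), features),
                  min_bucket = as.integer(min_bucket), n = nrow(data),
                  outcome = outcome, classes = classes, degenerate = TRUE)
    class(model) <- "oner_model"
    return(model)
  }
  rules <- lapply(features, function(f) {
    discretize_attribute(data[[f]], y, min_bucket = min_bucket)
  })
  errs <- vapply(rules, `[[`, numeric(1), "error")
  best <- which.min(errs)   # ties: earliest feature wins
  rule <- rules[[best]]
  model <- list(attribute = features[best], boundaries = rule$boundaries,
                bin_labels = rule$bin_labels, training_error = rule$error,
                feature_errors = stats::setNames(errs, features),
                min_bucket = as.integer(min_bucket), n = nrow(data),
                outcome = outcome, classes = classes, degenerate = FALSE)
  class(model) <- "oner_model"
  model
}

#' Fit a Zero-R baseline
#'
#' Constant classifier predicting the majority class; ties are broken toward
#' `"MCS"` when present, otherwise toward the first class level.
#'
#' @inheritParams fit_oner
#' @return An object of class `zeror_model` with the constant prediction and
#'   its training error.
#' @export
fit_zeror <- function(data, outcome = "diagnosis") {
  if (!nrow(data)) stop_hrvci("hrvci_error_bad_argument", "empty cohort.")
  y <- as.character(data[[outcome]])
  counts <- sort(table(y), decreasing = TRUE)
  top <- names(counts[counts == max(counts)])
  pred <- if ("MCS" %in% top) "MCS" else top[1]
  model <- list(prediction = pred, counts = counts,
                training_error = sum(y != pred), n = length(y), outcome = outcome)
  class(model) <- "zeror_model"
  model
}

#' @param object an `oner_model`.
#' @param newdata data frame carrying the model's attribute column.
#' @param ... unused.
#' @describeIn fit_oner Predict class labels: each value falls in the bin
#'   containing it, with boundary values classified into the upper bin
#'   (a value equal to a split point takes the label of the `>=` side).
#' @export
predict.oner_model <- function(object, newdata, ...) {
  if (object$degenerate) return(rep(object$bin_labels[1], nrow(newdata)))
  if (!object$attribute %in% names(newdata)) {
    stop_hrvci("hrvci_error_bad_argument",
               sprintf("`newdata` lacks the model attribute `%s`.", object$attribute))
  }
  x <- newdata[[object$attribute]]
  if (anyNA(x)) {
    stop_hrvci("hrvci_error_bad_argument",
               sprintf("missing `%s` value(s) in `newdata`.", object$attribute))
  }
  bins <- findInterval(x, object$boundaries) + 1L
  object$bin_labels[bins]
}

#' @param object a `zeror_model`.
#' @param newdata data frame (only its row count is used).
#' @param ... unused.
#' @describeIn fit_zeror Predict the constant majority class.
#' @export
predict.zeror_model <- function(object, newdata, ...) {
  rep(object$prediction, nrow(newdata))
}

#' @export
print.oner_model <- function(x, ...) {
  cat("<oner_model> One-R rule on", x$attribute, "\n")
  if (!length(x$boundaries)) {
    cat("  constant:", x$bin_labels[1], "\n")
  } else {
    for (k in seq_along(x$bin_labels)) {
      lo <- if (k == 1) "-Inf" else sprintf("%.4g", x$boundaries[k - 1])
      hi <- if (k > length(x$boundaries)) "Inf" else sprintf("%.4g", x$boundaries[k])
      cat(sprintf("  [%s, %s) -> %s\n", lo, hi, x$bin_labels[k]))
    }
  }
  cat(sprintf("  training error: %d / %d\n", x$training_error, x$n))
  invisible(x)
}

#' @export
print.zeror_model <- function(x, ...) {
  cat(sprintf("<zeror_model> always predicts %s (training error %d / %d)\n",
              x$prediction, x$training_error, x$n))
  invisible(x)
}

#' Tidy a One-R model
#' @param x an `oner_model`.
#' @param ... unused.
#' @return One row per bin: `bin`, `lower`, `upper`, `label`.
#' @export
tidy.oner_model <- function(x, ...) {
  nb <- length(x$bin_labels)
  tibble(
    bin = seq_len(nb),
    lower = c(-Inf, x$boundaries),
    upper = c(x$boundaries, Inf),
    label = x$bin_labels
  )
}

#' Glance at a One-R model
#' @param x an `oner_model`.
#' @param ... unused.
#' @return A one-row tibble: `attribute`, `n_bins`, `training_error`, `n`.
#' @export
glance.oner_model <- function(x, ...) {
  tibble(attribute = x$attribute, n_bins = length(x$bin_labels),
         training_error = x$training_error, n = x$n)
}
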