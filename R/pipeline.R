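#' Read / write a cohort table
#'
#' The cohort CSV carries one row per subject with columns `subject_id`,
#' `diagnosis` (`UWS`/`MCS`), `crs_r_total`, `ci_s`, `ci_l`; extra columns
#' are preserved.
#'
#' @param path CSV file path.
#' @return `read_cohort()` returns a tibble; `write_cohort()` returns `path`
#'   invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop_hrvci("hrvci_error_io", sprintf("cohort file not found: %s", path))
  }
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "diagnosis", "ci_s", "ci_l")
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    stop_hrvci("hrvci_error_parse",
               sprintf("cohort file lacks column(s): %s.", paste(miss, collapse = ", ")))
  }
  out
}

#' @param cohort a cohort tibble (list columns such as `ibi` are dropped).
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  flat <- cohort[, !vapply(cohort, is.list, logical(1)), drop = FALSE]
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

# run one pipeline stage, rethrowing errors tagged with stage and subject
run_stage <- function(stage, subject_id, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(
      sprintf("[%s] stage `%s` failed: %s", subject_id, stage, conditionMessage(e)),
      class = c("hrvci_error_stage", "hrvci_error"), parent = e, stage = stage
    )
  })
}

#' Run the per-subject pipeline
#'
#' Takes one recording — either a pre-extracted interval (`.rr`) file, which
#' skips detection, or a sampled waveform, which runs filter, beat detection,
#' ectopic screening and segment extraction — and returns the subject's
#' per-scale entropies and complexity indices. Any stage failure is reported
#' with the stage name and subject id.
#'
#' @param input an [ibi_series()], [waveform()], or a path to an interval or
#'   waveform file.
#' @param subject_id subject label used in outputs and error messages.
#' @param input_type `"auto"` (by extension/class), `"ibi"` or `"waveform"`.
#' @param sampling_rate Hz, required for single-column waveform files.
#' @param channel `"ecg"` or `"ppg"` (selects the filter band and detector).
#' @param passband FFT filter band in Hz; default `c(0.5, 40)` for ECG,
#'   `c(0.5, 8)` for PPG.
#' @param segment analysis segment duration in seconds (default 600); `NULL`
#'   analyses the screened series as-is (for pre-extracted segments).
#' @param ectopic_action `"flag"`, `"interpolate"` or `"delete"`.
#' @param m,r,max_scale,r_convention entropy parameters, see [mse_curve()].
#' @param out_dir optional directory; writes `<subject_id>_ci.csv` there.
#' @return A one-row tibble: `subject_id`, `n_intervals`, `sd_ref`,
#'   `ectopic_fraction`, `se_1` .. `se_<max_scale>`, `ci_s`, `ci_l`,
#'   `ci_total`.
#' @export
run_subject <- function(input, subject_id = "subject",
                        input_type = c("auto", "ibi", "waveform"),
                        sampling_rate = NULL, channel = c("ecg", "ppg"),
                        passband = NULL, segment = 600,
                        ectopic_action = "flag",
                        m = 2L, r = 0.15, max_scale = 10L,
                        r_convention = "fixed_scale1_sd", out_dir = NULL) {
  input_type <- match.arg(input_type)
  channel <- match.arg(channel)
  if (is.character(input)) {
    if (input_type == "auto") {
      input_type <- if (grepl("\\.(rr|ibi)$", input, ignore.case = TRUE)) "ibi" else "waveform"
    }
    input <- run_stage("read", subject_id, {
      if (input_type == "ibi") read_ibi(input)
      else read_waveform(input, sampling_rate = sampling_rate, channel = channel)
    })
  } else if (input_type == "auto") {
    input_type <- if (inherits(input, "hrv_waveform")) "waveform" else "ibi"
  }
  if (input_type == "waveform") {
    passband <- passband %||% if (channel == "ecg") c(0.5, 40) else c(0.5, 8)
    filtered <- run_stage("fft_filter", subject_id, fft_filter(input, passband))
    beats <- run_stage("detect_beats", subject_id, {
      detect_beats(filtered, method = if (channel == "ecg") "ecg_qrs" else "ppg_pulse")
    })
    ibi <- run_stage("to_ibi", subject_id, to_ibi(beats))
  } else {
    ibi <- input
  }
  screened <- run_stage("screen_ectopics", subject_id,
                        screen_ectopics(ibi, action = ectopic_action))
  seg <- if (is.null(segment)) {
    screened
  } else {
    run_stage("extract_segment", subject_id,
              extract_segment(screened, duration = segment))
  }
  curve <- run_stage("mse_curve", subject_id,
                     mse_curve(seg, m = m, r = r, max_scale = max_scale,
                               r_convention = r_convention))
  ci <- run_stage("complexity_index", subject_id,
                  complexity_indices(curve, strict = TRUE))
  se_wide <- stats::setNames(as.list(curve$se), paste0("se_", curve$scale))
  out <- dplyr::bind_cols(
    tibble(subject_id = subject_id, n_intervals = nrow(seg),
           sd_ref = attr(curve, "sd_ref"),
           ectopic_fraction = attr(screened, "ectopic_fraction") %||% 0),
    as_tibble(se_wide),
    dplyr::select(ci, -"sd_ref")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(out, file.path(out_dir, paste0(subject_id, "_ci.csv")),
                     progress = FALSE)
  }
  out
}

#' Run the cohort-level analysis
#'
#' Group statistics (Mann-Whitney on `ci_s` and `ci_l` between diagnoses,
#' Spearman correlation of each index with the CRS-R total), One-R rule
#' induction with a full-training metric panel, the Zero-R baseline, and
#' stratified k-fold cross-validation. When `out_dir` is given, writes
#' `cohort_report.json` and `cohort_report.tsv` (metric panels in the
#' conventional row order) plus the frozen configuration `run_config.json`.
#'
#' @param cohort a cohort tibble or CSV path (see [read_cohort()]).
#' @param features classifier features (default `c("ci_s", "ci_l")`).
#' @param k cross-validation folds (default 10).
#' @param seed integer seed for the fold assignment (required).
#' @param min_bucket One-R discretization parameter (default 6).
#' @param out_dir optional output directory.
#' @return A list of class `cohort_analysis`: `tests` (tibble of the four
#'   group tests), `model` (`oner_model`), `full_report`, `cv` (`oner_cv`),
#'   `zeror`, `zeror_report`, `config`.
#' @export
run_cohort <- function(cohort, features = c("ci_s", "ci_l"), k = 10L, seed,
                       min_bucket = 6L, out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (missing(seed) || is.null(seed)) {
    stop_hrvci("hrvci_error_bad_argument", "`seed` is required.")
  }
  need <- c("diagnosis", features)
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop_hrvci("hrvci_error_bad_argument",
               sprintf("cohort lacks column(s): %s.", paste(miss, collapse = ", ")))
  }
  if (length(unique(cohort$diagnosis)) < 2L) {
    stop_hrvci("hrvci_error_bad_argument", "cohort has a single diagnosis class.")
  }
  tests <- dplyr::bind_rows(lapply(features, function(f) {
    mw <- mann_whitney_exact(cohort, !!rlang::sym(f), "diagnosis")
    mw$comparison <- sprintf("%s by diagnosis", f)
    mw
  }))
  if ("crs_r_total" %in% names(cohort)) {
    cors <- dplyr::bind_rows(lapply(features, function(f) {
      sp <- spearman_test(cohort, "crs_r_total", !!rlang::sym(f))
      sp$comparison <- sprintf("crs_r_total vs %s", f)
      sp
    }))
    tests <- dplyr::bind_rows(tests, cors)
  }
  model <- fit_oner(cohort, features = features, min_bucket = min_bucket)
  full_report <- evaluate_classifier(cohort$diagnosis, predict(model, cohort))
  zr <- fit_zeror(cohort)
  zeror_report <- evaluate_classifier(cohort$diagnosis, predict(zr, cohort))
  cv <- cross_validate(cohort, k = k, seed = seed, features = features,
                       min_bucket = min_bucket)
  config <- list(features = features, k = k, seed = seed,
                 min_bucket = min_bucket, n = nrow(cohort))
  out <- list(tests = tests, model = model, full_report = full_report,
              cv = cv, zeror = zr, zeror_report = zeror_report,
              config = config)
  class(out) <- "cohort_analysis"
  if (!is.null(out_dir)) write_cohort_report(out, out_dir)
  out
}

write_cohort_report <- function(analysis, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- dplyr::bind_rows(
    dplyr::mutate(report_table(analysis$full_report), column = "full_training"),
    dplyr::mutate(report_table(analysis$cv$pooled),
                  column = sprintf("%d_fold_cv", analysis$cv$k))
  )
  panel <- dplyr::select(panel, "column", "metric", "value", "printed")
  readr::write_tsv(panel, file.path(out_dir, "cohort_report.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(
      tests = analysis$tests,
      rule = list(attribute = analysis$model$attribute,
                  boundaries = analysis$model$boundaries,
                  bin_labels = analysis$model$bin_labels,
                  min_bucket = analysis$model$min_bucket),
      full_training = as.list(analysis$full_report),
      cv_pooled = as.list(analysis$cv$pooled),
      zeror = as.list(analysis$zeror_report),
      panel = panel
    ),
    file.path(out_dir, "cohort_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  jsonlite::write_json(analysis$config, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis>\n\nGroup tests:\n")
  print(as_tibble(x$tests))
  cat("\n")
  print(x$model)
  cat(sprintf("\nFull-training accuracy: %.1f%%; %d-fold CV accuracy: %.1f%%; Zero-R: %.1f%%\n",
              100 * x$full_report$accuracy, x$cv$k, 100 * x$cv$pooled$accuracy,
              100 * x$zeror_report$accuracy))
  invisible(x)
}

#' Cohort complexity plots
#'
#' `plot_ci_by_group()` draws the by-diagnosis box plot of a complexity
#' index; `plot_ci_vs_crsr()` the dispersion of an index against the CRS-R
#' total.
#'
#' @param cohort a cohort tibble.
#' @param index which index to plot (default `"ci_l"`).
#' @return A ggplot.
#' @export
plot_ci_by_group <- function(cohort, index = "ci_l") {
  ggplot2::ggplot(cohort, ggplot2::aes(x = .data$diagnosis,
                                       y = .data[[index]],
                                       fill = .data$diagnosis)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = 21) +
    ggplot2::scale_fill_manual(values = c(MCS = "white", UWS = "grey60")) +
    ggplot2::labs(x = NULL, y = index) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @rdname plot_ci_by_group
#' @export
plot_ci_vs_crsr <- function(cohort, index = "ci_l") {
  ggplot2::ggplot(cohort, ggplot2::aes(x = .data$crs_r_total,
                                       y = .data[[index]],
                                       shape = .data$diagnosis)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(values = c(MCS = 1, UWS = 16)) +
    ggplot2::labs(x = "CRS-R total score", y = index, shape = NULL) +
    ggplot2::theme_minimal()
}
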