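#' Interbeat-interval (tachogram) container
#'
#' The tachogram is stored as a tibble with one row per interbeat interval:
#' `interval_ms` (duration in milliseconds) and `flag`, one of `"normal"`,
#' `"ectopic"`, `"missing"` or `"edited"`. All entropy computations consume
#' intervals in milliseconds.
#'
#' @param intervals numeric vector of interbeat intervals in ms, all > 0.
#' @param flags character vector of per-interval quality flags (recycled).
#' @return A tibble of class `hrv_ibi` with columns `interval_ms`, `flag`.
#' @export
ibi_series <- function(intervals, flags = "normal") {
  if (!is.numeric(intervals) || length(intervals) < 1L) {
    stop_hrvci("hrvci_error_bad_argument", "`intervals` must be a non-empty numeric vector.")
  }
  if (anyNA(intervals) || any(intervals <= 0)) {
    stop_hrvci("hrvci_error_bad_argument", "all interbeat intervals must be finite and > 0 ms.")
  }
  ok_flags <- c("normal", "ectopic", "missing", "edited")
  flags <- rep_len(as.character(flags), length(intervals))
  if (!all(flags %in% ok_flags)) {
    stop_hrvci("hrvci_error_bad_argument",
               sprintf("flags must be one of: %s.", paste(ok_flags, collapse = ", ")))
  }
  out <- tibble(interval_ms = as.numeric(intervals), flag = flags)
  class(out) <- c("hrv_ibi", class(out))
  out
}

ibi_values <- function(ibi) {
  if (inherits(ibi, "hrv_ibi") || (is.data.frame(ibi) && "interval_ms" %in% names(ibi))) {
    as.numeric(ibi$interval_ms)
  } else if (is.numeric(ibi)) {
    as.numeric(ibi)
  } else {
    stop_hrvci("hrvci_error_bad_argument",
               "expected an hrv_ibi tibble (or numeric vector of ms intervals).")
  }
}

#' Convert detected beats to an interbeat-interval series
#'
#' @param beats an `hrv_beats` tibble from [detect_beats()], or a numeric
#'   vector of strictly increasing beat times in seconds.
#' @return An [ibi_series()] with `n_beats - 1` intervals in ms, all flagged
#'   `"normal"`.
#' @export
#' @examples
#' to_ibi(c(0, 0.8, 1.6, 2.5))   # 800, 800, 900 ms
to_ibi <- function(beats) {
  times <- if (is.data.frame(beats) && "time" %in% names(beats)) beats$time else beats
  if (!is.numeric(times) || length(times) < 2L) {
    stop_hrvci("hrvci_error_too_few_beats", "need at least 2 beats to form intervals.")
  }
  if (any(diff(times) <= 0)) {
    stop_hrvci("hrvci_error_nonmonotone_beats", "beat times must be strictly increasing.")
  }
  ibi_series(diff(times) * 1000)
}

#' Flag, correct or remove ectopic intervals
#'
#' Automates the usual visual tachogram screen with a deterministic rule: an
#' interval deviating from the running median of its window by more than
#' `deviation_fraction` is marked ectopic. `action = "flag"` only marks;
#' `"interpolate"` replaces the value with the local running median and flags
#' it `"edited"`; `"delete"` drops the interval. The flagged fraction is
#' recorded in the `ectopic_fraction` attribute.
#'
#' @param ibi an [ibi_series()].
#' @param deviation_fraction relative deviation from the running median above
#'   which an interval is called ectopic (default 0.20).
#' @param window running-median window in beats (odd, default 11).
#' @param action one of `"flag"`, `"interpolate"`, `"delete"`.
#' @return The screened `hrv_ibi`; attribute `ectopic_fraction` gives the
#'   fraction of intervals that triggered the rule.
#' @export
screen_ectopics <- function(ibi, deviation_fraction = 0.20, window = 11L,
                            action = c("flag", "interpolate", "delete")) {
  action <- match.arg(action)
  check_number(deviation_fraction, "deviation_fraction", lower = 1e-9)
  window <- as.integer(window)
  if (window %% 2L == 0L) {
    stop_hrvci("hrvci_error_bad_argument", "`window` must be odd.")
  }
  x <- ibi_values(ibi)
  n <- length(x)
  if (window > n) {
    stop_hrvci("hrvci_error_bad_argument",
               sprintf("window (%d) larger than series (%d).", window, n))
  }
  flags <- if (is.data.frame(ibi) && "flag" %in% names(ibi)) ibi$flag else rep("normal", n)
  med <- as.numeric(stats::runmed(x, k = window, endrule = "median"))
  ect <- abs(x - med) / med > deviation_fraction
  out_flags <- flags
  out_flags[ect & flags != "edited"] <- "ectopic"
  frac <- mean(ect)
  if (action == "flag") {
    out <- ibi_series(x, out_flags)
  } else if (action == "interpolate") {
    x[ect] <- med[ect]
    out_flags[ect] <- "edited"
    out <- ibi_series(x, out_flags)
  } else {
    out <- ibi_series(x[!ect], flags[!ect])
  }
  attr(out, "ectopic_fraction") <- frac
  out
}

#' Extract a fixed-duration analysis segment from a tachogram
#'
#' Returns the maximal run of intervals, starting after `offset` seconds of
#' recording, whose cumulative sum does not exceed `duration` seconds. The
#' start policy is recorded in the `segment` attribute.
#'
#' @param ibi an [ibi_series()].
#' @param duration segment length in seconds (default 600 = 10 min).
#' @param offset seconds of recording to skip before the segment starts.
#' @return An `hrv_ibi` whose cumulative sum lies in
#'   `(duration - max(interval), duration]` seconds.
#' @export
extract_segment <- function(ibi, duration = 600, offset = 0) {
  check_number(duration, "duration", lower = 1e-9)
  check_number(offset, "offset", lower = 0)
  x <- ibi_values(ibi)
  flags <- if (is.data.frame(ibi) && "flag" %in% names(ibi)) ibi$flag else rep("normal", length(x))
  cs <- cumsum(x)
  start <- if (offset > 0) which(cs >= offset * 1000)[1] + 1L else 1L
  if (is.na(start) || start > length(x)) {
    stop_hrvci("hrvci_error_insufficient_duration",
               sprintf("offset %.1f s exceeds the recording (%.1f s available).",
                       offset, sum(x) / 1000))
  }
  avail <- (cs[length(cs)] - if (start > 1L) cs[start - 1L] else 0) / 1000
  if (avail < duration) {
    stop_hrvci("hrvci_error_insufficient_duration",
               sprintf("recording provides %.1f s after offset, %.1f s requested.",
                       avail, duration))
  }
  rel <- cs - if (start > 1L) cs[start - 1L] else 0
  end <- max(which(rel <= duration * 1000 + 1e-9))
  out <- ibi_series(x[start:end], flags[start:end])
  attr(out, "segment") <- list(duration_s = duration, offset_s = offset,
                               start_index = start, end_index = end)
  out
}

#' Read / write tachogram files
#'
#' The plain-text RR convention: one interval in milliseconds per line, with
#' an optional second column of quality flags; a CSV dialect with a header
#' (`interval_ms[,flag]`) is also accepted.
#'
#' @param path file path.
#' @return `read_ibi()` returns an [ibi_series()]; `write_ibi()` returns
#'   `path` invisibly.
#' @export
read_ibi <- function(path) {
  if (!file.exists(path)) {
    stop_hrvci("hrvci_error_io", sprintf("IBI file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_hrvci("hrvci_error_parse", "empty IBI file.")
  fields <- strsplit(trimws(lines), "[,;\t ]+")
  if (anyNA(suppressWarnings(as.numeric(fields[[1]][1])))) fields <- fields[-1]
  vals <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
  if (anyNA(vals)) {
    stop_hrvci("hrvci_error_parse",
               sprintf("non-numeric interval at data row %d.", which(is.na(vals))[1]))
  }
  flags <- vapply(fields, function(f) if (length(f) > 1L) f[2] else "normal", "")
  ibi_series(vals, flags)
}

#' @param ibi an [ibi_series()].
#' @param flags write the flag column as well (default: only when any flag is
#'   not `"normal"`).
#' @rdname read_ibi
#' @export
write_ibi <- function(ibi, path, flags = NULL) {
  x <- ibi_values(ibi)
  fl <- if (is.data.frame(ibi) && "flag" %in% names(ibi)) ibi$flag else rep("normal", length(x))
  flags <- flags %||% any(fl != "normal")
  lines <- if (flags) paste(format(x, trim = TRUE), fl) else format(x, trim = TRUE)
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.hrv_ibi <- function(x, ...) {
  cat(sprintf("<hrv_ibi> %d intervals, %.1f s, mean %.1f ms (%d non-normal)\n",
              nrow(x), sum(x$interval_ms) / 1000, mean(x$interval_ms),
              sum(x$flag != "normal")))
  NextMethod()
}

#' Plot a tachogram
#'
#' @param object an [ibi_series()].
#' @param ... unused.
#' @return A ggplot: interval duration (ms) against beat number, non-normal
#'   beats highlighted.
#' @export
autoplot.hrv_ibi <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object), beat = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beat, y = .data$interval_ms)) +
    ggplot2::geom_line(colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$flag != "normal"),
                        ggplot2::aes(colour = .data$flag), size = 1.4) +
    ggplot2::labs(x = "beat number", y = "interbeat interval (ms)",
                  colour = "flag") +
    ggplot2::theme_minimal()
}
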