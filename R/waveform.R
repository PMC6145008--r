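#' Waveform container
#'
#' A waveform is a tibble with columns `time` (seconds) and `amplitude`
#' (arbitrary units) plus a declared sampling rate and channel label. All
#' signal-level operations (`fft_filter()`, `detect_beats()`) consume and
#' return this shape.
#'
#' @param amplitude numeric vector of samples (arbitrary units).
#' @param sampling_rate sampling frequency in Hz, > 0.
#' @param channel channel label, e.g. `"ecg"` or `"ppg"`.
#' @param start_time time of the first sample in seconds.
#' @return A tibble of class `hrv_waveform` with columns `time`, `amplitude`.
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * 1 * seq(0, 2, by = 1 / 100)), sampling_rate = 100)
#' w
waveform <- function(amplitude, sampling_rate, channel = "ecg", start_time = 0) {
  check_number(sampling_rate, "sampling_rate", lower = 1e-9)
  if (!is.numeric(amplitude) || length(amplitude) < 2L) {
    stop_hrvci("hrvci_error_bad_argument",
               "`amplitude` must be a numeric vector with at least 2 samples.")
  }
  if (anyNA(amplitude)) {
    stop_hrvci("hrvci_error_parse", "waveform amplitudes contain missing values.")
  }
  out <- tibble(
    time = start_time + (seq_along(amplitude) - 1) / sampling_rate,
    amplitude = as.numeric(amplitude)
  )
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "channel") <- channel
  class(out) <- c("hrv_waveform", class(out))
  out
}

#' Sampling rate of a waveform
#' @param w an `hrv_waveform`.
#' @return Sampling rate in Hz.
#' @export
sampling_rate <- function(w) {
  fs <- attr(w, "sampling_rate")
  if (is.null(fs)) {
    stop_hrvci("hrvci_error_bad_argument", "`w` is not an hrv_waveform.")
  }
  fs
}

#' Read a sampled waveform from a delimited text file
#'
#' Accepts either a single-column file of amplitudes (the sampling rate must
#' then be supplied) or a two-column file of (time in seconds, amplitude),
#' from which the sampling rate is inferred from the median time step. Comma
#' or whitespace delimited; an optional non-numeric header line is skipped.
#'
#' @param path file path.
#' @param sampling_rate sampling rate in Hz; required for single-column input,
#'   ignored (with a check against the time column) for two-column input.
#' @param channel channel label recorded on the waveform.
#' @return An [waveform()] tibble.
#' @export
read_waveform <- function(path, sampling_rate = NULL, channel = "ecg") {
  if (!file.exists(path)) {
    stop_hrvci("hrvci_error_io", sprintf("waveform file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop_hrvci("hrvci_error_parse", "waveform file has fewer than 2 samples.")
  }
  split_row <- function(s) strsplit(trimws(s), "[,;\t ]+")[[1]]
  first <- suppressWarnings(as.numeric(split_row(lines[1])))
  header <- anyNA(first)
  if (header) lines <- lines[-1]
  fields <- lapply(lines, split_row)
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1L || !ncol %in% c(1L, 2L)) {
    stop_hrvci("hrvci_error_parse",
               "waveform file must have one (amplitude) or two (time, amplitude) columns.")
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = ncol, byrow = TRUE)
  bad <- which(rowSums(is.na(mat)) > 0)
  if (length(bad)) {
    stop_hrvci("hrvci_error_parse",
               sprintf("non-numeric value in waveform file at data row %d.", bad[1]))
  }
  if (ncol == 1L) {
    if (is.null(sampling_rate)) {
      stop_hrvci("hrvci_error_bad_argument",
                 "single-column waveform input requires `sampling_rate`.")
    }
    waveform(mat[, 1], sampling_rate, channel = channel)
  } else {
    tm <- mat[, 1]
    dt <- diff(tm)
    if (any(dt <= 0)) {
      stop_hrvci("hrvci_error_nonmonotone_time",
                 sprintf("time column is not strictly increasing at row %d.",
                         which(dt <= 0)[1] + 1L))
    }
    fs <- 1 / stats::median(dt)
    waveform(mat[, 2], fs, channel = channel, start_time = tm[1])
  }
}

# frequency-mask filter on a bare numeric vector (zero phase: the DFT bins
# outside the passband are zeroed symmetrically, no detrending is applied)
fft_filter_vec <- function(x, fs, passband) {
  n <- length(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  keep <- f >= passband[1] & f <= passband[2]
  X <- stats::fft(x)
  X[!keep] <- 0 + 0i
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' FFT bandpass filter
#'
#' Filters a waveform by zeroing DFT bins outside the passband and inverting
#' the transform. The operation is zero-phase, linear, and length-preserving;
#' no detrending is applied — any mean/trend removal comes only from the
#' passband itself (a low edge above 0 Hz removes the DC component).
#'
#' @param w an [waveform()] tibble.
#' @param passband numeric `c(low, high)` in Hz with
#'   `0 <= low < high <= sampling_rate / 2`.
#' @return A filtered `hrv_waveform` of identical length.
#' @export
fft_filter <- function(w, passband = c(0.5, 40)) {
  fs <- sampling_rate(w)
  if (!is.numeric(passband) || length(passband) != 2L ||
      passband[1] < 0 || passband[1] >= passband[2] || passband[2] > fs / 2) {
    stop_hrvci("hrvci_error_bad_band",
               sprintf("passband must satisfy 0 <= low < high <= %.6g Hz.", fs / 2))
  }
  if (nrow(w) < 2L) {
    stop_hrvci("hrvci_error_bad_argument", "waveform shorter than 2 samples.")
  }
  out <- w
  out$amplitude <- fft_filter_vec(w$amplitude, fs, passband)
  out
}

#' @export
print.hrv_waveform <- function(x, ...) {
  cat(sprintf("<hrv_waveform> %s channel, %d samples @ %.6g Hz (%.2f s)\n",
              attr(x, "channel"), nrow(x), attr(x, "sampling_rate"),
              nrow(x) / attr(x, "sampling_rate")))
  NextMethod()
}
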