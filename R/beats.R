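#' Detect heartbeats in an ECG or PPG waveform
#'
#' Derivative-energy peak detector in the Pan-Tompkins style: the signal is
#' band-limited (zero-phase FFT mask), differentiated, squared, and smoothed
#' with a centred moving-average window; candidate beats are runs of the
#' energy envelope above an adaptive threshold, refined to the local extremum
#' of the band-passed signal, with a refractory period preventing
#' double-detection. Because every stage is zero-phase, a symmetric QRS peak
#' is recovered at its true sample.
#'
#' A flatline (zero-variance) input yields an empty beat table with an
#' explicit warning rather than silent success.
#'
#' @param w an [waveform()].
#' @param method `"ecg_qrs"` (default band 5-25 Hz, 150 ms energy window) or
#'   `"ppg_pulse"` (band 0.5-8 Hz, 300 ms window).
#' @param band optional `c(low, high)` Hz override for the detection band.
#' @param refractory minimum separation between beats in seconds (default
#'   0.25).
#' @param threshold fraction of the upper energy envelope used as the
#'   detection threshold (default 0.25).
#' @return A tibble of class `hrv_beats` with columns `beat`, `time` (s);
#'   attributes `detector` and `source_channel`.
#' @export
detect_beats <- function(w, method = c("ecg_qrs", "ppg_pulse"), band = NULL,
                         refractory = 0.25, threshold = 0.25) {
  method <- match.arg(method)
  fs <- sampling_rate(w)
  x <- w$amplitude
  n <- length(x)
  if (n / fs < 0.5) {
    stop_hrvci("hrvci_error_bad_argument",
               "waveform shorter than one plausible cardiac cycle.")
  }
  empty <- function() {
    out <- tibble(beat = integer(), time = numeric())
    attr(out, "detector") <- method
    attr(out, "source_channel") <- attr(w, "channel")
    class(out) <- c("hrv_beats", class(out))
    out
  }
  if (stats::sd(x) < 1e-12) {
    warn_hrvci("hrvci_warning_flatline",
               "flat (zero-variance) signal: no beats detected.")
    return(empty())
  }
  band <- band %||% if (method == "ecg_qrs") c(5, 25) else c(0.5, 8)
  band[2] <- min(band[2], fs / 2 * 0.99)
  xf <- fft_filter_vec(x, fs, band)
  energy <- (c(0, diff(xf)) * fs)^2
  win <- if (method == "ecg_qrs") 0.15 else 0.30
  k <- max(3L, as.integer(round(win * fs)))
  if (k %% 2L == 0L) k <- k + 1L
  env <- as.numeric(stats::filter(energy, rep(1 / k, k), sides = 2))
  env[is.na(env)] <- 0
  thr <- threshold * as.numeric(stats::quantile(env, 0.995))
  above <- env > thr
  if (!any(above)) {
    warn_hrvci("hrvci_warning_no_beats", "no region exceeded the detection threshold.")
    return(empty())
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- mapply(function(s, e) s - 1L + which.max(env[s:e]),
                 starts[r$values], ends[r$values])
  # refine to the peak of the band-passed signal near each energy maximum
  if (method == "ecg_qrs") {
    lo_off <- as.integer(round(0.10 * fs)); hi_off <- lo_off
  } else {
    lo_off <- as.integer(round(0.05 * fs)); hi_off <- as.integer(round(0.30 * fs))
  }
  peaks <- vapply(cand, function(i) {
    a <- max(1L, i - lo_off); b <- min(n, i + hi_off)
    a - 1L + which.max(xf[a:b])
  }, integer(1))
  peaks <- sort(unique(peaks))
  # refractory pass: among peaks closer than `refractory`, keep the larger one
  keep <- integer(0)
  for (p in peaks) {
    if (length(keep) && (p - keep[length(keep)]) / fs < refractory) {
      if (xf[p] > xf[keep[length(keep)]]) keep[length(keep)] <- p
    } else {
      keep <- c(keep, p)
    }
  }
  # re-localise each peak on the unfiltered input (the detection band tilts
  # the apex slightly with the local baseline), then refine to sub-sample
  # precision by parabolic interpolation through the apex and its neighbours
  # — intervals are used at millisecond precision downstream, finer than one
  # sample at typical rates
  w2 <- as.integer(round(0.02 * fs))
  keep <- vapply(keep, function(p) {
    a <- max(1L, p - w2); b <- min(n, p + w2)
    a - 1L + which.max(x[a:b])
  }, integer(1))
  keep <- unique(keep)
  delta <- vapply(keep, function(p) {
    if (p <= 1L || p >= n) return(0)
    y0 <- x[p - 1L]; y1 <- x[p]; y2 <- x[p + 1L]
    den <- y0 - 2 * y1 + y2
    if (abs(den) < 1e-12) return(0)
    max(min(0.5 * (y0 - y2) / den, 0.5), -0.5)
  }, numeric(1))
  out <- tibble(beat = seq_along(keep), time = w$time[keep] + delta / fs)
  attr(out, "detector") <- method
  attr(out, "source_channel") <- attr(w, "channel")
  class(out) <- c("hrv_beats", class(out))
  out
}
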