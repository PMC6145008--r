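#' 1/f (pink) noise by spectral shaping
#'
#' White Gaussian noise is transformed to the frequency domain, its amplitude
#' spectrum scaled by `f^(-alpha/2)` (symmetrically, DC removed), and
#' transformed back; the result is standardised to zero mean and unit sample
#' SD. `alpha = 1` gives classic 1/f noise, `alpha = 0` white noise.
#' Deterministic given the RNG state.
#'
#' @param n series length (>= 2).
#' @param alpha spectral exponent (power ~ 1/f^alpha), default 1.
#' @return Numeric vector of length `n`, unit SD.
#' @export
pink_noise <- function(n, alpha = 1) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop_hrvci("hrvci_error_bad_argument", "`n` must be >= 2.")
  m <- composite_length(n)
  w <- stats::rnorm(m)
  k <- 0:(m - 1)
  f <- pmin(k, m - k) / m
  sc <- ifelse(f > 0, f^(-alpha / 2), 0)
  x <- Re(stats::fft(stats::fft(w) * sc, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  (x - mean(x)) / stats::sd(x)
}

#' Synthetic interbeat-interval generating profile
#'
#' Describes a stationary interbeat mixture: a mean level, a Mayer-wave (LF,
#' ~0.1 Hz) and a respiratory (HF, ~0.25 Hz) oscillation, and a coloured-noise
#' residual split between 1/f and white components. `regularity` sets the
#' fraction of the target variance carried by the deterministic oscillations
#' (0 = pure broadband noise, 1 = pure oscillation); `lf_amp`/`hf_amp` set
#' the relative LF/HF split, and `pink_weight`/`white_weight` the relative
#' split of the residual noise variance. At the default `regularity = 0.125`
#' the realized oscillation amplitudes equal `lf_amp * sd_target` and
#' `hf_amp * sd_target` exactly.
#'
#' This is a test fixture spanning the regimes of interest — from
#' oscillation-dominated, low-complexity series (the augmented periodicity of
#' unresponsive patients) to 1/f-dominated, high-complexity series — not a
#' physiological model.
#'
#' @param mean_ibi mean interbeat interval in ms (default 800).
#' @param sd_target target series SD in ms (default 40).
#' @param lf_amp,lf_freq LF oscillation: amplitude as a fraction of
#'   `sd_target` (default 0.4) and frequency in Hz (default 0.1).
#' @param hf_amp,hf_freq HF oscillation: amplitude fraction (default 0.3) and
#'   frequency in Hz (default 0.25).
#' @param pink_weight,white_weight relative weights of 1/f and white residual
#'   variance (non-negative, sum > 0 and <= 1; normalised internally).
#' @param regularity fraction of variance in the oscillations, in \[0, 1\].
#' @param seed optional integer seed stored with the profile.
#' @return A list of class `hrv_profile`.
#' @export
synthetic_profile <- function(mean_ibi = 800, sd_target = 40,
                              lf_amp = 0.4, lf_freq = 0.1,
                              hf_amp = 0.3, hf_freq = 0.25,
                              pink_weight = 0.5, white_weight = 0.5,
                              regularity = 0.125, seed = NULL) {
  check_number(mean_ibi, "mean_ibi", lower = 1e-9)
  check_number(sd_target, "sd_target", lower = 0)
  check_number(regularity, "regularity", lower = 0, upper = 1)
  if (pink_weight < 0 || white_weight < 0 || pink_weight + white_weight <= 0 ||
      pink_weight + white_weight > 1 + 1e-9) {
    stop_hrvci("hrvci_error_bad_argument",
               "noise weights must be >= 0 with 0 < pink_weight + white_weight <= 1.")
  }
  if (sd_target == 0 && regularity < 1) {
    stop_hrvci("hrvci_error_degenerate_profile",
               "sd_target = 0 with regularity < 1 is degenerate.")
  }
  structure(
    list(mean_ibi = mean_ibi, sd_target = sd_target,
         lf_amp = lf_amp, lf_freq = lf_freq, hf_amp = hf_amp, hf_freq = hf_freq,
         pink_weight = pink_weight, white_weight = white_weight,
         regularity = regularity, seed = seed),
    class = "hrv_profile"
  )
}

# latent complexity c in [0, 1] -> generating profile; c = 0 is the
# oscillation-dominated (low-complexity) end, c = 1 the 1/f-dominated end.
profile_from_complexity <- function(c, mean_ibi = 800, sd_target = 40, seed = NULL) {
  c <- min(max(c, 0), 1)
  synthetic_profile(
    mean_ibi = mean_ibi, sd_target = sd_target,
    regularity = 0.75 - 0.65 * c,
    pink_weight = 0.2 + 0.6 * c,
    white_weight = 1 - (0.2 + 0.6 * c),
    seed = seed
  )
}

#' Preset group profiles
#'
#' `mcs_profile()` is the high-complexity end of the generator (1/f-dominant,
#' weak oscillation); `uws_profile()` the low-complexity, oscillation-dominant
#' end.
#'
#' @param seed optional seed stored on the profile.
#' @return An [synthetic_profile()].
#' @export
mcs_profile <- function(seed = NULL) profile_from_complexity(1, seed = seed)

#' @rdname mcs_profile
#' @export
uws_profile <- function(seed = NULL) profile_from_complexity(0, seed = seed)

#' Generate a synthetic interbeat-interval series
#'
#' Samples the profile's oscillation + coloured-noise mixture at nominal beat
#' times, clips intervals to the physiological band \[300, 2000\] ms (clip
#' count recorded in the `n_clipped` attribute), and returns the shortest
#' prefix whose cumulative duration reaches `duration` seconds. Reproducible
#' given `seed`.
#'
#' @param profile an [synthetic_profile()].
#' @param duration target cumulative duration in seconds (default 600).
#' @param seed integer seed; defaults to the profile's stored seed.
#' @return An [ibi_series()]; attributes `n_clipped` and `profile`.
#' @export
generate_ibi <- function(profile, duration = 600, seed = profile$seed) {
  stopifnot(inherits(profile, "hrv_profile"))
  check_number(duration, "duration", lower = 1e-9)
  p <- profile
  n0 <- as.integer(ceiling(duration * 1000 / p$mean_ibi * 1.25)) + 16L
  x <- with_seed_if(seed, {
    t <- (seq_len(n0) - 1) * p$mean_ibi / 1000   # nominal beat times
    osc_var <- p$regularity * p$sd_target^2
    w_lf <- p$lf_amp^2 / (p$lf_amp^2 + p$hf_amp^2)
    a_lf <- sqrt(2 * osc_var * w_lf)
    a_hf <- sqrt(2 * osc_var * (1 - w_lf))
    ph <- stats::runif(2, 0, 2 * pi)
    noise_var <- (1 - p$regularity) * p$sd_target^2
    wsum <- p$pink_weight + p$white_weight
    s_pink <- sqrt(noise_var * p$pink_weight / wsum)
    s_white <- sqrt(noise_var * p$white_weight / wsum)
    noise <- numeric(n0)
    if (s_pink > 0) noise <- noise + s_pink * pink_noise(n0, alpha = 1)
    if (s_white > 0) noise <- noise + s_white * stats::rnorm(n0)
    p$mean_ibi +
      a_lf * sin(2 * pi * p$lf_freq * t + ph[1]) +
      a_hf * sin(2 * pi * p$hf_freq * t + ph[2]) +
      noise
  })
  clipped <- x < 300 | x > 2000
  x <- pmin(pmax(x, 300), 2000)
  cs <- cumsum(x)
  k <- which(cs >= duration * 1000)[1]
  if (is.na(k)) {
    stop_hrvci("hrvci_error_insufficient_duration",
               "generated series shorter than the requested duration.")
  }
  out <- ibi_series(x[seq_len(k)])
  attr(out, "n_clipped") <- sum(clipped[seq_len(k)])
  attr(out, "profile") <- p
  out
}

#' Synthetic cohort specification
#'
#' Group sizes default to the reference cohort (16 MCS, 14 UWS). Each subject
#' draws a latent complexity `c` around the group mean (`0.5 +/- gap / 2`,
#' MCS high) with SD `subject_sd`, clamped to \[0, 1\]; `c` drives both the
#' interbeat generating profile and the behavioural score. CRS-R totals are
#' `round(3 + 13 c + N(0, crs_r_noise))` clamped to the observed range
#' \[3, 16\]. The defaults `complexity_gap = 0.6`, `subject_sd = 0.12` and
#' `crs_r_noise = 3.0` were fixed by a one-off calibration of the Spearman
#' regime (rho between CRS-R and the long-scale index in \[0.5, 0.8\]).
#'
#' @param n_mcs,n_uws group sizes (defaults 16 and 14).
#' @param complexity_gap difference between the group means of the latent
#'   complexity, in \[0, 1\]; 0 makes the groups exchangeable.
#' @param subject_sd SD of the per-subject latent complexity around its group
#'   mean.
#' @param crs_r_noise SD of the Gaussian noise on the CRS-R map.
#' @param duration recording duration per subject in seconds.
#' @param mean_ibi,sd_target interbeat mean and SD (ms) shared by all
#'   subjects.
#' @param seed integer seed for the whole cohort draw.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mcs = 16L, n_uws = 14L, complexity_gap = 0.6,
                        subject_sd = 0.12, crs_r_noise = 3.0, duration = 600,
                        mean_ibi = 800, sd_target = 40, seed = NULL) {
  n_mcs <- as.integer(n_mcs); n_uws <- as.integer(n_uws)
  if (is.na(n_mcs) || is.na(n_uws) || n_mcs < 1L || n_uws < 1L) {
    stop_hrvci("hrvci_error_bad_argument", "group sizes must be >= 1.")
  }
  check_number(complexity_gap, "complexity_gap", lower = 0, upper = 1)
  check_number(subject_sd, "subject_sd", lower = 0)
  check_number(crs_r_noise, "crs_r_noise", lower = 0)
  structure(
    list(n_mcs = n_mcs, n_uws = n_uws, complexity_gap = complexity_gap,
         subject_sd = subject_sd, crs_r_noise = crs_r_noise,
         duration = duration, mean_ibi = mean_ibi, sd_target = sd_target,
         seed = seed),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort through the full entropy pipeline
#'
#' Draws one tachogram per subject from the group-specific profile, computes
#' the multiscale entropy curve and complexity indices through the real
#' pipeline (never a shortcut on the latent value), and attaches CRS-R-like
#' totals. MCS-like subjects come from the higher-complexity (1/f-dominant)
#' end, UWS-like from the oscillation-dominant end.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; defaults to the spec's stored seed.
#' @param keep_ibi keep the per-subject tachograms as a list column
#'   (default TRUE).
#' @param max_scale largest entropy scale (default 10).
#' @return A tibble with one row per subject: `subject_id`, `diagnosis`,
#'   `latent_complexity`, `crs_r_total`, `ci_s`, `ci_l`, `ci_total`,
#'   `sd_ref`, and (optionally) `ibi` list column.
#' @export
generate_cohort <- function(spec, seed = spec$seed, keep_ibi = TRUE,
                            max_scale = 10L) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_mcs + spec$n_uws
  diagnosis <- c(rep("MCS", spec$n_mcs), rep("UWS", spec$n_uws))
  with_seed_if(seed, {
    c_group <- ifelse(diagnosis == "MCS",
                      0.5 + spec$complexity_gap / 2,
                      0.5 - spec$complexity_gap / 2)
    c_subj <- pmin(pmax(c_group + stats::rnorm(n, 0, spec$subject_sd), 0), 1)
    crs_r <- pmin(pmax(round(3 + 13 * c_subj +
                               stats::rnorm(n, 0, spec$crs_r_noise)), 3), 16)
    ci_s <- ci_l <- ci_tot <- sd_ref <- numeric(n)
    ibis <- vector("list", n)
    for (i in seq_len(n)) {
      prof <- profile_from_complexity(c_subj[i], mean_ibi = spec$mean_ibi,
                                      sd_target = spec$sd_target)
      # a draw whose entropy is undefined at some scale (zero template
      # matches, possible for short, strongly periodic series) fails quality
      # control and is redrawn, like a recording rejected for artifacts
      for (attempt in 1:8) {
        ibi <- generate_ibi(prof, duration = spec$duration, seed = NULL)
        curve <- withCallingHandlers(
          mse_curve(ibi, max_scale = max_scale),
          hrvci_warning_undefined_scales = function(w) {
            invokeRestart("muffleWarning")
          }
        )
        if (all(curve$defined)) break
      }
      if (!all(curve$defined)) {
        stop_hrvci("hrvci_error_degenerate_profile",
                   sprintf("subject %d: entropy undefined after 8 redraws.", i))
      }
      ci_s[i] <- complexity_index(curve, c(1, 5))
      ci_l[i] <- complexity_index(curve, c(6, 10))
      ci_tot[i] <- ci_s[i] + ci_l[i]
      sd_ref[i] <- attr(curve, "sd_ref")
      if (keep_ibi) ibis[[i]] <- ibi
    }
    out <- tibble(
      subject_id = sprintf("S%02d", seq_len(n)),
      diagnosis = diagnosis,
      latent_complexity = c_subj,
      crs_r_total = as.integer(crs_r),
      ci_s = ci_s, ci_l = ci_l, ci_total = ci_tot, sd_ref = sd_ref
    )
    if (keep_ibi) out$ibi <- ibis
    out
  })
}

#' Feature-level cohort with a planted decision boundary
#'
#' Synthesizes the classifier's input table directly (no tachograms): the
#' long-scale index separates the groups with zero overlap around
#' `threshold` (margin `margin`, UWS below, MCS above) while the short-scale
#' index is drawn from a common overlapping distribution. Used for
#' parameter-recovery checks of the rule induction.
#'
#' @param n_mcs,n_uws group sizes.
#' @param threshold planted `ci_l` decision boundary.
#' @param margin width of the empty interval around the threshold.
#' @param spread extent of each group's uniform `ci_l` band beyond the
#'   margin.
#' @param seed integer seed.
#' @return A tibble: `subject_id`, `diagnosis`, `ci_s`, `ci_l`.
#' @export
planted_cohort <- function(n_mcs = 16L, n_uws = 14L, threshold = 4.876,
                           margin = 0.8, spread = 1.5, seed = NULL) {
  with_seed_if(seed, {
    ci_l <- c(stats::runif(n_mcs, threshold + margin / 2, threshold + margin / 2 + spread),
              stats::runif(n_uws, threshold - margin / 2 - spread, threshold - margin / 2))
    tibble(
      subject_id = sprintf("S%02d", seq_len(n_mcs + n_uws)),
      diagnosis = c(rep("MCS", n_mcs), rep("UWS", n_uws)),
      ci_s = stats::rnorm(n_mcs + n_uws, 4, 1),
      ci_l = ci_l
    )
  })
}

# stylised continuous-time PQRST template; the R apex is exactly at t = 0,
# evaluated at arbitrary (sub-sample) offsets so beat times are not quantised
# to the sampling grid
ecg_template_fun <- function(t, include_pt = TRUE) {
  g <- function(mu, sd, amp) amp * exp(-(t - mu)^2 / (2 * sd^2))
  y <- g(0, 0.012, 1) + g(-0.035, 0.015, -0.12) + g(0.035, 0.018, -0.18)
  if (include_pt) y <- y + g(-0.19, 0.03, 0.12) + g(0.29, 0.06, 0.25)
  y
}

# smooth gamma-like pulse wave peaking at `delay` seconds after the beat
ppg_template_fun <- function(t, delay) {
  y <- numeric(length(t))
  pos <- t > 0
  y[pos] <- (t[pos] / delay)^4 * exp(4 * (1 - t[pos] / delay))
  y
}

#' Render a tachogram as a synthetic waveform
#'
#' `synthesize_ecg()` places a stylised PQRST template (R peak centred on the
#' beat) at each cumulative beat time; `synthesize_ppg()` renders the same
#' beats as a smooth pulse wave peaking at a fixed systolic delay after the
#' beat. Optional additive Gaussian noise at a given signal-to-noise ratio.
#' On noiseless output, [detect_beats()] recovers the beat times to within
#' one sample.
#'
#' @param ibi an [ibi_series()].
#' @param sampling_rate output rate in Hz (>= 100).
#' @param snr signal-to-noise (variance) ratio; `Inf` (default) for
#'   noiseless output.
#' @param include_pt include P and T waves (ECG only, default TRUE).
#' @param seed seed for the noise draw.
#' @return An [waveform()]; attribute `beat_times` holds the true beat times
#'   in seconds.
#' @export
synthesize_ecg <- function(ibi, sampling_rate = 500, snr = Inf,
                           include_pt = TRUE, seed = NULL) {
  synth_waveform(ibi, sampling_rate, snr, seed, channel = "ecg",
                 include_pt = include_pt)
}

#' @param delay systolic peak delay after the beat in seconds (PPG, default
#'   0.15).
#' @rdname synthesize_ecg
#' @export
synthesize_ppg <- function(ibi, sampling_rate = 500, snr = Inf, delay = 0.15,
                           seed = NULL) {
  synth_waveform(ibi, sampling_rate, snr, seed, channel = "ppg", delay = delay)
}

synth_waveform <- function(ibi, sampling_rate, snr, seed, channel,
                           include_pt = TRUE, delay = 0.15) {
  check_number(sampling_rate, "sampling_rate", lower = 100)
  x <- ibi_values(ibi)
  beat_t <- c(0, cumsum(x)) / 1000
  pad <- 1.0
  n <- composite_length(as.integer(ceiling((beat_t[length(beat_t)] + 2 * pad) *
                                             sampling_rate)))
  y <- numeric(n)
  support <- if (channel == "ecg") c(-0.35, 0.45) else c(0, 0.7)
  for (bt in beat_t) {
    i0 <- max(1L, as.integer(floor((bt + pad + support[1]) * sampling_rate)) + 1L)
    i1 <- min(n, as.integer(ceiling((bt + pad + support[2]) * sampling_rate)) + 1L)
    if (i1 < i0) next
    idx <- i0:i1
    t_rel <- (idx - 1) / sampling_rate - pad - bt
    y[idx] <- y[idx] + if (channel == "ecg") {
      ecg_template_fun(t_rel, include_pt = include_pt)
    } else {
      ppg_template_fun(t_rel, delay)
    }
  }
  if (is.finite(snr)) {
    check_number(snr, "snr", lower = 1e-12)
    sig_var <- stats::var(y)
    y <- y + with_seed_if(seed, stats::rnorm(n, 0, sqrt(sig_var / snr)))
  }
  out <- waveform(y, sampling_rate, channel = channel, start_time = -pad)
  attr(out, "beat_times") <- beat_t
  out
}
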