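#' Coarse-grain a series
#'
#' Replaces the series by the means of consecutive non-overlapping windows of
#' length `tau`; a trailing incomplete window is dropped, so the output length
#' is `floor(N / tau)`. Scale 1 returns the original series.
#'
#' @param x numeric vector (interbeat intervals in ms, or any series).
#' @param tau integer scale factor >= 1.
#' @return Numeric vector of window means, length `floor(length(x) / tau)`.
#' @export
#' @examples
#' coarse_grain(c(2, 4, 6, 8), 2)            # 3, 7
#' coarse_grain(c(3, 6, 9, 12, 15, 18, 21), 3) # 6, 15 (7th point dropped)
coarse_grain <- function(x, tau) {
  x <- ibi_values(x)
  tau <- as.integer(tau)
  if (is.na(tau) || tau < 1L) {
    stop_hrvci("hrvci_error_bad_argument", "`tau` must be an integer >= 1.")
  }
  n <- length(x)
  if (n < tau) {
    stop_hrvci("hrvci_error_bad_argument",
               sprintf("series (length %d) shorter than tau (%d).", n, tau))
  }
  if (tau == 1L) return(x)
  m <- n %/% tau
  colMeans(matrix(x[seq_len(m * tau)], nrow = tau))
}

#' Sample entropy of a series
#'
#' SampEn(m, r, N) = -ln(A / B), where B counts pairs of length-`m` templates
#' and A pairs of length-`m + 1` templates lying within the absolute Chebyshev
#' tolerance `tolerance_abs`. Matching is over all distinct template pairs
#' (self-matches excluded); both counts are taken over the first `N - m`
#' template starts so their normalisations cancel in the ratio. When either
#' count is zero the entropy is undefined and returned as `NA` with
#' `defined = FALSE` — never a silent infinity.
#'
#' @param x numeric vector, length > `m + 1`.
#' @param m template (embedding) length, default 2.
#' @param tolerance_abs absolute match tolerance (same units as `x`), > 0.
#' @return A one-row tibble: `se`, `defined`, `a_count`, `b_count`, `phi_m`,
#'   `phi_m1`, `tolerance_abs`, `n`, `n_templates`.
#' @export
#' @examples
#' sample_entropy(rep(800, 100), m = 2, tolerance_abs = 10)$se  # 0
sample_entropy <- function(x, m = 2L, tolerance_abs) {
  x <- ibi_values(x)
  m <- as.integer(m)
  if (is.na(m) || m < 1L) {
    stop_hrvci("hrvci_error_bad_argument", "`m` must be an integer >= 1.")
  }
  check_number(tolerance_abs, "tolerance_abs", lower = .Machine$double.xmin)
  if (length(x) <= m + 1L) {
    stop_hrvci("hrvci_error_too_short",
               sprintf("series length %d too short for m = %d.", length(x), m))
  }
  cnt <- sampen_counts_cpp(x, m, tolerance_abs)
  nt <- cnt$n_templates
  denom <- nt * (nt - 1)                       # ordered template pairs
  phi_m <- if (denom > 0) 2 * cnt$b / denom else NA_real_
  phi_m1 <- if (denom > 0) 2 * cnt$a / denom else NA_real_
  defined <- cnt$a > 0 && cnt$b > 0
  tibble(
    se = if (defined) -log(cnt$a / cnt$b) else NA_real_,
    defined = defined,
    a_count = cnt$a, b_count = cnt$b,
    phi_m = phi_m, phi_m1 = phi_m1,
    tolerance_abs = tolerance_abs,
    n = length(x), n_templates = nt
  )
}

#' Multiscale sample entropy curve
#'
#' Computes SampEn on coarse-grained versions of the tachogram for scales
#' `1..max_scale` with `m = 2`, `r = 0.15` by default. Under the default
#' `"fixed_scale1_sd"` convention the absolute tolerance is `r` times the
#' standard deviation of the original (scale-1) segment, held fixed across
#' scales; `"per_scale_sd"` recomputes the tolerance from each coarse-grained
#' series. Scales whose coarse series is too short or yields zero template
#' matches are flagged undefined (with a warning), never dropped silently.
#' A constant segment has zero reference SD; its exact self-similarity is
#' counted at machine tolerance, giving an entropy of 0 rather than an
#' undefined scale.
#'
#' @param ibi an [ibi_series()] (or numeric vector of ms intervals). Intervals
#'   still flagged `"ectopic"` trigger a warning: screen or correct first.
#' @param m template length (default 2).
#' @param r tolerance as a fraction of the reference SD (default 0.15).
#' @param max_scale largest scale factor (default 10).
#' @param r_convention `"fixed_scale1_sd"` (default) or `"per_scale_sd"`.
#' @return A tibble of class `mse_curve` with one row per scale: `scale`,
#'   `se`, `defined`, `n_points`, `tolerance_abs`, `a_count`, `b_count`.
#'   Attributes: `m`, `r`, `r_convention`, `sd_ref` (ms).
#' @export
mse_curve <- function(ibi, m = 2L, r = 0.15, max_scale = 10L,
                      r_convention = c("fixed_scale1_sd", "per_scale_sd")) {
  r_convention <- match.arg(r_convention)
  check_number(r, "r", lower = 1e-9, upper = 1 - 1e-9)
  max_scale <- as.integer(max_scale)
  if (is.na(max_scale) || max_scale < 1L) {
    stop_hrvci("hrvci_error_bad_argument", "`max_scale` must be an integer >= 1.")
  }
  x <- ibi_values(ibi)
  if (!length(x)) stop_hrvci("hrvci_error_bad_argument", "empty series.")
  if (is.data.frame(ibi) && "flag" %in% names(ibi) && any(ibi$flag == "ectopic")) {
    warn_hrvci("hrvci_warning_unscreened",
               "series contains intervals flagged ectopic; screen or correct before entropy analysis.")
  }
  sd_ref <- stats::sd(x)
  if (length(x) <= (m + 1L)) {
    stop_hrvci("hrvci_error_too_short", "series too short even for scale 1.")
  }
  se <- tol_v <- a_v <- b_v <- rep(NA_real_, max_scale)
  defined <- logical(max_scale)
  npts <- integer(max_scale)
  for (tau in seq_len(max_scale)) {
    y <- if (length(x) >= tau) coarse_grain(x, tau) else numeric(0)
    tol <- switch(r_convention,
                  fixed_scale1_sd = r * sd_ref,
                  per_scale_sd = r * stats::sd(y))
    npts[tau] <- length(y)
    if ((!is.finite(tol) || tol <= 0) && length(y) && stats::sd(y) == 0) {
      # constant segment: zero reference SD; count exact matches at machine
      # tolerance so the entropy is 0 rather than undefined
      tol <- .Machine$double.eps
    }
    tol_v[tau] <- tol
    if (length(y) <= m + 1L || !is.finite(tol) || tol <= 0) next
    cnt <- sampen_counts_cpp(y, m, tol)
    a_v[tau] <- cnt$a; b_v[tau] <- cnt$b
    if (cnt$a > 0 && cnt$b > 0) {
      se[tau] <- -log(cnt$a / cnt$b)
      defined[tau] <- TRUE
    }
  }
  out <- tibble(scale = seq_len(max_scale), se = se, defined = defined,
                n_points = npts, tolerance_abs = tol_v,
                a_count = a_v, b_count = b_v)
  if (any(!out$defined)) {
    warn_hrvci("hrvci_warning_undefined_scales",
               sprintf("sample entropy undefined at scale(s) %s.",
                       paste(out$scale[!out$defined], collapse = ", ")))
  }
  attr(out, "m") <- m
  attr(out, "r") <- r
  attr(out, "r_convention") <- r_convention
  attr(out, "sd_ref") <- sd_ref
  class(out) <- c("mse_curve", class(out))
  out
}

#' Complexity index over a scale range
#'
#' Sum of the sample entropies over an inclusive scale range. In strict mode
#' (default) an undefined scale inside the range is an error naming the scale;
#' with `strict = FALSE` a flagged partial sum over the defined scales is
#' returned with a warning — never a silent partial sum.
#'
#' @param curve an [mse_curve()].
#' @param scales inclusive range `c(lo, hi)`; `c(1, 5)` gives the short-scale
#'   index, `c(6, 10)` the long-scale index.
#' @param strict error on undefined scales inside the range (default TRUE).
#' @return A single number, the sum of SE over the range (attribute `partial`
#'   marks a non-strict partial sum).
#' @export
complexity_index <- function(curve, scales = c(1, 5), strict = TRUE) {
  if (!is.data.frame(curve) || !all(c("scale", "se", "defined") %in% names(curve))) {
    stop_hrvci("hrvci_error_bad_argument", "`curve` must be an mse_curve.")
  }
  lo <- as.integer(scales[1]); hi <- as.integer(scales[2])
  if (is.na(lo) || is.na(hi) || lo < 1L || hi < lo) {
    stop_hrvci("hrvci_error_bad_argument", "`scales` must be an increasing integer range.")
  }
  if (hi > max(curve$scale)) {
    stop_hrvci("hrvci_error_bad_argument",
               sprintf("scale range [%d, %d] outside the curve (max scale %d).",
                       lo, hi, max(curve$scale)))
  }
  sel <- curve[curve$scale >= lo & curve$scale <= hi, ]
  if (any(!sel$defined)) {
    bad <- sel$scale[!sel$defined]
    if (strict) {
      stop_hrvci("hrvci_error_undefined_scale",
                 sprintf("sample entropy undefined at scale(s) %s inside [%d, %d].",
                         paste(bad, collapse = ", "), lo, hi))
    }
    warn_hrvci("hrvci_warning_partial_ci",
               sprintf("partial complexity index: scale(s) %s undefined.",
                       paste(bad, collapse = ", ")))
    out <- sum(sel$se[sel$defined])
    attr(out, "partial") <- TRUE
    return(out)
  }
  sum(sel$se)
}

#' Short- and long-scale complexity indices
#'
#' Convenience wrapper returning the two standard aggregates of the MSE curve:
#' `ci_s` (scales 1-5) and `ci_l` (scales 6-10), plus `ci_total` over all
#' scales of the curve.
#'
#' @inheritParams complexity_index
#' @return A one-row tibble: `ci_s`, `ci_l`, `ci_total`, `sd_ref`.
#' @export
complexity_indices <- function(curve, strict = TRUE) {
  tibble(
    ci_s = complexity_index(curve, c(1, 5), strict = strict),
    ci_l = complexity_index(curve, c(6, 10), strict = strict),
    ci_total = complexity_index(curve, c(1, max(curve$scale)), strict = strict),
    sd_ref = attr(curve, "sd_ref") %||% NA_real_
  )
}

#' Diagnose from a long-scale complexity index threshold
#'
#' Single-threshold rule on `ci_l`: values below the threshold are labelled
#' `"UWS"`, values at or above it `"MCS"` (the boundary belongs to the upper
#' bin). The default threshold 4.876 is the One-R boundary reported for the
#' reference cohort.
#'
#' @param ci_l numeric vector of long-scale complexity indices.
#' @param threshold decision boundary (default 4.876).
#' @return Character vector of `"UWS"` / `"MCS"` labels.
#' @export
#' @examples
#' classify_by_threshold(c(3.1, 4.876, 5.2))  # UWS MCS MCS
classify_by_threshold <- function(ci_l, threshold = 4.876) {
  check_number(threshold, "threshold")
  if (!is.numeric(ci_l) || !length(ci_l) || anyNA(ci_l) || any(!is.finite(ci_l))) {
    stop_hrvci("hrvci_error_bad_argument", "`ci_l` must be finite and non-missing.")
  }
  ifelse(ci_l < threshold, "UWS", "MCS")
}

#' @export
print.mse_curve <- function(x, ...) {
  cat(sprintf("<mse_curve> m = %d, r = %.3g (%s), sd_ref = %.2f ms\n",
              attr(x, "m"), attr(x, "r"), attr(x, "r_convention"),
              attr(x, "sd_ref")))
  NextMethod()
}

#' Plot a multiscale entropy curve
#'
#' @param object an [mse_curve()].
#' @param ... unused.
#' @return A ggplot of SE against scale; undefined scales are omitted.
#' @export
autoplot.mse_curve <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$defined)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scale, y = .data$se)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$scale) +
    ggplot2::labs(x = expression(scale ~ tau), y = "sample entropy") +
    ggplot2::theme_minimal()
}
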