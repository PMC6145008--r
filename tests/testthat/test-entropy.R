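test_that("coarse_grain averages non-overlapping windows and drops remainders", {
  expect_equal(coarse_grain(c(2, 4, 6, 8), 2), c(3, 7))
  expect_equal(coarse_grain(c(3, 6, 9, 12, 15, 18, 21), 3), c(6, 15))
  x <- rnorm(57)
  expect_identical(coarse_grain(x, 1), x)
  expect_length(coarse_grain(x, 4), 14)
  expect_error(coarse_grain(x, 0), class = "hrvci_error_bad_argument")
  expect_error(coarse_grain(rnorm(3), 4), class = "hrvci_error_bad_argument")
})

test_that("sample entropy is zero for perfectly self-similar series", {
  expect_equal(sample_entropy(rep(800, 100), 2, 10)$se, 0)
  alt <- rep(c(800, 850), 100)
  s <- sample_entropy(alt, 2, 10)
  expect_equal(s$se, 0)
  # brute-force confirmation that every length-2 match extends identically
  o <- sampen_oracle(alt, 2, 10)
  expect_equal(o$a, o$b)
})

test_that("sample entropy matches the quadratic template-counting oracle exactly", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    x <- rand_ibi_like(n)
    tol <- runif(1, 5, 30)
    s <- sample_entropy(x, 2, tol)
    o <- sampen_oracle(x, 2, tol)
    expect_identical(c(s$a_count, s$b_count), as.numeric(c(o$a, o$b)))
    if (s$defined) expect_equal(s$se, o$se)
  }
  # and for m = 3
  set.seed(202)
  x <- rand_ibi_like(120)
  s <- sample_entropy(x, 3, 20)
  o <- sampen_oracle(x, 3, 20)
  expect_identical(c(s$a_count, s$b_count), as.numeric(c(o$a, o$b)))
})

test_that("sample entropy structural invariants hold on random series", {
  set.seed(7)
  for (i in 1:20) {
    x <- rand_ibi_like(sample(30:150, 1))
    s <- sample_entropy(x, 2, runif(1, 2, 40))
    expect_lte(s$a_count, s$b_count)
    expect_lte(s$phi_m1, s$phi_m)
    expect_lte(s$phi_m, 1)
    if (s$defined) expect_gte(s$se, 0)
  }
})

test_that("sample entropy is invariant to positive rescaling with SD-fraction tolerance", {
  set.seed(33)
  x <- rand_ibi_like(300)
  for (k in c(0.1, 3, 250)) {
    s1 <- sample_entropy(x, 2, 0.15 * sd(x))
    s2 <- sample_entropy(k * x, 2, 0.15 * sd(k * x))
    expect_equal(s1$se, s2$se)
  }
})

test_that("iid Gaussian sample entropy approaches the analytic limit", {
  set.seed(88)
  x <- rnorm(10000)
  s <- sample_entropy(x, 2, 0.15)
  expect_equal(s$se, white_noise_se(1), tolerance = 0.05)
})

test_that("sample entropy flags undefined ratios and rejects bad input", {
  # strictly monotone ramp with tiny tolerance: no template matches at all
  s <- sample_entropy(seq(1, 1000, by = 10), 2, 0.5)
  expect_false(s$defined)
  expect_true(is.na(s$se))
  expect_error(sample_entropy(c(1, 2, 3), 2, 1), class = "hrvci_error_too_short")
  expect_error(sample_entropy(rnorm(50), 2, 0), class = "hrvci_error_bad_argument")
})

test_that("the MSE curve of a constant tachogram is zero at every scale", {
  curve <- mse_curve(ibi_series(rep(750, 750)))
  expect_true(all(curve$defined))
  expect_true(all(curve$se == 0))
})

test_that("MSE length bookkeeping flags scales that are too short", {
  set.seed(5)
  x <- rand_ibi_like(25)
  expect_warning(curve <- mse_curve(ibi_series(x)),
                 class = "hrvci_warning_undefined_scales")
  too_short <- floor(25 / curve$scale) <= 3
  expect_true(all(!curve$defined[too_short]))
  expect_equal(curve$n_points, floor(25 / curve$scale))
})

test_that("the white-noise MSE curve tracks its analytic form", {
  set.seed(61)
  reps <- 5
  mats <- replicate(reps, mse_curve(ibi_series(rand_ibi_like(4000)))$se)
  mean_se <- rowMeans(mats)
  se_of_mean <- apply(mats, 1, sd) / sqrt(reps)
  expected <- white_noise_se(1:10)
  expect_true(all(abs(mean_se - expected) <= pmax(3 * se_of_mean, 0.02)))
  # decreasing in scale for white noise under the fixed-tolerance convention
  expect_true(all(diff(mean_se) < 0.05))
})

test_that("both tolerance conventions are honoured and recorded", {
  set.seed(19)
  x <- rand_ibi_like(1500)
  fixed <- mse_curve(ibi_series(x))
  per <- mse_curve(ibi_series(x), r_convention = "per_scale_sd")
  expect_equal(attr(fixed, "r_convention"), "fixed_scale1_sd")
  expect_equal(fixed$tolerance_abs, rep(0.15 * sd(x), 10))
  expect_equal(per$tolerance_abs[3], 0.15 * sd(coarse_grain(x, 3)))
  # per-scale tolerance tracks the shrinking coarse SD, so the white-noise
  # curve stays roughly flat while the fixed-tolerance curve decreases
  expect_lt(abs(per$se[10] - per$se[1]), abs(fixed$se[10] - fixed$se[1]))
})

test_that("complexity indices sum the right scales and police undefined ones", {
  curve <- tibble::tibble(scale = 1:10, se = rep(1, 10), defined = TRUE)
  class(curve) <- c("mse_curve", class(curve))
  expect_equal(complexity_index(curve, c(1, 5)), 5)
  expect_equal(complexity_index(curve, c(6, 10)), 5)
  expect_error(complexity_index(curve, c(3, 12)), class = "hrvci_error_bad_argument")
  curve$defined[8] <- FALSE
  err <- expect_error(complexity_index(curve, c(6, 10)),
                      class = "hrvci_error_undefined_scale")
  expect_match(conditionMessage(err), "8")
  expect_warning(partial <- complexity_index(curve, c(6, 10), strict = FALSE),
                 class = "hrvci_warning_partial_ci")
  expect_equal(as.numeric(partial), 4)
  expect_true(attr(partial, "partial"))
})

test_that("ci_total equals ci_s + ci_l for ten-scale curves", {
  set.seed(14)
  curve <- mse_curve(ibi_series(rand_ibi_like(900)))
  ci <- complexity_indices(curve)
  expect_equal(ci$ci_total, ci$ci_s + ci$ci_l)
  white <- complexity_index(curve, c(1, 5))
  expect_equal(white, sum(curve$se[1:5]))
})

test_that("the threshold rule labels UWS below and MCS at or above the boundary", {
  expect_equal(classify_by_threshold(5.2), "MCS")
  expect_equal(classify_by_threshold(3.1), "UWS")
  expect_equal(classify_by_threshold(4.876), "MCS")
  expect_equal(classify_by_threshold(c(1, 6)), c("UWS", "MCS"))
  expect_error(classify_by_threshold(NA_real_), class = "hrvci_error_bad_argument")
})
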