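test_that("beats synthesized from known times are recovered within one sample", {
  ibi <- ibi_series(c(800, 800, 900))
  w <- synthesize_ecg(ibi, 500)
  b <- detect_beats(w)
  truth <- attr(w, "beat_times")
  expect_equal(nrow(b), 4)
  expect_true(all(abs(b$time - truth) <= 1 / 500))
})

test_that("a long noiseless tachogram round-trips through ECG within 2 samples per interval", {
  ibi <- generate_ibi(synthetic_profile(), duration = 120, seed = 7)
  w <- synthesize_ecg(ibi, 500)
  b <- detect_beats(w)
  expect_equal(nrow(b), nrow(ibi) + 1)
  rec <- to_ibi(b)
  expect_true(all(abs(rec$interval_ms - ibi$interval_ms) <= 2 / 500 * 1000))
})

test_that("ECG- and PPG-derived interval series are superimposable within 4 ms", {
  ibi <- generate_ibi(synthetic_profile(), duration = 90, seed = 21)
  be <- detect_beats(synthesize_ecg(ibi, 500), method = "ecg_qrs")
  bp <- detect_beats(synthesize_ppg(ibi, 500), method = "ppg_pulse")
  expect_equal(nrow(be), nrow(bp))
  expect_true(all(abs(to_ibi(be)$interval_ms - to_ibi(bp)$interval_ms) <= 4))
})

test_that("flatline input yields zero beats with an explicit warning", {
  w <- waveform(rep(2.5, 2000), 250)
  expect_warning(b <- detect_beats(w), class = "hrvci_warning_flatline")
  expect_equal(nrow(b), 0)
})

test_that("heavy noise degrades detection rather than failing silently", {
  ibi <- ibi_series(rep(800, 20))
  clean <- synthesize_ecg(ibi, 250)
  noisy <- synthesize_ecg(ibi, 250, snr = 0.02, seed = 5)
  nb <- tryCatch(nrow(detect_beats(noisy)), warning = function(w) 0L)
  expect_false(identical(nb, nrow(detect_beats(clean))))
  # determinism of the noisy render
  noisy2 <- synthesize_ecg(ibi, 250, snr = 0.02, seed = 5)
  expect_identical(noisy$amplitude, noisy2$amplitude)
})

test_that("synthesize_ecg rejects rates too low for the template", {
  expect_error(synthesize_ecg(ibi_series(rep(800, 5)), sampling_rate = 50),
               class = "hrvci_error_bad_argument")
})

test_that("to_ibi converts beat times and enforces its contract", {
  expect_equal(to_ibi(c(0, 0.8, 1.6, 2.5))$interval_ms, c(800, 800, 900))
  expect_equal(nrow(to_ibi(c(0, 1))), 1)
  expect_error(to_ibi(c(0, 1, 0.5)), class = "hrvci_error_nonmonotone_beats")
  expect_error(to_ibi(0.5), class = "hrvci_error_too_few_beats")
})

test_that("screen_ectopics flags planted ectopics and only those", {
  x <- rep(800, 200); x[77] <- 1600
  out <- screen_ectopics(ibi_series(x))
  expect_equal(which(out$flag == "ectopic"), 77L)
  expect_equal(attr(out, "ectopic_fraction"), 1 / 200)
  clean <- screen_ectopics(ibi_series(rep(800, 50)))
  expect_equal(sum(clean$flag != "normal"), 0)
  # five planted ectopics at twice the local median, well separated
  set.seed(42)
  y <- 800 + rnorm(400, 0, 10)
  at <- c(40, 110, 200, 290, 360)
  y[at] <- 2 * 800
  flagged <- screen_ectopics(ibi_series(y), deviation_fraction = 0.20)
  expect_setequal(which(flagged$flag == "ectopic"), at)
})

test_that("screen_ectopics is idempotent under flag and supports all actions", {
  set.seed(9)
  y <- 800 + rnorm(300, 0, 15); y[c(50, 150)] <- 1700
  once <- screen_ectopics(ibi_series(y))
  twice <- screen_ectopics(once)
  expect_identical(once$flag, twice$flag)
  interp <- screen_ectopics(ibi_series(y), action = "interpolate")
  expect_setequal(which(interp$flag == "edited"), c(50L, 150L))
  expect_lt(max(interp$interval_ms), 1000)
  dele <- screen_ectopics(ibi_series(y), action = "delete")
  expect_equal(nrow(dele), 298)
  expect_error(screen_ectopics(ibi_series(rep(800, 5)), window = 11),
               class = "hrvci_error_bad_argument")
})

test_that("extract_segment returns the maximal prefix within the duration", {
  seg <- extract_segment(ibi_series(rep(800, 900)), duration = 600)
  expect_equal(nrow(seg), 750)
  expect_equal(sum(seg$interval_ms) / 1000, 600)
  # cumulative sum lands in (duration - max interval, duration]
  set.seed(3)
  x <- 700 + runif(1200, 0, 300)
  s <- extract_segment(ibi_series(x), duration = 600)
  tot <- sum(s$interval_ms)
  expect_lte(tot, 600 * 1000)
  expect_gt(tot, 600 * 1000 - max(x))
  err <- expect_error(extract_segment(ibi_series(rep(1000, 300)), duration = 600),
                      class = "hrvci_error_insufficient_duration")
  expect_match(conditionMessage(err), "300")
  expect_error(extract_segment(ibi_series(rep(800, 10)), duration = 0),
               class = "hrvci_error_bad_argument")
})

test_that("interval files round-trip in both plain and flagged forms", {
  ibi <- ibi_series(c(812.5, 790, 805), c("normal", "ectopic", "normal"))
  path <- withr::local_tempfile(fileext = ".rr")
  write_ibi(ibi, path)
  back <- read_ibi(path)
  expect_equal(back$interval_ms, ibi$interval_ms)
  expect_equal(back$flag, ibi$flag)
  plain <- withr::local_tempfile(fileext = ".rr")
  write_ibi(ibi_series(c(800, 820)), plain)
  expect_equal(read_ibi(plain)$interval_ms, c(800, 820))
  bad <- withr::local_tempfile(fileext = ".rr")
  writeLines(c("800", "x"), bad)
  expect_error(read_ibi(bad), class = "hrvci_error_parse")
})
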