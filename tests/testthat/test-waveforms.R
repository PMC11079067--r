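test_that("a single synthesized wave peaks at its latency with its amplitude", {
  w <- synthesize_waveform(list(la_v = 5.7, am_v = 0.3))
  peak_i <- which.max(w$samples)
  expect_equal(w$time_ms[peak_i], 5.7, tolerance = 1e-9)
  trough <- min(w$samples[w$time_ms >= 5.7 & w$time_ms <= 7.2])
  expect_equal(w$samples[peak_i] - trough, 0.3, tolerance = 2 * w$quantum)
})

test_that("residual noise scales as one over the square root of the averages", {
  set.seed(42)
  w2000 <- synthesize_waveform(list(), noise_sd = 1, averages = 2000)
  set.seed(42)
  w500 <- synthesize_waveform(list(), noise_sd = 1, averages = 500)
  expect_equal(sd(w2000$samples) / sd(w500$samples), 0.5, tolerance = 0.02)
})

test_that("noise-free synthesis and extraction round-trip the reference template", {
  feats <- list(la_i = 1.7, la_ii = 2.8, la_iii = 3.9, la_iv = 5.1,
                la_v = 5.7, am_i = 0.15, am_v = 0.30)
  w <- synthesize_waveform(feats)
  got <- extract_wave_features(w)
  dt <- 1000 / w$sampling_rate
  for (nm in c("la_i", "la_ii", "la_iii", "la_iv", "la_v"))
    expect_lte(abs(got[[nm]] - feats[[nm]]), dt)
  expect_lte(abs(got$am_i - feats$am_i), 2 * w$quantum)
  expect_lte(abs(got$am_v - feats$am_v), 2 * w$quantum)
  # interpeak identities from detected components
  expect_equal(got$la_i_iii, got$la_iii - got$la_i)
  expect_equal(got$la_iii_v, got$la_v - got$la_iii)
  expect_equal(got$la_i_v, got$la_v - got$la_i)
})

test_that("a flat waveform yields all-absent indicators", {
  w <- synthesize_waveform(list())
  got <- extract_wave_features(w)
  expect_true(all(is.na(unlist(got[baep_indicators()]))))
})

test_that("equal-height peaks resolve to the earlier latency", {
  time_ms <- seq(0, 10, by = 0.01)
  x <- numeric(length(time_ms))
  x[abs(time_ms - 5.6) < 0.005] <- 0.3
  x[abs(time_ms - 6.0) < 0.005] <- 0.3
  w <- structure(list(samples = x, time_ms = time_ms, sampling_rate = 1e5,
                      window_ms = c(0, 10), quantum = 0.0025,
                      side = NA, timestamp = NA),
                 class = "baep_waveform")
  got <- extract_wave_features(w)
  expect_equal(got$la_v, 5.6)
})

test_that("extraction is translation-consistent", {
  set.seed(9)
  delta <- 0.35
  for (i in 1:5) {
    f <- random_wave_features()
    f_shift <- f
    for (nm in BAEP_WAVES_TEST) f_shift[[nm]] <- f[[nm]] + delta
    f_shift$la_v <- f$la_v + delta
    w <- synthesize_waveform(f)
    ws <- synthesize_waveform(f_shift)
    wins <- lapply(list(la_i = c(1.2, 2.2), la_ii = c(2.3, 3.3),
                        la_iii = c(3.4, 4.5), la_iv = c(4.6, 5.4),
                        la_v = c(5.4, 6.8)), identity)
    wins_shift <- lapply(wins, function(x) x + delta)
    a <- extract_wave_features(w, wins)
    b <- extract_wave_features(ws, wins_shift)
    dt <- 1000 / w$sampling_rate
    for (nm in c(BAEP_WAVES_TEST, "la_v"))
      expect_lte(abs(b[[nm]] - a[[nm]] - delta), dt + 1e-9)
    expect_lte(abs(b$am_v - a$am_v), 2 * w$quantum)
    expect_lte(abs(b$am_i - a$am_i), 2 * w$quantum)
  }
})

test_that("degenerate synthesis and extraction inputs are rejected", {
  expect_error(synthesize_waveform(list(la_v = 9.9, am_v = 0.3)),
               "too short")
  expect_error(synthesize_waveform(list(la_v = 5.7, am_v = -0.1)),
               "non-positive amplitude")
  w <- synthesize_waveform(list(la_v = 5.7, am_v = 0.3))
  bad <- list(la_i = c(1.2, 2.5), la_ii = c(2.3, 3.3), la_iii = c(3.4, 4.5),
              la_iv = c(4.6, 5.4), la_v = c(5.4, 6.8))
  expect_error(extract_wave_features(w, bad), "non-overlapping")
  outside <- list(la_i = c(-1, 2.2), la_ii = c(2.3, 3.3), la_iii = c(3.4, 4.5),
                  la_iv = c(4.6, 5.4), la_v = c(5.4, 6.8))
  expect_error(extract_wave_features(w, outside), "within the waveform window")
})

test_that("waveforms round-trip through the two-column text format", {
  path <- withr::local_tempfile(fileext = ".txt")
  w <- synthesize_waveform(list(la_v = 5.7, am_v = 0.3),
                           sampling_rate = 20000)
  write_waveform_txt(w, path)
  r <- read_waveform_txt(path)
  expect_equal(r$samples, w$samples, tolerance = 1e-9)
  expect_equal(r$sampling_rate, 20000)
  expect_equal(extract_wave_features(r)$la_v,
               extract_wave_features(w)$la_v)
})
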