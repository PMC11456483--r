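test_that("envelopes of a pure sinusoid recover offset +/- amplitude", {
  fx <- make_fixture("sinusoid")
  env <- envelope(fx$trace, "synthetic", window = c(200, 1800))
  # interior (away from edge extrapolation)
  mid <- env$time_ms > 300 & env$time_ms < 1700
  expect_equal(mean(env$upper[mid]), fx$expected$upper, tolerance = 0.01)
  expect_equal(mean(env$lower[mid]), fx$expected$lower, tolerance = 0.01)
  expect_equal(oscillation_amplitude(fx$trace, "synthetic", c(200, 1800)),
               1, tolerance = 0.01)
})

test_that("a constant trace has coincident envelopes and zero amplitude", {
  tr <- synthetic_trace(amplitude = 0, offset = 5)
  env <- envelope(tr, "synthetic")
  expect_equal(env$upper, rep(5, nrow(env)))
  expect_equal(env$lower, env$upper)
  expect_equal(oscillation_amplitude(tr, "synthetic"), 0)
})

test_that("too-short envelope windows are rejected", {
  tr <- synthetic_trace()
  expect_error(envelope(tr, "synthetic", window = c(0, 50)),
               class = "columnet_config_error")
  expect_error(envelope(tr, "nope"), class = "columnet_config_error")
})

test_that("the amplitude spectrum of a sinusoid peaks at its frequency", {
  for (f in c(18, 30, 44)) {
    tr <- synthetic_trace(f_hz = f, amplitude = 2, offset = 7, t_total = 3000)
    sp <- amplitude_spectrum(tr, "synthetic", window = c(2000, 3000))
    expect_equal(sp$peak_freq, f, tolerance = 1 / f) # +/- 1 Hz resolution
    expect_equal(nrow(sp$peaks), 1)
    expect_equal(max(sp$spectrum$amplitude), 2, tolerance = 0.05)
    if (f >= 25) {
      expect_gt(sp$gamma_amp, 1.5); expect_lt(sp$beta_amp, 0.1)
    } else {
      expect_gt(sp$beta_amp, 1.5)
    }
  }
})

test_that("spectral peaks are prominence-filtered and frequency-sorted", {
  t <- seq(0, 1000, by = 0.1)
  x <- 3 * sin(2 * pi * 30 * t / 1000) + 1 * sin(2 * pi * 60 * t / 1000)
  tr <- synthetic_trace(amplitude = 0, offset = 0, t_total = 1000)
  tr$rates[, 1] <- x
  sp <- amplitude_spectrum(tr, "synthetic", window = c(0, 1000))
  expect_equal(sp$peaks$freq_hz, c(30, 60), tolerance = 0.05)
  expect_true(!is.unsorted(sp$peaks$freq_hz))
  # a prominence threshold above the minor peak leaves only the major one
  sp2 <- amplitude_spectrum(tr, "synthetic", window = c(0, 1000),
                            prominence_frac = 0.5)
  expect_equal(nrow(sp2$peaks), 1)
})

test_that("min-max normalized rates span [0, 1] and are affine-invariant", {
  conds <- c("none", "S1", "S2", "S1S2", "S1S2_A1", "S1S2_A2")
  offsets <- c(2, 9, 4, 6, 8, 3)
  traces <- setNames(lapply(offsets, function(o)
    synthetic_trace(amplitude = 0.5, offset = o)), conds)
  nr <- normalized_rates(traces, "synthetic")
  expect_equal(nr$normalized[which.max(offsets)], 1)
  expect_equal(nr$normalized[which.min(offsets)], 0)
  expect_true(all(nr$normalized >= 0 & nr$normalized <= 1))
  # affine rescale of every trace leaves the normalized values unchanged
  scaled <- lapply(traces, function(tr) { tr$rates <- 3 * tr$rates + 11; tr })
  expect_equal(normalized_rates(scaled, "synthetic")$normalized,
               nr$normalized)
})

test_that("a flat response across conditions normalizes to 0.5 with a warning", {
  conds <- c("none", "S1", "S2", "S1S2", "S1S2_A1", "S1S2_A2")
  traces <- setNames(replicate(6, synthetic_trace(amplitude = 0, offset = 4),
                               simplify = FALSE), conds)
  expect_warning(nr <- normalized_rates(traces, "synthetic"), "Degenerate")
  expect_equal(nr$normalized, rep(0.5, 6))
})

test_that("regime classification is deterministic and margin-monotone", {
  trs <- reference_traces()
  lab1 <- classify_regime(trs)
  lab2 <- classify_regime(trs)
  expect_identical(as.data.frame(lab1), as.data.frame(lab2))
  # increasing the ordering margin can only switch ordered_pattern off
  eps <- c(0.005, 0.02, 0.05, 0.2, 1)
  ordered <- vapply(eps, function(e)
    classify_regime(trs, eps_ord = e)$ordered_pattern, logical(1))
  expect_true(all(diff(as.integer(ordered)) <= 0))
  expect_error(classify_regime(trs[c("S1", "S2")]),
               class = "columnet_config_error")
})

test_that("sweeps label every grid point and isolate failures", {
  # one sane point and one point forced to fail via an impossible ceiling
  map <- sweep_plane(0.3, 0.02, t_total = 6000, t_onset = 3000)
  expect_s3_class(map, "regime_map")
  expect_equal(nrow(map), 1)
  expect_false(map$failed[1])
  expect_true(map$oscillating[1])
})
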