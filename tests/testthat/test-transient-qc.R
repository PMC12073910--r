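# single-condition protocol used to keep spectral fixtures small
mini_protocol <- function(n_transients = 24, b = 0.01) {
  dmrs_protocol(b_values = b, directions = matrix(c(1, 0, 0) / 1, 1),
                transients_per_condition = n_transients)
}

test_that("injected phase corruptions are inverted exactly without noise", {
  ts <- generate_transients("astrosticks", c(Dintra = 0.346),
                            mini_protocol(3), snr_b0 = Inf,
                            peaks = c(tNAA = 2.01),
                            peak_amps = c(tNAA = 1), seed = 1)
  phases <- c(0.3, -0.7, 1.2)
  for (it in 1:3) {
    ts$spectra[, 1, 1, it] <- ts$spectra[, 1, 1, it] * exp(1i * phases[it])
  }
  out <- correct_phase_frequency(ts)
  expect_equal(out$report$phase_rad, phases, tolerance = 1e-6)
  # residual phase dispersion at the reference peak: a second pass finds
  # essentially nothing left to correct
  out2 <- correct_phase_frequency(out$ts)
  expect_lt(max(abs(out2$report$phase_rad)), 1e-6)
  expect_lt(diff(range(out2$report$phase_rad)), 1e-6)
})

test_that("already-aligned transients pass through unchanged", {
  # single clean peak: corrections vanish and the data are untouched
  ts <- generate_transients("astrosticks", c(Dintra = 0.346),
                            mini_protocol(4), snr_b0 = Inf,
                            peaks = c(tNAA = 2.01),
                            peak_amps = c(tNAA = 1), seed = 2)
  before <- ts$spectra
  out <- correct_phase_frequency(ts)
  expect_lt(max(abs(out$report$phase_rad)), 1e-6)
  expect_lt(max(abs(out$report$freq_hz)), 1e-3)
  expect_lt(max(Mod(out$ts$spectra - before)), 1e-5 * max(Mod(before)))
  # idempotence: a second pass changes nothing beyond float tolerance
  out2 <- correct_phase_frequency(out$ts)
  expect_lt(max(Mod(out2$ts$spectra - out$ts$spectra)),
            1e-7 * max(Mod(out$ts$spectra)))

  # with overlapping neighbours the dispersion tails leave only a small,
  # common correction (not an error, a property of crowded spectra)
  ts3 <- generate_transients("astrosticks", c(Dintra = 0.346),
                             mini_protocol(4), snr_b0 = Inf, seed = 2)
  out3 <- correct_phase_frequency(ts3)
  expect_lt(max(abs(out3$report$phase_rad)), 0.15)
  expect_lt(max(abs(out3$report$freq_hz)), 0.5)
  expect_lt(diff(range(out3$report$phase_rad)), 1e-6)
})

test_that("frequency drifts are corrected to sub-bin accuracy under noise", {
  errs <- sapply(1:40, function(i) {
    ts <- generate_transients("astrosticks", c(Dintra = 0.346),
                              mini_protocol(1), snr_b0 = 20,
                              drift_sd = 0, seed = 100 + i)
    # inject a known +2 Hz drift
    n <- dim(ts$spectra)[1]
    t_s <- (seq_len(n) - 1) / ts$bandwidth
    fid <- dmrsage:::fid_from_spec(ts$spectra[, 1, 1, 1])
    ts$spectra[, 1, 1, 1] <- dmrsage:::spec_from_fid(
      fid * exp(2i * pi * 2 * t_s))
    out <- correct_phase_frequency(ts)
    out$report$freq_hz - 2
  })
  expect_lt(median(abs(errs)), 0.2)
})

test_that("amplitude-corrupted transients are detected and discarded", {
  hits <- fa <- 0
  n_rep <- 40
  for (i in seq_len(n_rep)) {
    ts <- generate_transients("astrosticks", c(Dintra = 0.346),
                              mini_protocol(26), snr_b0 = 20,
                              seed = 300 + i)
    corrupted <- c(5, 12)
    for (it in corrupted) {
      ts$spectra[, 1, 1, it] <- ts$spectra[, 1, 1, it] * 0.5
    }
    out <- threshold_transients(correct_phase_frequency(ts)$ts)
    dropped <- which(!out$ts$keep[1, 1, ])
    hits <- hits + as.integer(all(corrupted %in% dropped))
    fa <- fa + length(setdiff(dropped, corrupted))
  }
  expect_gte(hits / n_rep, 0.95)
  expect_lt(fa / (n_rep * 24), 0.05)
})

test_that("clean conditions keep everything; dead conditions are unusable", {
  ts <- generate_transients("astrosticks", c(Dintra = 0.346),
                            mini_protocol(24), snr_b0 = Inf, seed = 4)
  out <- threshold_transients(ts)
  expect_true(all(out$ts$keep))
  expect_true(out$report$usable)

  ts2 <- generate_transients("astrosticks", c(Dintra = 0.346),
                             mini_protocol(24), snr_b0 = 20, seed = 5)
  ts2$spectra <- ts2$spectra * 0
  withr::with_seed(6, {
    ts2$spectra <- ts2$spectra +
      complex(real = rnorm(length(ts2$spectra), 0, 1),
              imaginary = rnorm(length(ts2$spectra), 0, 1))
  })
  out2 <- threshold_transients(correct_phase_frequency(ts2)$ts)
  expect_false(out2$report$usable)
  expect_true(all(is.na(
    quantify_and_average(out2$ts, list(tNAA = c(1.91, 2.11)))$area)))
})

test_that("windowed integration recovers the truncated Lorentzian area", {
  lw <- 4.6
  ts <- generate_transients("astrosticks", c(Dintra = 0.346),
                            mini_protocol(1), snr_b0 = Inf,
                            linewidth = lw, peaks = c(tNAA = 2.01),
                            peak_amps = c(tNAA = 1), seed = 1)
  hw <- 0.1
  ar <- quantify_and_average(ts, list(tNAA = c(2.01 - hw, 2.01 + hw)))
  # analytic oracle: one-sided FID of amplitude A gives absorption area
  # A*(1/pi)*atan(2W/lw) over +/-W (Hz); in the pipeline's summed-bin ppm
  # units that scales by bandwidth/f0, plus the half-first-point DFT
  # baseline across the window's bins
  A <- astrosticks_signal(0.01, 0.346)
  W_hz <- hw * ts$f0
  dppm <- ts$bandwidth / dim(ts$spectra)[1] / ts$f0
  nbins <- sum(abs(ts$ppm - 2.01) <= hw)
  oracle <- A / pi * atan(2 * W_hz / lw) * ts$bandwidth / ts$f0 +
    nbins * A / 2 * dppm
  expect_equal(ar$area, oracle, tolerance = 0.01)
  # linearity: doubling the peak amplitude doubles the area
  ts2 <- generate_transients("astrosticks", c(Dintra = 0.346),
                             mini_protocol(1), snr_b0 = Inf,
                             linewidth = lw, peaks = c(tNAA = 2.01),
                             peak_amps = c(tNAA = 2), seed = 1)
  ar2 <- quantify_and_average(ts2, list(tNAA = c(2.01 - hw, 2.01 + hw)))
  expect_equal(ar2$area / ar$area, 2, tolerance = 1e-8)
})

test_that("pure-noise windows integrate to zero within propagated error", {
  z <- sapply(1:60, function(i) {
    ts <- generate_transients("astrosticks", c(Dintra = 0.346),
                              mini_protocol(1), snr_b0 = 20, seed = 600 + i)
    # integrate a signal-free window and compare with its uncertainty
    ar <- quantify_and_average(ts, list(empty = c(6.2, 6.4)))
    ar$area / ar$area_sd
  })
  expect_lt(abs(mean(z)), 3 / sqrt(60) * 2 + 0.5)
  expect_gt(mean(abs(z) < 3), 0.95)
})

test_that("overlapping quantification windows are rejected", {
  ts <- generate_transients("astrosticks", c(Dintra = 0.346),
                            mini_protocol(1), snr_b0 = Inf, seed = 1)
  expect_error(
    quantify_and_average(ts, list(a = c(2.0, 2.2), b = c(2.1, 2.3))),
    "overlap")
})

test_that("direction averaging is the arithmetic mean with SE spread", {
  areas <- data.frame(metabolite = "tNAA", b = rep(c(0.01, 1.012), each = 4),
                      direction = rep(1:4, 2),
                      area = c(1, 1.1, 0.9, 1, rep(0.8, 4)))
  out <- direction_average(areas)
  expect_equal(out$tNAA$amplitude, c(1, 0.8))
  expect_equal(out$tNAA$sd[1], sd(c(1, 1.1, 0.9, 1)) / 2)
  expect_equal(out$tNAA$sd[2], 0)
  # a b-value with no usable direction is dropped with a warning
  areas$area[areas$b == 1.012] <- NA
  expect_warning(out2 <- direction_average(areas), "dropped")
  expect_equal(out2$tNAA$b, 0.01)
})

test_that("QC improves decay-curve accuracy under matched corruption", {
  p <- dmrs_protocol(b_values = c(0.01, 9.06, 25.1),
                     transients_per_condition = 16)
  rel_err <- function(ts, do_qc) {
    if (do_qc) {
      ts <- correct_phase_frequency(ts)$ts
      ts <- threshold_transients(ts)$ts
    }
    ar <- quantify_and_average(ts, list(tNAA = c(1.91, 2.11)))
    cv <- direction_average(ar)$tNAA
    truth <- astrosticks_signal(cv$b, 0.346)
    mean(abs(cv$amplitude / cv$amplitude[1] - truth / truth[1]))
  }
  errs <- sapply(1:12, function(i) {
    ts <- generate_transients("astrosticks", c(Dintra = 0.346), p,
                              snr_b0 = 20, phase_sd = 0.3, drift_sd = 1.5,
                              corrupt_frac = 0.05, peaks = c(tNAA = 2.01),
                              peak_amps = c(tNAA = 1), seed = 900 + i)
    c(qc = rel_err(ts, TRUE), raw = rel_err(ts, FALSE))
  })
  # paired comparison across seeds: QC must reduce the error
  expect_lt(mean(errs["qc", ] - errs["raw", ]), 0)
  expect_gt(mean(errs["qc", ] < errs["raw", ]), 0.6)
})
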