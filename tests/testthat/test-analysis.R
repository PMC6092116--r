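# Phase-encoded analysis: preprocessing chain, cosine fit, coherence,
# circular statistics.

test_that("preprocessing discards the half cycle and guards its state", {
  truth <- fx_truth()
  run <- generate_run(run_design("radial", "ccw"), truth,
                      noise_model(seed = 5))
  pp <- preprocess_run(run)
  expect_equal(ncol(pp$values), 160)
  expect_true(pp$preprocessed)
  expect_equal(pp$n_cycles_retained, 10)
  expect_error(preprocess_run(pp), "already preprocessed")
  short <- run_timeseries(run$values[, 1:20, drop = FALSE],
                          run$design, preprocessed = TRUE)
  short$preprocessed <- FALSE
  expect_error(preprocess_run(short), "1.5 cycles")
})

test_that("a constant series preprocesses to exactly zero percent change", {
  d <- run_design("radial", "ccw")
  run <- run_timeseries(matrix(700, 3, 168), d)
  pp <- preprocess_run(run)
  expect_equal(max(abs(pp$values)), 0)
})

test_that("drift is removed by detrend + high-pass", {
  truth <- fx_truth()
  drifty <- noise_model(white_sd = 0, drift_linear = 2, drift_quad = 1.5,
                        drift_pink = 0, seed = 8)
  run <- generate_run(run_design("radial", "ccw"), truth, drifty)
  clean <- generate_run(run_design("radial", "ccw"), truth, fx_noiseless())
  pd <- preprocess_run(run)$values
  pc <- preprocess_run(clean)$values
  # quadratic drift is not perfectly removable by a linear + 0.01 Hz
  # chain; the residual must stay small and leave recovery intact
  expect_lt(max(abs(pd - pc)), 0.25 * max(abs(pc)))
  truthp <- fx_truth()$preferred$radial
  fits <- apply(pd, 1, fit_phase_encoded, n_cycles = 10)
  rec <- vapply(fits, `[[`, numeric(1), "preferred_deg")
  amp <- vapply(fits, `[[`, numeric(1), "amplitude")
  ok <- amp > 0.5 * max(amp)
  expect_lt(max(axial_difference(rec[ok], truthp[ok])), 180 / 32)
})

test_that("the cosine fit returns exact amplitude, phase and coherence", {
  n <- 160
  t <- seq_len(n) - 1
  for (phi in c(0.3, 2.1, 5.5)) {
    x <- 1.7 * cos(2 * pi * 10 * t / n - phi)
    f <- fit_phase_encoded(x, 10)
    expect_equal(f$amplitude, 1.7, tolerance = 1e-10)
    expect_equal(f$phase_rad, phi, tolerance = 1e-10)
    expect_equal(f$coherence, 1, tolerance = 1e-12)
  }
  fc <- fit_phase_encoded(rep(2, n), 10)
  expect_equal(fc$amplitude, 0)
  expect_equal(fc$coherence, 0)
  expect_true(is.na(fc$preferred_deg))
  # equal-amplitude second harmonic halves the squared coherence
  x2 <- cos(2 * pi * 10 * t / n) + cos(2 * pi * 30 * t / n + 1)
  expect_equal(fit_phase_encoded(x2, 10)$coherence, 1 / sqrt(2),
               tolerance = 1e-10)
  expect_error(fit_phase_encoded(x2, 80), "n_cycles")
  expect_error(fit_phase_encoded(x2[1:153], 10), "divisible")
})

test_that("phase maps onto the orientation axis with the ccw anchor", {
  expect_equal(phase_to_orientation(0), 0)
  expect_equal(phase_to_orientation(pi), 90)
  expect_equal(phase_to_orientation(2 * pi), 0)
  expect_equal(phase_to_orientation(pi / 2), 45)
})

test_that("noiseless end-to-end recovery is exact; coherence equals the tuning's own spectrum", {
  truth <- fx_truth()
  run <- generate_run(run_design("angular", "ccw"), truth, fx_noiseless())
  pp <- preprocess_run(run)
  tun <- truth$tuning_by_phase$angular$cosine
  for (v in c(2, 17, 33)) {
    f <- fit_phase_encoded(pp$values[v, ], 10)
    expect_lt(axial_difference(f$preferred_deg,
                               cosine_pref_oracle(tun[v, ])), 180 / 32)
    # oracle: fundamental-to-total amplitude ratio of the tuning itself
    x <- tun[v, ] - mean(tun[v, ])
    Fv <- fft(x)
    expect_equal(f$coherence, Mod(Fv[2]) / sqrt(sum(Mod(Fv[2:9])^2)),
                 tolerance = 1e-10)
  }
})

test_that("averaging runs within modulator does not lower coherence below the worst run", {
  truth <- fx_truth()
  sess <- generate_session(session_design(), truth,
                           noise_model(white_sd = 3, seed = 6))
  rad_runs <- Filter(function(r) r$design$modulator_axis == "radial",
                     sess$runs)
  pp <- lapply(rad_runs, preprocess_run)
  single_coh <- vapply(pp, function(r)
    apply(r$values, 1, function(x) fit_phase_encoded(x, 10)$coherence),
    numeric(truth$n_voxels))
  avg <- average_runs(sess, "radial")
  avg_coh <- apply(avg$values, 1, function(x)
    fit_phase_encoded(x, 10)$coherence)
  worst <- apply(single_coh, 1, min)
  # the guarantee is meaningful for signal-carrying voxels; voxels with
  # near-zero response amplitude have noise-dominated coherence either way
  carrying <- avg_coh >= 0.2
  expect_true(all(avg_coh[carrying] >= worst[carrying]))
  expect_gte(mean(avg_coh >= worst), 0.95)
})

test_that("circular correlation behaves as a rotation-invariant axial statistic", {
  set.seed(12)
  a <- runif(40, 0, 180)
  expect_equal(circular_correlation(a, a), 1, tolerance = 1e-12)
  expect_equal(circular_correlation(a, (a + 37) %% 180), 1,
               tolerance = 1e-12)
  b <- runif(1000, 0, 180)
  c2 <- runif(1000, 0, 180)
  expect_lt(abs(circular_correlation(b, c2)), 0.1)
  expect_error(circular_correlation(a, a[-1]), "length")
})

test_that("analyze_session flags voxels under the coherence threshold", {
  truth <- fx_truth()
  sess <- generate_session(session_design(), truth,
                           noise_model(white_sd = 2, seed = 14))
  prefs <- analyze_session(sess, coherence_threshold = 0.2)
  expect_setequal(unique(prefs$modulator), c("radial", "angular"))
  expect_equal(nrow(prefs), 2 * truth$n_voxels)
  expect_identical(prefs$reliable, prefs$coherence >= 0.2)
})
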