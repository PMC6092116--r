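# Shared fixtures, built once per test run and cached. The "world" is
# the sinusoidal-modulator experiment at desk scale: 96 x 96 px over a
# 20 deg field, 1.4 cpd carrier, 0.75-9 deg annulus with 1 deg
# raised-cosine transitions, eccentricity-scaled radial rings (1
# cycle/octave) and 12-cycle angular wedges.

fx <- new.env()

fx_bank <- function(n = 64) {
  key <- sprintf("bank_%d", n)
  if (is.null(fx[[key]]))
    fx[[key]] <- build_filter_bank(pyramid_config(c(n, n)))
  fx[[key]]
}

fx_geom <- function(n = 64, fov = 16) display_geometry(c(n, n), fov / n)

fx_modulators <- function(waveform = "sine") {
  list(
    radial = sapply(c("cosine", "sine"), function(q)
      modulator_spec("radial", waveform, q, 1, log_scaled = TRUE),
      simplify = FALSE),
    angular = sapply(c("cosine", "sine"), function(q)
      modulator_spec("angular", waveform, q, 12), simplify = FALSE))
}

fx_annulus <- function() annulus_spec(0.75, 9, 1)

# session stimulus simulations for the 96 px world (few seconds; cached)
fx_sims <- function() {
  if (is.null(fx$sims)) {
    n <- 96
    geom <- fx_geom(n, 20)
    bank <- fx_bank(n)
    fx$sims <- simulate_session_stimuli(geom, bank, fx_modulators(),
                                        fx_annulus(), sf_cpd = 1.4)
  }
  fx$sims
}

# 48-voxel ground truth (3 eccentricity rings x 16 polar angles)
fx_truth <- function() {
  if (is.null(fx$truth))
    fx$truth <- make_ground_truth(make_prf_grid(c(2, 6.5), 3, 16), fx_sims())
  fx$truth
}

fx_noiseless <- function() noise_model(white_sd = 0, drift_linear = 0,
                                       drift_quad = 0, drift_pink = 0,
                                       seed = 1)

# flat-tuning ground truth: runs carry no stimulus-locked signal
fx_null_truth <- function(V = 8) {
  structure(list(
    prfs = NULL,
    tuning = list(radial = matrix(1, V, 16), angular = matrix(1, V, 16)),
    tuning_by_phase = NULL,
    preferred = list(radial = rep(NA_real_, V),
                     angular = rep(NA_real_, V)),
    baseline = 1000, amplitude_scale = 0, n_voxels = V),
    class = "ground_truth")
}

# small pure-noise session: 4 radial runs, V voxels
fx_null_session <- function(seed, V = 8, white_sd = 1) {
  truth <- fx_null_truth(V)
  designs <- list(run_design("radial", "ccw", "cosine"),
                  run_design("radial", "cw", "cosine"),
                  run_design("radial", "ccw", "sine"),
                  run_design("radial", "cw", "sine"))
  runs <- lapply(seq_along(designs), function(i)
    generate_run(designs[[i]], truth,
                 noise_model(white_sd = white_sd,
                             seed = (seed * 37 + i) %% .Machine$integer.max)))
  list(runs = runs)
}

# independent preferred-orientation oracle: least-squares single-cycle
# cosine fit over the 16 orientation samples
cosine_pref_oracle <- function(responses) {
  th <- 2 * pi * (seq_along(responses) - 1) / length(responses)
  fit <- stats::lm(responses ~ cos(th) + sin(th))
  unname((atan2(stats::coef(fit)[3], stats::coef(fit)[2]) %% (2 * pi)) /
           (2 * pi) * 180)
}

# brute-force diagonal-Gaussian posterior oracle (independent of the
# package's classifier implementation)
oracle_diag_gaussian <- function(train_X, train_y, test_X, n_classes) {
  V <- ncol(train_X)
  means <- t(vapply(seq_len(n_classes), function(k)
    colMeans(train_X[train_y == k, , drop = FALSE]), numeric(V)))
  pooled <- numeric(V)
  for (k in seq_len(n_classes)) {
    rows <- train_X[train_y == k, , drop = FALSE]
    pooled <- pooled + colSums((rows - rep(means[k, ], each = nrow(rows)))^2)
  }
  pooled <- pmax(pooled / (nrow(train_X) - n_classes), 1e-12)
  apply(test_X, 1, function(x) {
    ll <- vapply(seq_len(n_classes), function(k)
      sum(stats::dnorm(x, means[k, ], sqrt(pooled), log = TRUE)), numeric(1))
    which.max(ll)
  })
}
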