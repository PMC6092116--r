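# Synthetic phase-encoded fMRI sessions emulating the orientation
# mapping design: the carrier orientation cycles through 16 evenly
# spaced angles (1.5 s each, TR 1.5 s, one volume per orientation
# step), 10.5 cycles per 252 s run; 8 conditions (cw/ccw x
# radial/angular x sine/cosine modulator phase) x 2 runs = 16 runs per
# session. Voxels are Gaussian pRFs whose orientation tuning comes from
# the vignetting simulation; hemodynamics default to a pure 3-volume
# delay (matching the analysis' shift-based compensation), with an
# optional gamma-IRF convolution; low-frequency drift and white noise
# are added on top.

#' Phase-encoded run design
#'
#' @param modulator_axis `"radial"` or `"angular"`.
#' @param direction `"ccw"` (ascending orientations) or `"cw"`
#'   (descending; defined as the exact time reversal of the ccw
#'   sequence, starting at 168.75 deg).
#' @param modulator_phase `"cosine"` or `"sine"` (stimulus bookkeeping;
#'   tuning is shared within a modulator axis).
#' @param tr_s repetition time in seconds.
#' @param s_per_orientation seconds per orientation step.
#' @param n_orientations orientation steps per cycle.
#' @param n_cycles cycles per run (default 10.5; the leading half cycle
#'   is discarded during preprocessing).
#' @return object of class `run_design` with derived `cycle_s`, `run_s`
#'   and `n_volumes`.
#' @export
run_design <- function(modulator_axis = c("radial", "angular"),
                       direction = c("ccw", "cw"),
                       modulator_phase = c("cosine", "sine"),
                       tr_s = 1.5, s_per_orientation = 1.5,
                       n_orientations = 16L, n_cycles = 10.5) {
  modulator_axis <- match.arg(modulator_axis)
  direction <- match.arg(direction)
  modulator_phase <- match.arg(modulator_phase)
  cycle_s <- n_orientations * s_per_orientation
  run_s <- n_cycles * cycle_s
  n_volumes <- run_s / tr_s
  if (abs(n_volumes - round(n_volumes)) > 1e-9)
    stop("run length must be an integer number of volumes")
  structure(list(modulator_axis = modulator_axis, direction = direction,
                 modulator_phase = modulator_phase,
                 tr_s = tr_s, s_per_orientation = s_per_orientation,
                 n_orientations = as.integer(n_orientations),
                 n_cycles = n_cycles, cycle_s = cycle_s, run_s = run_s,
                 n_volumes = as.integer(round(n_volumes))),
            class = "run_design")
}

# 0-based orientation index shown at volume t (vector ok). ccw ascends
# from index 0; cw is its exact time reversal.
orientation_index <- function(design, t) {
  K <- design$n_orientations
  if (design$direction == "ccw") (t - 1) %% K else (-t) %% K
}

#' Orientation labels of the design
#' @param design a [run_design()].
#' @return the evenly spaced orientations in degrees, `0, 180/K, ...`.
#' @export
orientation_labels <- function(design) {
  (seq_len(design$n_orientations) - 1) * 180 / design$n_orientations
}

#' Session design: the full condition crossing
#'
#' @param runs_per_condition repeats per condition (default 2).
#' @return object of class `session_design`; `$conditions` is the
#'   data.frame of the `{cw, ccw} x {radial, angular} x {sine, cosine}`
#'   crossing with one row per run.
#' @export
session_design <- function(runs_per_condition = 2L) {
  cond <- expand.grid(direction = c("ccw", "cw"),
                      modulator_axis = c("radial", "angular"),
                      modulator_phase = c("cosine", "sine"),
                      stringsAsFactors = FALSE)
  runs <- cond[rep(seq_len(nrow(cond)), each = runs_per_condition), ]
  runs$repetition <- rep(seq_len(runs_per_condition), nrow(cond))
  rownames(runs) <- NULL
  structure(list(conditions = cond, runs = runs,
                 runs_per_condition = as.integer(runs_per_condition)),
            class = "session_design")
}

#' Noise model for synthetic runs
#'
#' Amplitudes are in percent of the voxel baseline. The drift terms
#' (linear + quadratic polynomial and a 1/f Gaussian-process component)
#' exist so the detrend/high-pass stages do real work; the white term
#' sets measurement noise. Defaults give clearly super-threshold but
#' realistically noisy single runs.
#'
#' @param white_sd white-noise SD, percent signal.
#' @param drift_linear,drift_quad maximum excursion of the linear and
#'   quadratic drift terms over a run, percent signal.
#' @param drift_pink SD of the 1/f component, percent signal.
#' @param hemo `"delay"` (pure 3-volume lag) or `"gamma"` (IRF
#'   convolution).
#' @param hemo_lag_s hemodynamic lag in seconds (delay mode; rounded to
#'   whole volumes).
#' @param seed integer RNG seed; identical seeds give identical runs.
#' @export
noise_model <- function(white_sd = 1, drift_linear = 0.5, drift_quad = 0.3,
                        drift_pink = 0.3, hemo = c("delay", "gamma"),
                        hemo_lag_s = 4.5, seed = 1L) {
  hemo <- match.arg(hemo)
  if (white_sd < 0) stop("white_sd must be >= 0")
  structure(list(white_sd = white_sd, drift_linear = drift_linear,
                 drift_quad = drift_quad, drift_pink = drift_pink,
                 hemo = hemo, hemo_lag_s = hemo_lag_s,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Deterministic grid of pRFs
#'
#' @param ecc_range `(min, max)` eccentricity in degrees.
#' @param n_ecc number of eccentricity rings.
#' @param n_polar number of equally spaced polar angles per ring.
#' @param sigma_rule function mapping eccentricity to pRF sigma
#'   (monotone nondecreasing for realistic cortex); default
#'   `0.5 + 0.1 * ecc`.
#' @return list of [prf()] objects of length `n_ecc * n_polar`.
#' @export
make_prf_grid <- function(ecc_range, n_ecc, n_polar,
                          sigma_rule = function(e) 0.5 + 0.1 * e) {
  if (n_ecc < 1 || n_polar < 1) stop("pRF grid must be nonempty")
  eccs <- seq(ecc_range[1], ecc_range[2], length.out = n_ecc)
  angs <- seq(0, 2 * pi, length.out = n_polar + 1)[-(n_polar + 1)]
  out <- list()
  for (e in eccs) for (a in angs)
    out[[length(out) + 1L]] <- prf(e * cos(a), e * sin(a), sigma_rule(e))
  out
}

#' Ground truth voxels from the vignetting model
#'
#' Samples the per-modulator orientation maps with each pRF to obtain
#' the 16-point tuning that drives the synthetic voxel, and attaches
#' signal bookkeeping.
#'
#' @param prfs list of [prf()] objects.
#' @param sims either a [simulate_session_stimuli()] result
#'   (`modulator_sims`; gives per-modulator-phase tuning) or a named
#'   list of [simulate_orientation_maps()] results, one per modulator
#'   axis (names `"radial"`, `"angular"`).
#' @param baseline image-intensity baseline.
#' @param amplitude_scale peak-to-baseline modulation, percent signal.
#' @return object of class `ground_truth`: per-axis phase-averaged
#'   tuning matrices (voxels x 16) in `$tuning`, per-modulator-phase
#'   tuning in `$tuning_by_phase` when available, preferred
#'   orientations, and the pRFs.
#' @export
make_ground_truth <- function(prfs, sims, baseline = 1000,
                              amplitude_scale = 2) {
  V <- length(prfs)
  tune_from <- function(sim) {
    tp <- lapply(prfs, function(p) predict_prf_tuning(sim, p))
    list(tuning = do.call(rbind, lapply(tp, `[[`, "responses")),
         preferred = vapply(tp, `[[`, numeric(1), "preferred_deg"))
  }
  tuning <- list(); preferred <- list(); by_phase <- NULL
  if (inherits(sims, "modulator_sims")) {
    by_phase <- list()
    for (ax in names(sims$avg)) {
      tf <- tune_from(sims$avg[[ax]])
      tuning[[ax]] <- tf$tuning
      preferred[[ax]] <- tf$preferred
      by_phase[[ax]] <- lapply(sims$by_phase[[ax]],
                               function(s) tune_from(s)$tuning)
    }
  } else {
    stopifnot(length(sims) >= 1, !is.null(names(sims)))
    for (ax in names(sims)) {
      tf <- tune_from(sims[[ax]])
      tuning[[ax]] <- tf$tuning
      preferred[[ax]] <- tf$preferred
    }
  }
  structure(list(prfs = prfs, tuning = tuning,
                 tuning_by_phase = by_phase, preferred = preferred,
                 baseline = baseline, amplitude_scale = amplitude_scale,
                 n_voxels = V),
            class = "ground_truth")
}

# causal gamma IRF sampled at TR (peak ~ hemo_lag_s)
gamma_irf <- function(tr_s, lag_s, len = 16) {
  t <- (0:(len - 1)) * tr_s
  shape <- 4
  rate <- shape / lag_s
  h <- stats::dgamma(t, shape = shape, rate = rate)
  h / sum(h)
}

#' Generate one synthetic phase-encoded run
#'
#' The neural drive per volume is the voxel's ground-truth tuning at
#' the orientation currently shown (cw runs reverse the sequence). The
#' drive is delayed (or convolved) by the hemodynamic model using the
#' periodic pre-run extension of the stimulus sequence, scaled to
#' `amplitude_scale` percent about the baseline, and drift plus white
#' noise are added.
#'
#' @param design a [run_design()].
#' @param truth a [make_ground_truth()] result containing the design's
#'   modulator axis.
#' @param noise a [noise_model()].
#' @return object of class `run_timeseries` (`values`: voxels x
#'   volumes, raw intensity units) with the design attached.
#' @export
generate_run <- function(design, truth, noise) {
  stopifnot(inherits(design, "run_design"), inherits(truth, "ground_truth"),
            inherits(noise, "noise_model"))
  tun <- NULL
  if (!is.null(truth$tuning_by_phase))
    tun <- truth$tuning_by_phase[[design$modulator_axis]][[design$modulator_phase]]
  if (is.null(tun)) tun <- truth$tuning[[design$modulator_axis]]
  if (is.null(tun))
    stop("ground truth has no tuning for modulator axis '",
         design$modulator_axis, "'")
  V <- nrow(tun)
  Tn <- design$n_volumes
  lag <- as.integer(round(noise$hemo_lag_s / design$tr_s))

  # neural drive with periodic pre-run extension for causality
  pad <- 32L
  t_ext <- (1 - pad):Tn
  drive_ext <- tun[, orientation_index(design, t_ext) + 1, drop = FALSE]
  if (noise$hemo == "delay") {
    resp <- drive_ext[, pad + seq_len(Tn) - lag, drop = FALSE]
  } else {
    h <- gamma_irf(design$tr_s, noise$hemo_lag_s)
    resp <- matrix(0, V, Tn)
    for (j in seq_along(h))
      resp <- resp + h[j] * drive_ext[, pad + seq_len(Tn) - (j - 1),
                                      drop = FALSE]
  }

  # Scale to percent-signal modulation about the baseline. The mean and
  # range are taken from the 16-point tuning itself (not the realized
  # run, whose extra half cycle over-samples some orientations), so cw
  # and ccw runs of one condition are exact time reversals of each
  # other before noise.
  m <- rowMeans(tun)
  d0 <- resp - m
  rng <- apply(abs(tun - m), 1, max)
  rng[rng == 0] <- 1
  pct <- (truth$amplitude_scale / 100) * d0 / rng
  base <- truth$baseline
  values <- base * (1 + pct)

  with_seed(noise$seed, {
    tt <- seq(0, 1, length.out = Tn)
    if (noise$drift_linear > 0)
      values <- values + base * (noise$drift_linear / 100) *
        stats::runif(V, -1, 1) %o% (2 * tt - 1)
    if (noise$drift_quad > 0)
      values <- values + base * (noise$drift_quad / 100) *
        stats::runif(V, -1, 1) %o% (8 * (tt - 0.5)^2 - 1)
    if (noise$drift_pink > 0)
      values <- values + base * (noise$drift_pink / 100) *
        pink_noise(V, Tn)
    if (noise$white_sd > 0)
      values <- values + matrix(stats::rnorm(V * Tn,
                                             sd = base * noise$white_sd / 100),
                                V, Tn)
  })
  run_timeseries(values, design)
}

# unit-SD 1/f (amplitude ~ f^(-1/2)) Gaussian noise, one row per voxel
pink_noise <- function(V, Tn) {
  f <- seq_len(Tn) - 1
  f[f > Tn / 2] <- f[f > Tn / 2] - Tn
  w <- ifelse(f == 0, 0, 1 / sqrt(abs(f)))
  out <- matrix(0, V, Tn)
  for (v in seq_len(V)) {
    Fw <- stats::fft(stats::rnorm(Tn)) * w
    x <- Re(stats::fft(Fw, inverse = TRUE) / Tn)
    out[v, ] <- (x - mean(x)) / stats::sd(x)
  }
  out
}

#' Run time-series container
#'
#' @param values voxels x volumes matrix.
#' @param design the [run_design()].
#' @param preprocessed logical preprocessing state flag.
#' @export
run_timeseries <- function(values, design, preprocessed = FALSE) {
  stopifnot(is.matrix(values), inherits(design, "run_design"))
  if (!preprocessed && ncol(values) != design$n_volumes)
    stop("volume count (", ncol(values),
         ") inconsistent with design (", design$n_volumes, ")")
  structure(list(values = values, design = design,
                 preprocessed = preprocessed),
            class = "run_timeseries")
}

#' @export
print.run_timeseries <- function(x, ...) {
  cat(sprintf("run_timeseries: %d voxels x %d volumes (%s, %s, %s)\n",
              nrow(x$values), ncol(x$values), x$design$modulator_axis,
              x$design$direction,
              if (x$preprocessed) "preprocessed" else "raw"))
  invisible(x)
}

#' Generate a full synthetic session
#'
#' All 16 runs of the 2 x 2 x 2 crossing with 2 repeats; ground truth
#' is retained alongside. Per-run noise seeds are derived
#' deterministically from the session seed.
#'
#' @param sdesign a [session_design()].
#' @param truth a [make_ground_truth()] result.
#' @param noise a [noise_model()]; its `seed` seeds the whole session.
#' @return object of class `synthetic_session` with `runs` (list of
#'   `run_timeseries`), `truth`, `noise`, `design`.
#' @export
generate_session <- function(sdesign = session_design(), truth, noise) {
  stopifnot(inherits(sdesign, "session_design"))
  runs <- vector("list", nrow(sdesign$runs))
  for (i in seq_len(nrow(sdesign$runs))) {
    row <- sdesign$runs[i, ]
    rd <- run_design(row$modulator_axis, row$direction, row$modulator_phase)
    rnoise <- noise
    rnoise$seed <- as.integer((noise$seed * 131L + i) %% .Machine$integer.max)
    runs[[i]] <- generate_run(rd, truth, rnoise)
  }
  structure(list(runs = runs, truth = truth, noise = noise,
                 design = sdesign),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("synthetic_session: %d runs, %d voxels\n",
              length(x$runs), nrow(x$runs[[1]]$values)))
  invisible(x)
}

#' Calibrate white-noise level to a target coherence
#'
#' Chooses `white_sd` so that the median single-run voxel coherence
#' (after standard preprocessing) is approximately `target`. Bisection
#' on log noise level; deterministic given the seed.
#'
#' @param truth a [make_ground_truth()] result.
#' @param target target median coherence in (0, 1).
#' @param noise template [noise_model()] (drift/hemo settings reused).
#' @param iters bisection iterations.
#' @return the calibrated `white_sd` (percent signal).
#' @export
calibrate_noise <- function(truth, target = 0.3, noise = noise_model(),
                            iters = 8) {
  stopifnot(target > 0, target < 1)
  design <- run_design("radial", "ccw")
  med_coh <- function(sd) {
    nm <- noise
    nm$white_sd <- sd
    run <- generate_run(design, truth, nm)
    pp <- preprocess_run(run)
    co <- apply(pp$values, 1, function(x)
      fit_phase_encoded(x, n_cycles = 10)$coherence)
    stats::median(co)
  }
  lo <- 0.05; hi <- 50
  for (i in seq_len(iters)) {
    mid <- sqrt(lo * hi)
    if (med_coh(mid) > target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}
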