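# Voxelwise phase-encoded analysis: the preprocessing chain, cosine fit
# with coherence, phase-to-orientation mapping, and the Fisher-Lee
# circular correlation used to compare measured preferences against
# model predictions.

#' Preprocess a phase-encoded run
#'
#' In order: discard the first half cycle (8 volumes, leaving an
#' integer number of cycles); linear detrend per voxel; high-pass
#' filter by zeroing Fourier bins strictly below the cutoff; divide by
#' the (pre-detrend) mean to convert to percent signal change; shift
#' back in time by the hemodynamic compensation (3 volumes = 4.5 s,
#' circular over the retained cycles); time-reverse clockwise runs to
#' match the counterclockwise sequence; and circularly realign by the
#' discarded half cycle so volume 1 again corresponds to the first
#' orientation of the ccw sequence (making phase 0 map to 0 deg).
#'
#' @param run a raw [run_timeseries()].
#' @param highpass_hz high-pass cutoff in Hz (default 0.01).
#' @param shift_volumes hemodynamic compensation in volumes (default 3).
#' @param pct_before_filter divide by the mean before (instead of
#'   after) detrending/filtering; sensitivity-analysis flag, identical
#'   results up to scaling.
#' @return a preprocessed `run_timeseries` in percent-change units
#'   (zero mean), with `n_cycles_retained` attached.
#' @export
preprocess_run <- function(run, highpass_hz = 0.01, shift_volumes = 3L,
                           pct_before_filter = FALSE) {
  stopifnot(inherits(run, "run_timeseries"))
  if (run$preprocessed)
    stop("run is already preprocessed; preprocessing stages must not be applied twice")
  d <- run$design
  K <- d$n_orientations
  n_discard <- as.integer(K / 2)
  if (ncol(run$values) < 1.5 * K)
    stop("run too short: need at least 1.5 cycles")
  vals <- run$values[, -(seq_len(n_discard)), drop = FALSE]
  Tn <- ncol(vals)
  if (Tn %% K != 0)
    stop("retained volumes must be an integer number of cycles")

  mean0 <- rowMeans(vals)
  if (pct_before_filter) {
    vals <- 100 * (vals / mean0 - 1)
  }

  # Linear detrend: remove the per-voxel mean and best-fit slope. The
  # slope is estimated after projecting out the within-cycle mean
  # pattern, so a purely periodic (noiseless) series is left exactly
  # unchanged; on noisy data this matches a plain linear fit to within
  # the trend aliased into the stimulus frequency.
  tt <- seq_len(Tn) - (Tn + 1) / 2
  n_cyc <- Tn %/% K
  cyc_proj <- function(M) {
    # subtract each voxel's within-cycle mean pattern
    M - t(apply(M, 1, function(x) rep(rowMeans(matrix(x, nrow = K)),
                                      times = n_cyc)))
  }
  vals <- vals - rowMeans(vals)
  resid <- cyc_proj(vals)
  tt_r <- tt - rep(rowMeans(matrix(tt, nrow = K)), times = n_cyc)
  denom_t <- sum(tt_r^2)
  slope <- if (denom_t > 0) as.numeric(resid %*% tt_r) / denom_t else 0
  vals <- vals - slope %o% tt

  # high-pass: zero bins strictly below the cutoff (and conjugates)
  freqs <- (seq_len(Tn) - 1) / (Tn * d$tr_s)
  freqs <- pmin(freqs, 1 / d$tr_s - freqs)   # two-sided
  kill <- freqs > 0 & freqs < highpass_hz
  if (any(kill)) {
    Fv <- stats::mvfft(t(vals))
    Fv[kill, ] <- 0
    vals <- t(Re(stats::mvfft(Fv, inverse = TRUE) / Tn))
  }

  if (!pct_before_filter) {
    vals <- 100 * vals / mean0
  }

  # circular shift back by the hemodynamic compensation
  idx <- ((seq_len(Tn) - 1 + shift_volumes) %% Tn) + 1
  vals <- vals[, idx, drop = FALSE]

  # direction normalization: reverse cw runs
  if (d$direction == "cw") vals <- vals[, rev(seq_len(Tn)), drop = FALSE]

  # realign the discarded half cycle (circular; series is periodic)
  idx2 <- ((seq_len(Tn) - 1 - n_discard) %% Tn) + 1
  vals <- vals[, idx2, drop = FALSE]

  out <- run_timeseries(vals, d, preprocessed = TRUE)
  out$n_cycles_retained <- Tn / K
  out
}

#' Cosine fit at the stimulus fundamental
#'
#' Amplitude and phase are the discrete Fourier component at the
#' stimulus fundamental (`n_cycles` cycles per series). Coherence is
#' the fundamental amplitude divided by the root-sum-square of
#' amplitudes at all nonzero frequencies (half spectrum), the standard
#' traveling-wave reliability index in `[0, 1]`.
#'
#' @param ts numeric vector, one voxel's (preprocessed) series.
#' @param n_cycles stimulus cycles in the series.
#' @return object of class `voxel_preference`: `amplitude`, `phase_rad`
#'   (cosine phase delay in `[0, 2pi)`), `coherence`, and
#'   `preferred_deg` mapped through [phase_to_orientation()] (`NA` when
#'   the series is constant).
#' @export
fit_phase_encoded <- function(ts, n_cycles) {
  n <- length(ts)
  if (n_cycles < 1 || n_cycles >= n / 2)
    stop("n_cycles must be in [1, length(ts)/2)")
  if (n %% n_cycles != 0)
    stop("series length must be divisible by n_cycles")
  Fv <- stats::fft(ts)
  k <- n_cycles + 1L
  amp <- 2 * Mod(Fv[k]) / n
  denom <- sqrt(sum(Mod(Fv[2:(floor(n / 2) + 1)])^2))
  if (denom <= .Machine$double.eps * n * (mean(abs(ts)) + 1)) {
    return(structure(list(amplitude = 0, phase_rad = NA_real_,
                          coherence = 0, preferred_deg = NA_real_),
                     class = "voxel_preference"))
  }
  coh <- Mod(Fv[k]) / denom
  phase <- (-Arg(Fv[k])) %% (2 * pi)
  structure(list(amplitude = amp, phase_rad = phase, coherence = coh,
                 preferred_deg = phase_to_orientation(phase)),
            class = "voxel_preference")
}

#' Map a cosine phase to an orientation
#'
#' For a lag-compensated, direction-normalized, realigned series, phase
#' 0 corresponds to the first orientation of the ccw sequence (0 deg)
#' and one full response cycle spans the 180 deg orientation sweep.
#'
#' @param phase_rad cosine phase delay in radians.
#' @param design optional [run_design()] (unused by the default
#'   mapping; accepted for interface symmetry).
#' @return orientation in degrees, `[0, 180)`.
#' @export
phase_to_orientation <- function(phase_rad, design = NULL) {
  (phase_rad / (2 * pi) * 180) %% 180
}

#' Average preprocessed runs within a modulator type
#'
#' Averages the (preprocessed) time series of all runs of the given
#' modulator axis: sine + cosine modulator phases, cw + ccw directions
#' and repeats, as the sequence-normalized series are aligned.
#'
#' @param session a `synthetic_session` (or any list with `$runs`).
#' @param modulator_axis `"radial"` or `"angular"`.
#' @param ... passed to [preprocess_run()] for raw runs.
#' @return a preprocessed `run_timeseries` of the averaged series.
#' @export
average_runs <- function(session, modulator_axis, ...) {
  runs <- Filter(function(r) r$design$modulator_axis == modulator_axis,
                 session$runs)
  if (length(runs) == 0) stop("no runs for modulator '", modulator_axis, "'")
  pp <- lapply(runs, function(r)
    if (r$preprocessed) r else preprocess_run(r, ...))
  avg <- Reduce(`+`, lapply(pp, `[[`, "values")) / length(pp)
  out <- run_timeseries(avg, pp[[1]]$design, preprocessed = TRUE)
  out$n_cycles_retained <- pp[[1]]$n_cycles_retained
  out
}

#' Voxelwise preference table for a session
#'
#' Preprocesses and averages runs within each modulator type, fits the
#' fundamental cosine per voxel, and flags voxels below the coherence
#' reporting threshold.
#'
#' @param session a `synthetic_session` or imported session.
#' @param coherence_threshold reporting threshold (default 0.2, the
#'   conventional map threshold).
#' @param ... passed to [preprocess_run()].
#' @return data.frame: `voxel`, `modulator`, `preferred_deg`,
#'   `amplitude`, `coherence`, `reliable`.
#' @export
analyze_session <- function(session, coherence_threshold = 0.2, ...) {
  axes <- unique(vapply(session$runs,
                        function(r) r$design$modulator_axis, character(1)))
  out <- list()
  for (ax in axes) {
    avg <- average_runs(session, ax, ...)
    nc <- avg$n_cycles_retained
    fits <- apply(avg$values, 1, fit_phase_encoded, n_cycles = nc)
    out[[ax]] <- data.frame(
      voxel = seq_len(nrow(avg$values)),
      modulator = ax,
      preferred_deg = vapply(fits, `[[`, numeric(1), "preferred_deg"),
      amplitude = vapply(fits, `[[`, numeric(1), "amplitude"),
      coherence = vapply(fits, `[[`, numeric(1), "coherence"))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$reliable <- res$coherence >= coherence_threshold
  res
}

#' Fisher-Lee circular correlation for axial data
#'
#' Angles are doubled before correlating (orientations are axial,
#' period 180 deg). The statistic is invariant to rotating either set
#' by a constant.
#'
#' @param a,b orientations in degrees, equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
circular_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3) stop("need at least 3 paired angles")
  aa <- 2 * a * pi / 180
  bb <- 2 * b * pi / 180
  sa <- outer(aa, aa, function(x, y) sin(x - y))
  sb <- outer(bb, bb, function(x, y) sin(x - y))
  num <- sum(sa * sb)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den == 0) return(0)
  num / den
}
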