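# Vignetting simulation: turn model channel energy into simulated voxel
# maps, orientation-bias maps, and pRF-sampled single-voxel orientation
# tuning predictions.
#
# A "simulated voxel map" treats each pixel of the model output as a
# voxel at the corresponding retinotopic location: for each stimulus
# (one per carrier phase) the image is decomposed, channel energies are
# computed, the scale with maximal total response (summed over pixels
# and orientations, averaged over phases) is selected globally for the
# stimulus family, and the orientation-summed energy at that scale is
# returned, phase-averaged. Because orientation channels are *summed*,
# any orientation dependence that survives is due to the vignette.

#' Simulate a voxel map for one stimulus condition
#'
#' @param stimuli a luminance matrix or a list of matrices (one per
#'   carrier phase) sharing the bank's geometry.
#' @param bank a [build_filter_bank()] result.
#' @param scale optional scale index to force; by default the scale with
#'   maximal phase-averaged total energy is selected.
#' @return a matrix (pixels) of nonnegative simulated responses with
#'   attributes `scale` (the selected scale) and `scale_totals`.
#' @export
simulate_voxel_map <- function(stimuli, bank, scale = NULL) {
  stopifnot(inherits(bank, "filter_bank"))
  if (is.matrix(stimuli)) stimuli <- list(stimuli)
  if (!is.list(stimuli) || length(stimuli) == 0)
    stop("stimuli must be a nonempty list of luminance matrices")
  n_scales <- bank$config$n_scales
  acc <- vector("list", n_scales)
  for (im in stimuli) {
    maps <- scale_energy_maps(im, bank)
    for (s in seq_len(n_scales))
      acc[[s]] <- if (is.null(acc[[s]])) maps[[s]] else acc[[s]] + maps[[s]]
  }
  totals <- vapply(acc, sum, numeric(1)) / length(stimuli)
  if (is.null(scale)) scale <- which.max(totals)
  out <- acc[[scale]] / length(stimuli)
  attr(out, "scale") <- scale
  attr(out, "scale_totals") <- totals
  out
}

#' Orientation bias map
#'
#' Pixelwise difference between the simulated responses to two carrier
#' orientations (conventionally vertical minus horizontal). Positive
#' values mean a preference for the first input.
#'
#' @param map_v,map_h voxel maps with identical geometry.
#' @return signed bias map; `orientation_bias_map(a, b) == -orientation_bias_map(b, a)`.
#' @export
orientation_bias_map <- function(map_v, map_h) {
  if (!all(dim(map_v) == dim(map_h)))
    stop("bias map inputs must share the same geometry")
  unclass(map_v) - unclass(map_h)
}

#' Gaussian population receptive field
#'
#' @param x0,y0 center in degrees (x rightward, y upward from fixation).
#' @param sigma Gaussian SD in degrees (> 0).
#' @export
prf <- function(x0, y0, sigma) {
  if (sigma <= 0) stop("prf sigma must be positive")
  structure(list(x0 = x0, y0 = y0, sigma = sigma), class = "prf")
}

# pRF weight map, truncated at 4 sigma and renormalized to unit mass.
prf_weights <- function(geom, p) {
  xy <- geometry_xy(geom)
  d2 <- (xy$x - p$x0)^2 + (xy$y - p$y0)^2
  w <- exp(-d2 / (2 * p$sigma^2))
  w[d2 > (4 * p$sigma)^2] <- 0
  tot <- sum(w)
  if (tot <= .Machine$double.eps * length(w) * 10)
    stop("pRF has (almost) no mass inside the field of view")
  w / tot
}

#' Simulate orientation-tuned response maps for a modulator condition
#'
#' Renders the full carrier-orientation sweep under one modulator,
#' passes each phase set through the energy model, selects a single
#' scale for the whole family (maximal total energy across orientations
#' and phases), and returns the per-orientation phase-averaged
#' orientation-summed energy maps.
#'
#' @param geom a [display_geometry()].
#' @param bank a matching `filter_bank`.
#' @param orientations_deg carrier orientations (default the 16 values
#'   `0, 11.25, ..., 168.75`).
#' @param sf_cpd carrier spatial frequency in cycles/degree.
#' @param modulator optional [modulator_spec()].
#' @param annulus optional [annulus_spec()].
#' @param phases carrier phases averaged over (default quadrature pair,
#'   exactly equal to the 16-phase uniform average for energy responses).
#' @param contrast carrier contrast.
#' @param scale force this scale index instead of selecting the maximal
#'   one (used to hold the scale fixed across stimulus families).
#' @return list with `maps` (one matrix per orientation),
#'   `orientations_deg`, `scale`, `scale_totals`, `geom`.
#' @export
simulate_orientation_maps <- function(geom, bank,
                                      orientations_deg = seq(0, 180, length.out = 17)[-17],
                                      sf_cpd = 0.5,
                                      modulator = NULL, annulus = NULL,
                                      phases = c(0, pi / 2),
                                      contrast = 1, scale = NULL) {
  stopifnot(inherits(geom, "display_geometry"),
            inherits(bank, "filter_bank"))
  if (!all(geom$shape == bank$config$image_shape))
    stop("geometry and filter bank shapes differ")
  n_scales <- bank$config$n_scales
  n_or <- length(orientations_deg)
  per_or <- vector("list", n_or)   # per orientation: list of per-scale maps
  for (i in seq_len(n_or)) {
    stims <- stimulus_phase_set(
      geom, carrier_spec(orientations_deg[i], sf_cpd, contrast = contrast),
      modulator = modulator, annulus = annulus, phases = phases)
    acc <- vector("list", n_scales)
    for (im in stims) {
      maps <- scale_energy_maps(im, bank)
      for (s in seq_len(n_scales))
        acc[[s]] <- if (is.null(acc[[s]])) maps[[s]] else acc[[s]] + maps[[s]]
    }
    per_or[[i]] <- lapply(acc, function(m) m / length(stims))
  }
  totals <- rowSums(vapply(per_or, function(l) vapply(l, sum, numeric(1)),
                           numeric(n_scales)))
  best <- if (is.null(scale)) which.max(totals) else as.integer(scale)
  list(maps = lapply(per_or, `[[`, best),
       orientations_deg = orientations_deg,
       scale = best, scale_totals = totals, geom = geom)
}

#' Simulate the full session stimulus family
#'
#' Runs the energy model for every modulator axis and modulator spatial
#' phase of the experiment, under a single pyramid scale selected
#' globally across the whole family (the experiment holds one carrier
#' frequency, so population responses arise from one band). Per-axis
#' maps averaged across modulator phases are also returned; these are
#' the model predictions for an analysis that averages runs across
#' modulator phase.
#'
#' @param geom,bank geometry and filter bank.
#' @param modulators named list (`radial`, `angular`) of *lists* of
#'   [modulator_spec()]s, one per modulator spatial phase.
#' @param annulus an [annulus_spec()].
#' @param sf_cpd carrier spatial frequency.
#' @param ... further arguments to [simulate_orientation_maps()].
#' @return object of class `modulator_sims`: `by_phase[[axis]][[phase]]`
#'   (per-phase sims), `avg[[axis]]` (phase-averaged sims), `scale`.
#' @export
simulate_session_stimuli <- function(geom, bank, modulators, annulus,
                                     sf_cpd, ...) {
  one <- function(m, scale = NULL)
    simulate_orientation_maps(geom, bank, sf_cpd = sf_cpd, modulator = m,
                              annulus = annulus, scale = scale, ...)
  by_phase <- lapply(modulators, function(specs) lapply(specs, one))
  flat <- unlist(by_phase, recursive = FALSE)
  totals <- Reduce(`+`, lapply(flat, `[[`, "scale_totals"))
  scale <- which.max(totals)
  for (ax in names(by_phase)) {
    for (q in seq_along(by_phase[[ax]])) {
      if (by_phase[[ax]][[q]]$scale != scale)
        by_phase[[ax]][[q]] <- one(modulators[[ax]][[q]], scale = scale)
    }
  }
  avg <- lapply(by_phase, function(phs) {
    out <- phs[[1]]
    out$maps <- Reduce(function(a, b) Map(`+`, a, b),
                       lapply(phs, `[[`, "maps"))
    out$maps <- lapply(out$maps, function(m) m / length(phs))
    out
  })
  structure(list(by_phase = by_phase, avg = avg, scale = scale,
                 geom = geom),
            class = "modulator_sims")
}

#' Predict a voxel's orientation tuning from its pRF
#'
#' Each per-orientation voxel map is sampled by the Gaussian pRF
#' (truncated at 4 sigma, unit mass), and a single-cycle cosine is fit
#' to the resulting responses via the fundamental discrete Fourier
#' component; the cosine phase maps linearly onto the orientation axis.
#'
#' @param maps list of per-orientation voxel maps (evenly spaced
#'   orientations starting at 0), or a [simulate_orientation_maps()]
#'   result.
#' @param p a [prf()].
#' @param geom the [display_geometry()] of the maps (taken from `maps`
#'   when it is a `simulate_orientation_maps` result).
#' @return object of class `tuning_prediction`: `responses`,
#'   `preferred_deg` in `[0, 180)` (`NA` when amplitude is 0),
#'   `amplitude`.
#' @export
predict_prf_tuning <- function(maps, p, geom = NULL) {
  if (is.list(maps) && !is.null(maps$maps)) {
    geom <- maps$geom
    maps <- maps$maps
  }
  stopifnot(inherits(p, "prf"), inherits(geom, "display_geometry"))
  w <- prf_weights(geom, p)
  responses <- vapply(maps, function(m) sum(unclass(m) * w), numeric(1))
  fit <- cosine_fit_fundamental(responses)
  structure(list(responses = responses,
                 preferred_deg = fit$preferred_deg,
                 amplitude = fit$amplitude),
            class = "tuning_prediction")
}

# Fundamental DFT component of an n-point tuning vector sampled at
# orientations i * 180/n, i = 0..n-1. Equivalent to the least-squares
# single-cycle cosine fit for complete, evenly spaced samples.
cosine_fit_fundamental <- function(responses) {
  n <- length(responses)
  z <- sum(responses * exp(-2i * pi * (seq_len(n) - 1) / n))
  amplitude <- 2 * Mod(z) / n
  scale_ref <- mean(abs(responses)) + .Machine$double.eps
  if (amplitude <= 1e-12 * scale_ref) {
    return(list(amplitude = 0, preferred_deg = NA_real_, phase_rad = NA_real_))
  }
  phi <- (-Arg(z)) %% (2 * pi)
  list(amplitude = amplitude, preferred_deg = phi / (2 * pi) * 180,
       phase_rad = phi)
}

#' Predicted preferred orientations on a ring of pRFs
#'
#' Convenience used for the modulator-flip analysis: places `n_polar`
#' pRFs of SD `sigma` on a ring at eccentricity `ecc` and returns their
#' predicted preferred orientation under the supplied orientation maps.
#'
#' @param sim a [simulate_orientation_maps()] result.
#' @param ecc ring eccentricity in degrees.
#' @param n_polar number of equally spaced polar angles.
#' @param sigma pRF SD in degrees.
#' @return data.frame with `polar_deg`, `x0`, `y0`, `preferred_deg`,
#'   `amplitude`.
#' @export
ring_preferences <- function(sim, ecc, n_polar = 16, sigma = 1) {
  ang <- seq(0, 2 * pi, length.out = n_polar + 1)[-(n_polar + 1)]
  out <- lapply(ang, function(a) {
    p <- prf(ecc * cos(a), ecc * sin(a), sigma)
    tp <- predict_prf_tuning(sim, p)
    data.frame(polar_deg = a * 180 / pi, x0 = p$x0, y0 = p$y0,
               preferred_deg = tp$preferred_deg, amplitude = tp$amplitude)
  })
  do.call(rbind, out)
}
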