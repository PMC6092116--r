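# Stimulus synthesis: oriented sinusoidal carriers, raised-cosine
# annulus vignettes, and polar (radial/angular) modulators, composed
# multiplicatively on a calibrated degrees-per-pixel grid.
#
# Conventions (fixed once, used everywhere):
#   * orientation 0 deg = horizontal stripes (luminance varies
#     vertically); angles increase counterclockwise, modulo 180.
#   * x increases rightward with column, y increases upward (i.e.
#     against row index); the fixation center is at `geom$center`.
#   * carrier phase 0 puts a luminance maximum at fixation.

#' Display geometry
#'
#' @param shape `(rows, cols)` in pixels.
#' @param deg_per_pixel degrees of visual angle per pixel (> 0).
#' @param center fixation position `(row, col)`; defaults to the image
#'   center. Must lie inside the image.
#' @return object of class `display_geometry`.
#' @export
display_geometry <- function(shape, deg_per_pixel,
                             center = (shape + 1) / 2) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1))
    stop("shape must be two positive integers")
  if (deg_per_pixel <= 0) stop("deg_per_pixel must be positive")
  if (center[1] < 1 || center[1] > shape[1] ||
      center[2] < 1 || center[2] > shape[2])
    stop("center must lie inside the image")
  structure(list(shape = shape, deg_per_pixel = deg_per_pixel,
                 center = center),
            class = "display_geometry")
}

# x (deg, rightward) and y (deg, upward) coordinate matrices
geometry_xy <- function(geom) {
  rows <- seq_len(geom$shape[1])
  cols <- seq_len(geom$shape[2])
  x <- matrix((cols - geom$center[2]) * geom$deg_per_pixel,
              geom$shape[1], geom$shape[2], byrow = TRUE)
  y <- matrix((geom$center[1] - rows) * geom$deg_per_pixel,
              geom$shape[1], geom$shape[2])
  list(x = x, y = y)
}

#' Carrier grating specification
#'
#' @param orientation_deg stripe orientation in `[0, 180)`; 0 means
#'   horizontal stripes.
#' @param sf_cpd spatial frequency in cycles per degree.
#' @param phase_rad spatial phase in radians (0 = maximum at fixation).
#' @param contrast Michelson contrast in (0, 1].
#' @export
carrier_spec <- function(orientation_deg, sf_cpd, phase_rad = 0,
                         contrast = 1) {
  if (sf_cpd <= 0) stop("sf_cpd must be positive")
  if (contrast <= 0 || contrast > 1) stop("contrast must be in (0, 1]")
  structure(list(orientation_deg = orientation_deg %% 180,
                 sf_cpd = sf_cpd, phase_rad = phase_rad,
                 contrast = contrast),
            class = "carrier_spec")
}

#' Annulus vignette specification
#'
#' Raised-cosine transitions are centered on the nominal inner and
#' outer radii, so the mask equals 0.5 exactly at each edge.
#'
#' @param inner_deg,outer_deg eccentricities in degrees, `0 <= inner < outer`.
#' @param transition_deg total raised-cosine transition width (>= 0).
#' @export
annulus_spec <- function(inner_deg, outer_deg, transition_deg = 1) {
  if (inner_deg < 0 || inner_deg >= outer_deg)
    stop("need 0 <= inner_deg < outer_deg")
  if (transition_deg < 0) stop("transition_deg must be >= 0")
  structure(list(inner_deg = inner_deg, outer_deg = outer_deg,
                 transition_deg = transition_deg),
            class = "annulus_spec")
}

#' Polar modulator specification
#'
#' @param axis `"radial"` (rings) or `"angular"` (wedges).
#' @param waveform `"sine"` (smooth, edge-free) or `"square"`.
#' @param phase `"cosine"` or `"sine"`; the two differ by a
#'   quarter-period shift along the modulation axis.
#' @param frequency cycles/degree along eccentricity (radial, linear),
#'   cycles/octave of eccentricity (radial with `log_scaled = TRUE`), or
#'   integer cycles/revolution (angular; wrap continuity).
#' @param log_scaled radial only: scale ring spacing with eccentricity.
#' @export
modulator_spec <- function(axis = c("radial", "angular"),
                           waveform = c("sine", "square"),
                           phase = c("cosine", "sine"),
                           frequency = NULL, log_scaled = FALSE) {
  axis <- match.arg(axis)
  waveform <- match.arg(waveform)
  phase <- match.arg(phase)
  if (is.null(frequency))
    frequency <- if (axis == "angular") 12 else if (log_scaled) 1 else 0.5
  if (frequency <= 0) stop("modulator frequency must be positive")
  if (axis == "angular" && frequency != round(frequency))
    stop("angular modulator frequency must be a positive integer ",
         "(cycles per revolution) for wrap continuity")
  structure(list(axis = axis, waveform = waveform, phase = phase,
                 frequency = frequency, log_scaled = log_scaled),
            class = "modulator_spec")
}

#' Make an oriented sinusoidal carrier
#'
#' @param geom a [display_geometry()].
#' @param spec a [carrier_spec()].
#' @return signed contrast map in `[-contrast, contrast]`.
#' @export
make_carrier <- function(geom, spec) {
  stopifnot(inherits(geom, "display_geometry"),
            inherits(spec, "carrier_spec"))
  if (spec$sf_cpd * geom$deg_per_pixel >= 0.5)
    stop("carrier spatial frequency ", spec$sf_cpd,
         " cpd is at or above the Nyquist limit for this geometry (",
         signif(0.5 / geom$deg_per_pixel, 4), " cpd)")
  th <- spec$orientation_deg * pi / 180
  xy <- geometry_xy(geom)
  arg <- 2 * pi * spec$sf_cpd * (xy$x * sin(th) - xy$y * cos(th)) +
    spec$phase_rad
  spec$contrast * cos(arg)
}

#' Make a raised-cosine annulus mask
#'
#' @param geom a [display_geometry()].
#' @param spec an [annulus_spec()].
#' @return mask in `[0, 1]`, 1 on the annulus plateau, 0 outside, 0.5
#'   exactly at the nominal edges.
#' @export
make_annulus <- function(geom, spec) {
  stopifnot(inherits(geom, "display_geometry"),
            inherits(spec, "annulus_spec"))
  xy <- geometry_xy(geom)
  r <- sqrt(xy$x^2 + xy$y^2)
  ramp <- function(r, edge, w) {
    if (w == 0) return((r >= edge) * 1)
    t <- (r - (edge - w / 2)) / w
    t <- pmin(pmax(t, 0), 1)
    0.5 * (1 - cos(pi * t))
  }
  up <- ramp(r, spec$inner_deg, spec$transition_deg)
  down <- 1 - ramp(r, spec$outer_deg, spec$transition_deg)
  up * down
}

#' Make a polar modulator
#'
#' Radial modulators are functions of eccentricity only (rings);
#' angular modulators are functions of polar angle only (wedges).
#'
#' @param geom a [display_geometry()].
#' @param spec a [modulator_spec()].
#' @return signed map in `[-1, 1]`; square waveforms take values -1/+1.
#' @export
make_modulator <- function(geom, spec) {
  stopifnot(inherits(geom, "display_geometry"),
            inherits(spec, "modulator_spec"))
  xy <- geometry_xy(geom)
  if (spec$axis == "radial") {
    r <- sqrt(xy$x^2 + xy$y^2)
    if (spec$log_scaled) {
      # 1 deg reference eccentricity; clip below half a pixel to keep
      # log2 finite (the annulus removes the fovea in practice)
      r <- pmax(r, geom$deg_per_pixel / 2)
      arg <- 2 * pi * spec$frequency * log2(r)
    } else {
      arg <- 2 * pi * spec$frequency * r
    }
  } else {
    theta <- atan2(xy$y, xy$x)
    arg <- spec$frequency * theta
  }
  m <- if (spec$phase == "cosine") cos(arg) else sin(arg)
  if (spec$waveform == "square") m <- sign(m) + (m == 0)
  m
}

#' Compose a stimulus image
#'
#' `luminance = mean_lum + 0.5 * carrier * modulator * annulus`, the
#' multiplicative carrier-times-modulator construction restricted to the
#' annulus vignette.
#'
#' @param carrier signed contrast map from [make_carrier()].
#' @param modulator signed map from [make_modulator()], or `1`.
#' @param annulus mask from [make_annulus()], or `1`.
#' @param mean_lum mean luminance in display units (default 0.5).
#' @return luminance matrix in `[0, 1]`.
#' @export
compose_stimulus <- function(carrier, modulator = 1, annulus = 1,
                             mean_lum = 0.5) {
  dims <- lapply(Filter(is.matrix, list(carrier, modulator, annulus)), dim)
  if (length(unique(dims)) > 1L)
    stop("carrier, modulator and annulus must share the same geometry")
  lum <- mean_lum + 0.5 * carrier * modulator * annulus
  if (min(lum) < -1e-12 || max(lum) > 1 + 1e-12)
    stop("luminance out of [0, 1]: check carrier contrast and mean_lum")
  lum[] <- pmin(1, pmax(0, lum))
  lum
}

#' Render the 16-phase stimulus set for one condition
#'
#' The experiments randomized the carrier phase over 16 values uniform
#' in `[0, 2pi)`; model responses are averaged over this set. Energy
#' responses are quadratic in the image, so averaging over any uniform
#' phase set equals averaging over the quadrature pair `{0, pi/2}`; both
#' set sizes are supported.
#'
#' @param geom a [display_geometry()].
#' @param carrier a [carrier_spec()] (its `phase_rad` is ignored).
#' @param modulator optional [modulator_spec()].
#' @param annulus optional [annulus_spec()].
#' @param phases vector of carrier phases in radians.
#' @param mean_lum mean luminance.
#' @return list of luminance matrices, one per phase.
#' @export
stimulus_phase_set <- function(geom, carrier, modulator = NULL,
                               annulus = NULL,
                               phases = seq(0, 2 * pi, length.out = 17)[-17],
                               mean_lum = 0.5) {
  mod_map <- if (is.null(modulator)) 1 else make_modulator(geom, modulator)
  ann_map <- if (is.null(annulus)) 1 else make_annulus(geom, annulus)
  lapply(phases, function(p) {
    spec <- carrier_spec(carrier$orientation_deg, carrier$sf_cpd,
                         phase_rad = p, contrast = carrier$contrast)
    compose_stimulus(make_carrier(geom, spec), mod_map, ann_map, mean_lum)
  })
}
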