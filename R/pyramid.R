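# Frequency-domain steerable pyramid with quadrature pairs: the
# image-computable V1 energy model. All filters are constructed directly
# on the 2D DFT grid with periodic boundary handling; the squared
# amplitudes of all channels plus the two residuals tile frequency space
# exactly (partition of unity), which is what makes "summing across all
# orientation channels" a meaningful orientation-agnostic population
# response.

#' Number of spatial-frequency channels for a pyramid
#'
#' The channel count is determined by the image size and the
#' spatial-frequency bandwidth: scales are spaced `bandwidth` octaves
#' apart downward from the Nyquist frequency, and the count is
#' `floor((floor(log2(min(rows, cols))) - 2) / bandwidth + 1)`.
#' For a 768 x 1024 image at 0.5 octaves this gives 15 channels.
#'
#' @param image_shape integer vector `(rows, cols)` in pixels.
#' @param bandwidth spatial-frequency bandwidth in octaves, in (0, 1].
#'   Bandwidth is the full width at half maximum of the squared radial
#'   transfer function.
#' @return integer number of spatial-frequency channels (>= 1).
#' @export
#' @examples
#' plan_scales(c(768, 1024), 0.5)  # 15
plan_scales <- function(image_shape, bandwidth) {
  if (length(image_shape) != 2L || any(image_shape < 1))
    stop("image_shape must be two positive integers (rows, cols)")
  if (!is.numeric(bandwidth) || bandwidth <= 0 || bandwidth > 1)
    stop("bandwidth must be in (0, 1] octaves")
  m <- min(image_shape)
  if (m < 32)
    stop("image too small: minimum dimension must be at least 32 pixels, got ", m)
  n <- floor((floor(log2(m)) - 2) / bandwidth + 1)
  max(1L, as.integer(n))
}

#' Pyramid configuration
#'
#' @param image_shape `(rows, cols)` in pixels; minimum dimension 32.
#' @param n_orientations number of orientation bands spanning 180
#'   degrees evenly (default 6).
#' @param sf_bandwidth_octaves radial bandwidth in octaves (default 0.5),
#'   measured as FWHM of the squared radial transfer.
#' @return an object of class `pyramid_config` with the derived
#'   `n_scales`.
#' @export
pyramid_config <- function(image_shape, n_orientations = 6L,
                           sf_bandwidth_octaves = 0.5) {
  if (!is.numeric(n_orientations) || n_orientations < 2)
    stop("n_orientations must be at least 2")
  n_scales <- plan_scales(image_shape, sf_bandwidth_octaves)
  structure(list(
    image_shape = as.integer(image_shape),
    n_orientations = as.integer(n_orientations),
    sf_bandwidth_octaves = sf_bandwidth_octaves,
    n_scales = n_scales
  ), class = "pyramid_config")
}

#' @export
print.pyramid_config <- function(x, ...) {
  cat(sprintf(
    "pyramid_config: %d x %d px, %d orientations, %.2f-octave bands, %d scales\n",
    x$image_shape[1], x$image_shape[2], x$n_orientations,
    x$sf_bandwidth_octaves, x$n_scales))
  invisible(x)
}

# DFT frequency grid for an image of the given shape.
# r: radial frequency in cycles/pixel; alpha: frequency-plane polar
# angle under the package's spatial convention (x rightward, y upward;
# row frequency enters with a minus sign).
fourier_grid <- function(shape) {
  fr <- seq_len(shape[1]) - 1L
  fr[fr > shape[1] / 2] <- fr[fr > shape[1] / 2] - shape[1]
  fc <- seq_len(shape[2]) - 1L
  fc[fc > shape[2] / 2] <- fc[fc > shape[2] / 2] - shape[2]
  fr <- fr / shape[1]
  fc <- fc / shape[2]
  FR <- matrix(fr, shape[1], shape[2])
  FC <- matrix(fc, shape[1], shape[2], byrow = TRUE)
  list(r = sqrt(FR^2 + FC^2), alpha = atan2(-FR, FC))
}

#' Build the steerable-pyramid filter bank
#'
#' Radial profiles are raised cosines in log2 frequency with FWHM (of
#' the squared profile) equal to the configured bandwidth, centered
#' `bandwidth` octaves apart downward from Nyquist. Angular profiles are
#' the standard `cos^(K-1)` windows for K orientation bands, normalized
#' so that the squared amplitudes of all channels (both quadrature
#' phases) and the two residuals sum to one at every frequency sample.
#'
#' @param config a [pyramid_config()].
#' @return an object of class `filter_bank` holding, per scale, the
#'   radial amplitude map, per orientation the angular amplitude map and
#'   analytic half-plane mask, the high/low residual amplitude maps, and
#'   `peak_frequency` (cycles/pixel) per scale. The amplitude of channel
#'   (s, k) for either quadrature phase is `radial[[s]] * angular[[k]]`.
#' @export
build_filter_bank <- function(config) {
  stopifnot(inherits(config, "pyramid_config"))
  shape <- config$image_shape
  b <- config$sf_bandwidth_octaves
  K <- config$n_orientations
  n_scales <- config$n_scales
  g <- fourier_grid(shape)
  x <- suppressWarnings(log2(g$r))          # -Inf at DC, handled below
  centers <- -1 - b * (seq_len(n_scales) - 1)

  radial <- vector("list", n_scales)
  total_sq <- matrix(0, shape[1], shape[2])
  for (s in seq_len(n_scales)) {
    u <- (x - centers[s]) / b
    a <- matrix(0, shape[1], shape[2])
    idx <- is.finite(u) & abs(u) < 1
    a[idx] <- cos(pi / 2 * u[idx])
    radial[[s]] <- a
    total_sq <- total_sq + a^2
  }
  deficit <- pmax(0, 1 - total_sq)
  hi <- sqrt(deficit * (x > centers[1]))
  lo <- sqrt(deficit * (x < centers[n_scales]))
  lo[g$r == 0] <- 1

  # cos^(K-1) angular windows; the constant-sum identity makes
  # sum_k 2 * g_k^2 == 1 exactly for any K >= 2
  Cnorm <- K * choose(2 * K - 2, K - 1) / 4^(K - 1)
  theta_k <- (seq_len(K) - 1) * pi / K       # preferred grating orientation
  alpha_k <- theta_k - pi / 2                # frequency-plane angle
  angular <- vector("list", K)
  halfplane <- vector("list", K)
  for (k in seq_len(K)) {
    ca <- cos(g$alpha - alpha_k[k])
    angular[[k]] <- abs(ca)^(K - 1) / sqrt(2 * Cnorm)
    halfplane[[k]] <- ca > 0
  }

  # Bins on a Nyquist row/column are their own conjugate mirror: the
  # analytic half-plane split is undefined there, so the quadrature
  # realization weights them sqrt(2) instead of 2 x half-plane (keeps
  # energy conservation exact; see decompose()).
  fr <- seq_len(shape[1]) - 1L
  fr[fr > shape[1] / 2] <- fr[fr > shape[1] / 2] - shape[1]
  fc <- seq_len(shape[2]) - 1L
  fc[fc > shape[2] / 2] <- fc[fc > shape[2] / 2] - shape[2]
  nyq <- outer(abs(fr / shape[1]) == 0.5, rep(TRUE, shape[2])) |
    outer(rep(TRUE, shape[1]), abs(fc / shape[2]) == 0.5)

  structure(list(
    config = config,
    radial = radial,
    angular = angular,
    halfplane = halfplane,
    nyquist_mask = nyq,
    residual_high = hi,
    residual_low = lo,
    peak_frequency = 2^centers,
    centers_log2 = centers,
    orientations_deg = theta_k * 180 / pi
  ), class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  print(x$config)
  cat(sprintf("  peak frequencies: %s cycles/pixel\n",
              paste(signif(x$peak_frequency, 3), collapse = ", ")))
  invisible(x)
}

#' Amplitude map of one channel
#'
#' Both quadrature phases of a channel share this amplitude.
#'
#' @param bank a [build_filter_bank()] result.
#' @param scale,orientation channel indices.
#' @return a nonnegative amplitude map over the frequency grid.
#' @export
channel_amplitude <- function(bank, scale, orientation) {
  stopifnot(inherits(bank, "filter_bank"))
  bank$radial[[scale]] * bank$angular[[orientation]]
}

#' Tiling error of a filter bank
#'
#' Maximum over frequency samples of the absolute deviation of the sum
#' of squared channel amplitudes (both quadrature phases of every scale
#' x orientation channel, plus the two residuals) from one.
#'
#' @param bank a `filter_bank`.
#' @return a nonnegative scalar; <= 1e-6 for every built bank.
#' @export
tiling_error <- function(bank) {
  stopifnot(inherits(bank, "filter_bank"))
  total <- bank$residual_high^2 + bank$residual_low^2
  for (s in seq_along(bank$radial)) {
    for (k in seq_along(bank$angular)) {
      a <- bank$radial[[s]] * bank$angular[[k]]
      total <- total + 2 * a^2   # odd + even share the amplitude
    }
  }
  max(abs(total - 1))
}

#' Decompose an image into pyramid coefficients
#'
#' Linear decomposition: each channel computes a weighted sum of the
#' image. Coefficient maps are returned at full input resolution (no
#' downsampling). Even- and odd-phase members of each quadrature pair
#' are the real and imaginary parts of the analytic (half-plane) band.
#'
#' @param image a numeric matrix matching the bank's frequency grid.
#' @param bank a `filter_bank`.
#' @return an object of class `pyramid_coefficients`: a list of
#'   channels, each with `scale`, `orientation`, `even`, `odd`, plus
#'   `residual_high`/`residual_low` coefficient maps.
#' @export
decompose <- function(image, bank) {
  stopifnot(inherits(bank, "filter_bank"))
  if (!is.matrix(image) || !all(dim(image) == bank$config$image_shape))
    stop("image dimensions (", paste(dim(image), collapse = " x "),
         ") do not match the bank's frequency grid (",
         paste(bank$config$image_shape, collapse = " x "), ")")
  Fim <- stats::fft(image)
  N <- length(Fim)
  channels <- list()
  i <- 0L
  for (s in seq_along(bank$radial)) {
    for (k in seq_along(bank$angular)) {
      B <- analytic_transfer(bank, s, k)
      cc <- stats::fft(Fim * B, inverse = TRUE) / N
      i <- i + 1L
      channels[[i]] <- list(scale = s, orientation = k,
                            even = Re(cc), odd = Im(cc))
    }
  }
  rh <- Re(stats::fft(Fim * bank$residual_high, inverse = TRUE) / N)
  rl <- Re(stats::fft(Fim * bank$residual_low, inverse = TRUE) / N)
  structure(list(channels = channels, residual_high = rh, residual_low = rl,
                 config = bank$config),
            class = "pyramid_coefficients")
}

#' Channel energy
#'
#' The energy of a channel is the pixelwise sum of squares of its odd-
#' and even-phase coefficients: a phase-invariant measure of local
#' spectral power at that orientation and spatial frequency.
#'
#' @param coefficients a [decompose()] result.
#' @return object of class `channel_energy`: list of channels each with
#'   `scale`, `orientation` and a nonnegative `energy` map.
#' @export
channel_energy <- function(coefficients) {
  stopifnot(inherits(coefficients, "pyramid_coefficients"))
  out <- lapply(coefficients$channels, function(ch) {
    if (is.null(ch$even) || is.null(ch$odd))
      stop("channel (scale ", ch$scale, ", orientation ", ch$orientation,
           ") is missing a quadrature phase member")
    list(scale = ch$scale, orientation = ch$orientation,
         energy = ch$even^2 + ch$odd^2)
  })
  structure(list(channels = out, config = coefficients$config),
            class = "channel_energy")
}

# --- internal fast paths used by the simulation module ----------------

# Frequency response of the analytic (complex) band whose real and
# imaginary parts are the even/odd quadrature pair.
analytic_transfer <- function(bank, s, k) {
  a <- bank$radial[[s]] * bank$angular[[k]]
  B <- 2 * a * bank$halfplane[[k]]
  B[bank$nyquist_mask] <- sqrt(2) * a[bank$nyquist_mask]
  B
}

# Per-scale orientation-summed energy maps of one image, as a list of
# matrices, plus the residual energies. Equivalent to
# channel_energy(decompose(...)) summed over orientations, but without
# materializing every coefficient map.
scale_energy_maps <- function(image, bank) {
  Fim <- stats::fft(image)
  N <- length(Fim)
  maps <- vector("list", length(bank$radial))
  for (s in seq_along(bank$radial)) {
    acc <- 0
    for (k in seq_along(bank$angular)) {
      B <- analytic_transfer(bank, s, k)
      cc <- stats::fft(Fim * B, inverse = TRUE) / N
      acc <- acc + Re(cc)^2 + Im(cc)^2
    }
    maps[[s]] <- acc
  }
  maps
}
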