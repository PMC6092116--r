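# Steerable-pyramid model: scale planning, tiling, decomposition,
# energy.

test_that("plan_scales follows the octave-spacing rule", {
  expect_identical(plan_scales(c(768, 1024), 0.5), 15L)
  expect_identical(plan_scales(c(768, 1024), 1.0), 8L)
  expect_identical(plan_scales(c(64, 64), 0.5), 9L)
  expect_error(plan_scales(c(8, 8), 0.5), "32")
  expect_error(plan_scales(c(64, 64), 1.5), "octaves")
})

test_that("bank structure matches the configuration", {
  bank <- fx_bank(64)
  expect_s3_class(bank, "filter_bank")
  expect_length(bank$radial, 9)
  expect_length(bank$angular, 6)
  expect_length(bank$peak_frequency, 9)
  # each channel has two quadrature members in a decomposition
  co <- decompose(matrix(rnorm(64 * 64), 64, 64), bank)
  expect_length(co$channels, 9 * 6)
  for (ch in co$channels[c(1, 25, 54)]) {
    expect_true(is.matrix(ch$even) && is.matrix(ch$odd))
  }
  expect_error(pyramid_config(c(64, 64), n_orientations = 1), "at least 2")
})

test_that("squared tuning curves tile frequency space", {
  expect_lt(tiling_error(fx_bank(64)), 1e-6)
  # non-square and alternate orientation counts
  b2 <- build_filter_bank(pyramid_config(c(48, 96), n_orientations = 4))
  expect_lt(tiling_error(b2), 1e-6)
  b3 <- build_filter_bank(pyramid_config(c(64, 64), n_orientations = 8,
                                         sf_bandwidth_octaves = 1))
  expect_lt(tiling_error(b3), 1e-6)
})

test_that("tiling error detects a removed channel and the degenerate bank", {
  bank <- fx_bank(64)
  # drop orientation band 2 (both quadrature phases, all scales) and
  # compare against an oracle: the peak total squared amplitude of the
  # removed channels
  mutbank <- bank
  mutbank$angular[[2]] <- bank$angular[[2]] * 0
  removed <- Reduce(`+`, lapply(seq_along(bank$radial), function(s)
    2 * channel_amplitude(bank, s, 2)^2))
  err <- tiling_error(mutbank)
  expect_gt(err, 0.1)
  expect_equal(err, max(removed), tolerance = 1e-12)

  degenerate <- structure(list(
    config = bank$config,
    radial = list(matrix(1, 4, 4)),
    angular = list(matrix(sqrt(0.5), 4, 4)),
    residual_high = matrix(0, 4, 4),
    residual_low = matrix(0, 4, 4)), class = "filter_bank")
  expect_equal(tiling_error(degenerate), 0)
})

test_that("decomposition is linear and shape-checked", {
  bank <- fx_bank(64)
  zero <- decompose(matrix(0, 64, 64), bank)
  expect_true(all(vapply(zero$channels, function(ch)
    max(abs(ch$even), abs(ch$odd)) == 0, logical(1))))
  set.seed(42)
  im <- matrix(rnorm(64 * 64), 64, 64)
  c1 <- decompose(im, bank)
  c3 <- decompose(3 * im, bank)
  for (i in c(2, 17, 50)) {
    expect_equal(c3$channels[[i]]$even, 3 * c1$channels[[i]]$even,
                 tolerance = 1e-12)
    expect_equal(c3$channels[[i]]$odd, 3 * c1$channels[[i]]$odd,
                 tolerance = 1e-12)
  }
  expect_error(decompose(matrix(0, 32, 64), bank), "do not match")
})

test_that("a grating at a channel's peak drives that channel hardest", {
  bank <- fx_bank(64)
  geom <- display_geometry(c(64, 64), 1)   # 1 deg/px: cpd == cycles/px
  for (probe in list(c(4, 3), c(6, 1), c(3, 5))) {
    carr <- make_carrier(geom, carrier_spec(
      bank$orientations_deg[probe[2]], bank$peak_frequency[probe[1]]))
    en <- channel_energy(decompose(carr, bank))
    means <- vapply(en$channels, function(ch) mean(ch$energy), numeric(1))
    best <- en$channels[[which.max(means)]]
    expect_identical(c(best$scale, best$orientation), as.integer(probe))
  }
})

test_that("channel energy is a nonnegative quadrature sum", {
  bank <- fx_bank(64)
  zero <- channel_energy(decompose(matrix(0, 64, 64), bank))
  expect_true(all(vapply(zero$channels, function(ch) max(ch$energy) == 0,
                         logical(1))))
  set.seed(7)
  en <- channel_energy(decompose(matrix(rnorm(64^2), 64, 64), bank))
  expect_true(all(vapply(en$channels, function(ch) min(ch$energy) >= 0,
                         logical(1))))
  broken <- decompose(matrix(0, 64, 64), bank)
  broken$channels[[5]]$odd <- NULL
  expect_error(channel_energy(broken), "quadrature phase")
})

test_that("energy conserves total spectral power (Parseval)", {
  bank <- fx_bank(64)
  set.seed(11)
  for (i in 1:3) {
    im <- matrix(rnorm(64 * 64), 64, 64)
    co <- decompose(im, bank)
    en <- channel_energy(co)
    total <- sum(vapply(en$channels, function(ch) sum(ch$energy),
                        numeric(1))) +
      sum(co$residual_high^2) + sum(co$residual_low^2)
    expect_equal(total, sum(im^2), tolerance = 1e-6)
  }
})

test_that("energy of a full-field grating is phase invariant and uniform", {
  n <- 192
  bank <- fx_bank(n)
  geom <- display_geometry(c(n, n), 0.25)
  mar <- ceiling(0.1 * n)
  idx <- (mar + 1):(n - mar)
  phases <- seq(0, 2 * pi, length.out = 17)[-17]
  maps <- lapply(phases, function(p)
    simulate_voxel_map(compose_stimulus(
      make_carrier(geom, carrier_spec(30, 0.7, p))), bank, scale = NULL))
  ref <- unclass(maps[[1]])[idx, idx]
  for (m in maps[-1]) {
    dev <- max(abs(unclass(m)[idx, idx] - ref)) / mean(ref)
    expect_lt(dev, 0.01)
  }
  avg <- simulate_voxel_map(lapply(c(0, pi / 2), function(p)
    compose_stimulus(make_carrier(geom, carrier_spec(30, 0.7, p)))), bank)
  inner <- unclass(avg)[idx, idx]
  expect_lt((max(inner) - min(inner)) / mean(inner), 0.02)
})

test_that("orientation channels are quasi-equivariant under 30 deg rotation", {
  n <- 96
  bank <- fx_bank(n)
  geom <- display_geometry(c(n, n), 20 / n)
  ann <- annulus_spec(3, 7, 1)   # rotation-symmetric vignette
  avg_energy <- function(theta) {
    stim <- compose_stimulus(make_carrier(geom, carrier_spec(theta, 1.0)),
                             1, make_annulus(geom, ann))
    en <- channel_energy(decompose(stim, bank))
    s_best <- en$channels[[which.max(vapply(en$channels, function(ch)
      sum(ch$energy), numeric(1)))]]$scale
    vapply(seq_along(bank$angular), function(k) {
      sum(Reduce(`+`, lapply(Filter(function(ch)
        ch$scale == s_best && ch$orientation == k, en$channels),
        `[[`, "energy")))
    }, numeric(1))
  }
  e15 <- avg_energy(15)
  e45 <- avg_energy(45)            # rotated by one channel spacing
  shifted <- e15[c(6, 1:5)]        # cyclic permutation by one band
  expect_lt(max(abs(e45 - shifted)) / max(e15), 0.02)
})
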