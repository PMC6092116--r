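# MVPA suite: population responses, diagonal-Gaussian decoding,
# permutation tests, RSA and MDS.

test_that("cycle averaging folds the run into 16 labelled responses", {
  truth <- fx_truth()
  run <- preprocess_run(generate_run(run_design("radial", "ccw"), truth,
                                     noise_model(seed = 3)))
  pr <- cycle_average(run)
  expect_equal(dim(pr$matrix), c(16, truth$n_voxels))
  expect_equal(pr$labels, (0:15) * 11.25)
  expect_identical(pr$modulator, "radial")

  # noiseless periodic series: rows equal any single cycle exactly
  clean <- preprocess_run(generate_run(run_design("radial", "ccw"), truth,
                                       fx_noiseless()))
  pc <- cycle_average(clean)
  expect_equal(pc$matrix, t(clean$values[, 1:16]), tolerance = 1e-12)

  # white noise: cycle averaging divides variance by the cycle count
  set.seed(31)
  wn <- run_timeseries(matrix(rnorm(40 * 160), 40, 160),
                       run_design("radial", "ccw"), preprocessed = TRUE)
  pw <- cycle_average(wn)
  expect_equal(mean(apply(pw$matrix, 2, var)) /
                 mean(apply(wn$values, 1, var)), 1 / 10, tolerance = 0.25)

  bad <- run_timeseries(matrix(0, 4, 150), run_design("radial", "ccw"),
                        preprocessed = TRUE)
  expect_error(cycle_average(bad), "non-integer")
  expect_error(cycle_average(generate_run(run_design("radial", "ccw"),
                                          truth, fx_noiseless())),
               "preprocessed")
})

test_that("decoder predictions match the brute-force Gaussian posterior oracle", {
  set.seed(99)
  for (rep in 1:20) {
    K <- sample(2:5, 1)
    V <- sample(2:5, 1)
    n_train <- K * sample(3:5, 1)
    y <- rep(seq_len(K), length.out = n_train)
    X <- matrix(rnorm(n_train * V, mean = y), n_train, V)
    Xt <- matrix(rnorm(3 * K * V, mean = rep(seq_len(K), 3)), 3 * K, V)
    model <- vignetta:::nb_train(X, y, K)
    expect_identical(as.integer(vignetta:::nb_predict(model, Xt)),
                     as.integer(oracle_diag_gaussian(X, y, Xt, K)))
  }
})

test_that("within-modulator decoding is perfect without noise and at chance after label shuffling", {
  truth <- fx_truth()
  sess <- generate_session(session_design(), truth, fx_noiseless())
  responses <- session_responses(sess)
  expect_equal(decode_within(responses), 1.0)
  expect_error(decode_within(responses[1]), "at least 2")

  # destroying the label structure drives accuracy to chance
  set.seed(17)
  accs <- replicate(100, {
    shuffled <- lapply(responses[1:4], function(r) {
      r$matrix <- r$matrix[sample(16), ]
      r
    })
    decode_within(shuffled)
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 1 / 16), 3 * se + 1e-12)
})

test_that("across-modulator decoding obeys the label-shift algebra", {
  truth <- fx_truth()
  sess <- generate_session(session_design(), truth,
                           noise_model(white_sd = 2, seed = 23))
  responses <- session_responses(sess)
  rad <- Filter(function(r) r$modulator == "radial", responses)
  ang <- Filter(function(r) r$modulator == "angular", responses)
  # shifting by 90 twice is the identity labelling
  expect_equal(decode_across(rad, ang, 0), decode_across(rad, ang, 180))
  expect_error(decode_across(rad, ang, 37), "multiple")
})

test_that("phase randomization preserves amplitude spectra and kills structure", {
  truth <- fx_truth()
  run <- generate_run(run_design("radial", "ccw"), truth,
                      noise_model(white_sd = 1, seed = 4))
  set.seed(5)
  surr <- phase_randomize(run$values)
  for (v in c(1, 20, 48)) {
    expect_equal(Mod(fft(surr[v, ])), Mod(fft(run$values[v, ])),
                 tolerance = 1e-9)
    expect_gt(max(abs(surr[v, ] - run$values[v, ])), 0)
  }
  expect_false(any(abs(Im(surr)) > 0))   # surrogates are real

  # permuted within-modulator accuracy sits at chance
  null_sess <- fx_null_session(seed = 2)
  statistic <- function(s) decode_within(session_responses(s))
  pt <- permutation_test(null_sess, statistic, n_perm = 60, seed = 8)
  se <- sd(pt$null) / sqrt(length(pt$null))
  expect_lt(abs(mean(pt$null) - 1 / 16), 3 * se + 0.01)
  expect_error(permutation_test(null_sess, statistic, n_perm = 0), "n_perm")
  pp_sess <- list(runs = lapply(null_sess$runs, preprocess_run))
  expect_error(permutation_test(pp_sess, statistic, 10), "raw")
})

test_that("dissimilarity matrices are well-formed correlation distances", {
  truth <- fx_truth()
  sess <- generate_session(session_design(), truth,
                           noise_model(white_sd = 2, seed = 29))
  cm <- condition_means(session_responses(sess))
  expect_equal(dim(cm), c(32, truth$n_voxels))
  D <- dissimilarity_matrix(cm)
  expect_equal(D, t(D))
  expect_equal(max(abs(diag(D))), 0)
  expect_true(all(D >= 0 & D <= 2))
  v <- rbind(cm[1, ], -cm[1, ])
  expect_equal(dissimilarity_matrix(v)[1, 2], 2, tolerance = 1e-12)
  flat <- rbind(rep(1, 8), rnorm(8))
  expect_error(dissimilarity_matrix(flat), "zero-variance")
})

test_that("MDS reproduces exact configurations and ring geometry", {
  # metric 4-point configuration: distances recovered to 1e-6
  set.seed(41)
  P <- matrix(rnorm(8), 4, 2)
  D <- as.matrix(dist(P))
  emb <- mds_embed(D, 2, seed = 1, n_restarts = 3)
  expect_equal(as.matrix(dist(emb)), D, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(mds_embed(matrix(runif(16), 4, 4)), "symmetric")

  # shifted-cosine similarity over 16 conditions embeds as an ordered ring
  th <- 2 * pi * (0:15) / 16
  D16 <- 1 - cos(outer(th, th, `-`))
  e16 <- mds_embed(D16, 2, seed = 2, n_restarts = 5)
  ang <- atan2(e16[, 2], e16[, 1])
  ranks <- order(ang)
  start <- which(ranks == 1)
  seq_fwd <- ranks[((start + 0:15 - 1) %% 16) + 1]
  seq_rev <- ranks[((start - 0:15 - 1) %% 16) + 1]
  expect_true(identical(seq_fwd, 1:16) || identical(seq_rev, 1:16))
})

test_that("rotating angular labels by 90 deg aligns the two MDS rings", {
  truth <- fx_truth()
  sess <- generate_session(session_design(), truth,
                           noise_model(white_sd = 2, seed = 37))
  cm <- condition_means(session_responses(sess))
  D <- dissimilarity_matrix(cm)
  emb <- mds_embed(D, 2, seed = 3, n_restarts = 5)
  pair_dist <- function(shift) {
    idx_r <- 1:16
    idx_a <- 16 + ((0:15 + shift) %% 16) + 1
    mean(sqrt(rowSums((emb[idx_r, ] - emb[idx_a, ])^2)))
  }
  expect_lt(pair_dist(8), pair_dist(0))   # 8 steps = 90 deg
})
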