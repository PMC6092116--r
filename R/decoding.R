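# MVPA suite: cycle-averaged population responses, diagonal-Gaussian
# ("diagLinear") decoding within and across modulators with optional
# 90-degree label shifting, Fourier phase-randomization permutation
# tests, and representational similarity analysis with metric MDS.

#' Cycle-average a preprocessed run into population responses
#'
#' Averages the retained cycles within a run, yielding one response per
#' orientation step per voxel. Row i is labelled with the i-th
#' orientation of the ccw sequence (preprocessing normalizes direction
#' and alignment).
#'
#' @param run a preprocessed [run_timeseries()].
#' @return object of class `population_response`: `matrix` (16
#'   orientations x voxels, percent signal), `labels` (degrees),
#'   `modulator`.
#' @export
cycle_average <- function(run) {
  stopifnot(inherits(run, "run_timeseries"))
  if (!run$preprocessed)
    stop("cycle_average expects a preprocessed run")
  K <- run$design$n_orientations
  Tn <- ncol(run$values)
  if (Tn %% K != 0)
    stop("non-integer cycle count: ", Tn, " volumes for ", K, " steps")
  n_cyc <- Tn %/% K
  V <- nrow(run$values)
  m <- matrix(0, K, V)
  for (v in seq_len(V))
    m[, v] <- rowMeans(matrix(run$values[v, ], nrow = K))
  structure(list(matrix = m, labels = orientation_labels(run$design),
                 modulator = run$design$modulator_axis,
                 n_cycles = n_cyc),
            class = "population_response")
}

# ---- diagonal-Gaussian (diagLinear) classifier ----------------------

# Train: per-class feature means plus a single pooled per-feature
# variance (shared diagonal covariance -> linear boundaries), equal
# priors, variance floored at 1e-12.
nb_train <- function(X, y, n_classes) {
  V <- ncol(X)
  means <- matrix(0, n_classes, V)
  ss <- numeric(V)
  for (k in seq_len(n_classes)) {
    rows <- which(y == k)
    mk <- colMeans(X[rows, , drop = FALSE])
    means[k, ] <- mk
    ss <- ss + colSums((X[rows, , drop = FALSE] -
                          rep(mk, each = length(rows)))^2)
  }
  pooled <- ss / max(1, nrow(X) - n_classes)
  pooled <- pmax(pooled, 1e-12)
  list(means = means, var = pooled, n_classes = n_classes)
}

# Predict: max class-conditional Gaussian log-likelihood; ties go to
# the lowest class index (which.max's convention).
nb_predict <- function(model, X) {
  iv <- 1 / model$var
  scores <- -0.5 * (outer(rowSums(X^2 * rep(iv, each = nrow(X))),
                          rep(1, model$n_classes)) -
                      2 * X %*% t(model$means * rep(iv, each = model$n_classes)) +
                      outer(rep(1, nrow(X)),
                            rowSums(model$means^2 * rep(iv, each = model$n_classes))))
  apply(scores, 1, which.max)
}

#' Within-modulator leave-one-run-out decoding
#'
#' Trains the diagonal-Gaussian classifier on all but one run and
#' tests on the held-out run, cycling through folds; when both
#' modulators are present the two within-modulator accuracies are
#' averaged.
#'
#' @param responses list of [cycle_average()] results.
#' @return mean decoding accuracy in `[0, 1]`.
#' @export
decode_within <- function(responses) {
  axes <- unique(vapply(responses, `[[`, character(1), "modulator"))
  accs <- vapply(axes, function(ax) {
    rs <- Filter(function(r) r$modulator == ax, responses)
    if (length(rs) < 2)
      stop("within-modulator decoding needs at least 2 runs (", ax, ")")
    K <- nrow(rs[[1]]$matrix)
    fold_acc <- vapply(seq_along(rs), function(i) {
      train <- rs[-i]
      X <- do.call(rbind, lapply(train, function(r) r$matrix))
      y <- rep(seq_len(K), length(train))
      model <- nb_train(X, y, K)
      pred <- nb_predict(model, rs[[i]]$matrix)
      mean(pred == seq_len(K))
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))
  mean(accs)
}

#' Across-modulator decoding with optional label shift
#'
#' Trains on all runs of one modulator and tests on all runs of the
#' other, averaging both directions. `label_shift_deg` rotates the
#' test-set orientation labels before scoring (90 deg = 8 of 16
#' positions), the paper-style probe for a 90-degree representational
#' flip.
#'
#' @param responses_a,responses_b lists of [cycle_average()] results
#'   for the two modulators.
#' @param label_shift_deg label rotation in degrees; must be a multiple
#'   of the orientation step.
#' @return mean accuracy over both train/test directions.
#' @export
decode_across <- function(responses_a, responses_b, label_shift_deg = 0) {
  K <- nrow(responses_a[[1]]$matrix)
  step <- 180 / K
  if (abs(label_shift_deg / step - round(label_shift_deg / step)) > 1e-9)
    stop("label_shift_deg must be a multiple of the orientation step (",
         step, " deg)")
  shift <- as.integer(round(label_shift_deg / step))
  one_dir <- function(train_rs, test_rs) {
    X <- do.call(rbind, lapply(train_rs, function(r) r$matrix))
    y <- rep(seq_len(K), length(train_rs))
    model <- nb_train(X, y, K)
    accs <- vapply(test_rs, function(r) {
      pred <- nb_predict(model, r$matrix)
      truth <- ((seq_len(K) - 1 + shift) %% K) + 1
      mean(pred == truth)
    }, numeric(1))
    mean(accs)
  }
  mean(c(one_dir(responses_a, responses_b),
         one_dir(responses_b, responses_a)))
}

#' Fourier phase-randomization permutation test
#'
#' Each permutation randomizes the Fourier phases of every voxel's raw
#' time course independently (preserving the amplitude spectrum and
#' conjugate symmetry, so surrogates are real), reruns the full
#' preprocessing plus the supplied statistic, and compares against the
#' observed statistic. The p value is the fraction of permutations with
#' statistic >= observed.
#'
#' @param session a session of raw runs.
#' @param statistic function(session) -> scalar; must do its own
#'   preprocessing (e.g. preprocess + cycle-average + decode).
#' @param n_perm number of permutations (>= 1); 1000 is a desk-scale
#'   default, 10000 the full-scale count.
#' @param seed RNG seed.
#' @return list with `p`, `observed`, `null` (the permutation
#'   distribution).
#' @export
permutation_test <- function(session, statistic, n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (any(vapply(session$runs, `[[`, logical(1), "preprocessed")))
    stop("permutation_test needs raw (pre-preprocessing) runs")
  observed <- statistic(session)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    perm <- session
    perm$runs <- lapply(session$runs, function(r) {
      r$values <- phase_randomize(r$values)
      r
    })
    statistic(perm)
  }, numeric(1)))
  list(p = mean(null >= observed), observed = observed, null = null)
}

#' Phase-randomize time series rows
#'
#' Randomizes Fourier phases at all nonzero, non-Nyquist frequencies
#' independently per row, preserving each row's amplitude spectrum
#' exactly; output is real.
#'
#' @param values voxels x volumes matrix.
#' @return surrogate matrix of the same size.
#' @export
phase_randomize <- function(values) {
  Tn <- ncol(values)
  half <- seq(2, ceiling((Tn + 1) / 2))
  has_nyq <- Tn %% 2 == 0
  if (has_nyq) half <- half[half != Tn / 2 + 1]
  out <- values
  for (v in seq_len(nrow(values))) {
    Fv <- stats::fft(values[v, ])
    ph <- stats::runif(length(half), 0, 2 * pi)
    Fv[half] <- Mod(Fv[half]) * exp(1i * ph)
    Fv[Tn + 2 - half] <- Conj(Fv[half])
    out[v, ] <- Re(stats::fft(Fv, inverse = TRUE) / Tn)
  }
  out
}

#' Condition-mean population responses
#'
#' Averages cycle-averaged responses across runs within each
#' (modulator, orientation) condition: the 32 x V matrix underlying the
#' dissimilarity analysis.
#'
#' @param responses list of [cycle_average()] results (both modulators).
#' @return matrix `(2 * K) x V` with rownames `axis_label`.
#' @export
condition_means <- function(responses) {
  axes <- unique(vapply(responses, `[[`, character(1), "modulator"))
  out <- list()
  for (ax in axes) {
    rs <- Filter(function(r) r$modulator == ax, responses)
    m <- Reduce(`+`, lapply(rs, `[[`, "matrix")) / length(rs)
    rownames(m) <- paste0(ax, "_", rs[[1]]$labels)
    out[[ax]] <- m
  }
  do.call(rbind, out)
}

#' Correlation-distance dissimilarity matrix
#'
#' Entry (i, j) is `1 - r` where `r` is the Pearson correlation between
#' the condition-mean response vectors: symmetric, zero diagonal,
#' entries in `[0, 2]`.
#'
#' @param conditions conditions x voxels matrix (e.g.
#'   [condition_means()]).
#' @return `dissimilarity_matrix` (a plain matrix).
#' @export
dissimilarity_matrix <- function(conditions) {
  if (nrow(conditions) < 2) stop("need at least 2 conditions")
  vars <- apply(conditions, 1, stats::sd)
  if (any(vars == 0))
    stop("zero-variance condition vector(s): ",
         paste(which(vars == 0), collapse = ", "))
  D <- 1 - stats::cor(t(conditions))
  diag(D) <- 0
  D
}

#' Metric MDS by stress majorization
#'
#' Deterministic-seeded SMACOF with restarts: the first start is the
#' classical (Torgerson) solution, the rest are random; the
#' configuration with minimal raw stress is returned.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @param dim embedding dimension (default 2).
#' @param seed RNG seed for the random restarts.
#' @param n_restarts number of starts (default 10).
#' @param max_iter,tol majorization iteration controls.
#' @return `n x dim` coordinate matrix with attribute `stress` (raw
#'   stress, `sum((dist - delta)^2)`).
#' @export
mds_embed <- function(d, dim = 2, seed = 1, n_restarts = 10,
                      max_iter = 300, tol = 1e-10) {
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("dissimilarity matrix must be symmetric")
  n <- nrow(d)
  delta <- as.matrix(d)
  smacof <- function(X) {
    prev <- Inf
    for (it in seq_len(max_iter)) {
      Dx <- as.matrix(stats::dist(X))
      stress <- sum((Dx - delta)^2) / 2
      if (prev - stress < tol * (1 + stress)) break
      prev <- stress
      ratio <- ifelse(Dx > 0, delta / Dx, 0)
      B <- -ratio
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      X <- B %*% X / n
    }
    Dx <- as.matrix(stats::dist(X))
    attr(X, "stress") <- sum((Dx - delta)^2) / 2
    X
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      X0 <- if (r == 1) {
        cm <- stats::cmdscale(delta, k = dim)
        if (ncol(cm) < dim)
          cm <- cbind(cm, matrix(0, n, dim - ncol(cm)))
        cm
      } else {
        matrix(stats::rnorm(n * dim, sd = stats::sd(delta)), n, dim)
      }
      sol <- smacof(X0)
      if (is.null(best) || attr(sol, "stress") < attr(best, "stress"))
        best <- sol
    }
  })
  best
}
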