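# Orchestration and I/O: a single serializable configuration, the
# end-to-end pipeline (stimuli -> model -> synthetic session ->
# analysis -> decoding/RSA -> figures), and plain-text session
# import/export (CSV matrices + JSON design sidecar).

#' Experiment configuration
#'
#' One block per stage; all defaults are the 3T ("nyu") printed
#' parameters, `preset = "nih"` switches to the 7T variant (1.4 cpd
#' carrier, 0.75-9 deg annulus, eccentricity-scaled sinusoidal rings).
#' Fully JSON-serializable; re-running with the same config and seed
#' reproduces all outputs.
#'
#' @param preset `"nyu"` or `"nih"`.
#' @param ... named overrides of top-level blocks (lists are merged).
#' @return object of class `vignetta_config`.
#' @export
vignetta_config <- function(preset = c("nyu", "nih"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    seed = 1L,
    geometry = list(resolution = 128L, fov_deg = 20),
    pyramid = list(n_orientations = 6L, sf_bandwidth_octaves = 0.5),
    stimulus = list(
      carrier_sf_cpd = 0.5,
      annulus = list(inner_deg = 0.5, outer_deg = 9.5, transition_deg = 1),
      modulator_waveform = "square",
      radial_frequency = 0.5, radial_log_scaled = FALSE,
      angular_frequency = 12L),
    prf_grid = list(ecc = c(2, 6.5), n_ecc = 3L, n_polar = 16L),
    session = list(runs_per_condition = 2L, baseline = 1000,
                   amplitude_scale = 2),
    noise = list(white_sd = 1, drift_linear = 0.5, drift_quad = 0.3,
                 drift_pink = 0.3, hemo = "delay", hemo_lag_s = 4.5),
    analysis = list(coherence_threshold = 0.2, highpass_hz = 0.01,
                    shift_volumes = 3L),
    decoding = list(n_perm = 0L, mds_restarts = 10L)
  )
  if (preset == "nih") {
    cfg$stimulus$carrier_sf_cpd <- 1.4
    cfg$stimulus$annulus <- list(inner_deg = 0.75, outer_deg = 9,
                                 transition_deg = 1)
    cfg$stimulus$modulator_waveform <- "sine"
    cfg$stimulus$radial_frequency <- 1
    cfg$stimulus$radial_log_scaled <- TRUE
  }
  dots <- list(...)
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      utils::modifyList(cfg[[nm]], dots[[nm]]) else dots[[nm]]
  }
  structure(cfg, class = "vignetta_config")
}

#' Write / read a configuration as JSON
#' @param config a [vignetta_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(utils::modifyList(unclass(vignetta_config(cfg$preset)), cfg),
            class = "vignetta_config")
}

# modulator specs for both axes and both spatial phases under a config
config_modulators <- function(cfg) {
  st <- cfg$stimulus
  lapply(list(radial = "radial", angular = "angular"), function(ax) {
    sapply(c("cosine", "sine"), function(q) {
      if (ax == "radial")
        modulator_spec("radial", st$modulator_waveform, q,
                       st$radial_frequency,
                       log_scaled = isTRUE(st$radial_log_scaled))
      else
        modulator_spec("angular", st$modulator_waveform, q,
                       st$angular_frequency)
    }, simplify = FALSE)
  })
}

#' Preprocess a session and cycle-average every run
#'
#' @param session a session of raw runs.
#' @param ... passed to [preprocess_run()].
#' @return list of [cycle_average()] results, one per run.
#' @export
session_responses <- function(session, ...) {
  lapply(session$runs, function(r) {
    cycle_average(if (r$preprocessed) r else preprocess_run(r, ...))
  })
}

#' Run the full pipeline
#'
#' Builds stimuli and the energy model, simulates orientation maps for
#' both modulators, synthesizes a phase-encoded session from
#' pRF-sampled ground truth, runs the voxelwise analysis and the
#' decoding/RSA suite, and writes figures (bias maps, single-voxel
#' preference scatter, model-vs-measured comparison, decoding
#' accuracies, MDS rings), CSV tables and a JSON run log to `out_dir`.
#'
#' @param config a [vignetta_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main intermediate results and
#'   output paths.
#' @export
run_pipeline <- function(config = vignetta_config(), out_dir = tempfile("vignetta_")) {
  stopifnot(inherits(config, "vignetta_config"))
  t_start <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(stages = list(), config = unclass(config))

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log$stages[[name]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
    res
  }

  n <- config$geometry$resolution
  geom <- display_geometry(c(n, n), config$geometry$fov_deg / n)
  bank <- stage("filter_bank", build_filter_bank(pyramid_config(
    c(n, n), config$pyramid$n_orientations,
    config$pyramid$sf_bandwidth_octaves)))
  ann <- do.call(annulus_spec, config$stimulus$annulus)
  mods <- config_modulators(config)

  sims <- stage("model_simulation", simulate_session_stimuli(
    geom, bank, mods, ann, sf_cpd = config$stimulus$carrier_sf_cpd))

  # Fig 2/3 analogs: vertical-minus-horizontal bias maps
  vh <- function(sim) {
    iv <- which.min(axial_difference(sim$orientations_deg, 90))
    ih <- which.min(axial_difference(sim$orientations_deg, 0))
    orientation_bias_map(sim$maps[[iv]], sim$maps[[ih]])
  }
  bias <- lapply(sims$avg, vh)
  unmod <- stage("unmodulated_bias", {
    s <- simulate_orientation_maps(
      geom, bank, orientations_deg = c(0, 90),
      sf_cpd = config$stimulus$carrier_sf_cpd,
      annulus = annulus_spec(5, 9, 1))
    orientation_bias_map(s$maps[[2]], s$maps[[1]])
  })

  prfs <- stage("prf_grid", make_prf_grid(config$prf_grid$ecc,
                                          config$prf_grid$n_ecc,
                                          config$prf_grid$n_polar))
  truth <- stage("ground_truth", make_ground_truth(
    prfs, sims, baseline = config$session$baseline,
    amplitude_scale = config$session$amplitude_scale))

  noise <- do.call(noise_model, c(config$noise, list(seed = config$seed)))
  session <- stage("synthetic_session", generate_session(
    session_design(config$session$runs_per_condition), truth, noise))

  prefs <- stage("phase_encoded_analysis", analyze_session(
    session, coherence_threshold = config$analysis$coherence_threshold,
    highpass_hz = config$analysis$highpass_hz,
    shift_volumes = config$analysis$shift_volumes))

  responses <- stage("population_responses", session_responses(session))
  rad <- Filter(function(r) r$modulator == "radial", responses)
  ang <- Filter(function(r) r$modulator == "angular", responses)
  acc <- stage("decoding", list(
    within = decode_within(responses),
    across = decode_across(rad, ang, 0),
    across_shifted = decode_across(rad, ang, 90)))

  rsa <- stage("rsa", {
    cm <- condition_means(responses)
    D <- dissimilarity_matrix(cm)
    emb <- mds_embed(D, 2, seed = config$seed,
                     n_restarts = config$decoding$mds_restarts)
    list(dissimilarity = D, embedding = emb)
  })

  paths <- stage("outputs", {
    p <- list()
    p$prefs_csv <- file.path(out_dir, "voxel_preferences.csv")
    data.table::fwrite(prefs, p$prefs_csv)
    p$accuracy_csv <- file.path(out_dir, "decoding_accuracy.csv")
    data.table::fwrite(data.frame(scheme = names(acc),
                                  accuracy = unlist(acc)), p$accuracy_csv)
    p$rdm_csv <- file.path(out_dir, "dissimilarity_matrix.csv")
    data.table::fwrite(as.data.frame(rsa$dissimilarity), p$rdm_csv)
    p$mds_csv <- file.path(out_dir, "mds_embedding.csv")
    data.table::fwrite(data.frame(condition = rownames(rsa$dissimilarity),
                                  dim1 = rsa$embedding[, 1],
                                  dim2 = rsa$embedding[, 2]), p$mds_csv)
    p$figures <- write_pipeline_figures(out_dir, bias, unmod, truth, prefs,
                                        acc, rsa)
    p
  })

  log$total_seconds <- round(as.numeric(difftime(Sys.time(), t_start,
                                                 units = "secs")), 3)
  log$r_version <- R.version.string
  jsonlite::write_json(log, file.path(out_dir, "runlog.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(config = config, geom = geom, bank = bank, sims = sims,
                 bias = bias, truth = truth, session = session,
                 preferences = prefs, accuracy = acc, rsa = rsa,
                 out_dir = out_dir, paths = paths))
}

# six figure analogs; base graphics, diverging scale for bias maps
write_pipeline_figures <- function(out_dir, bias, unmod, truth, prefs,
                                   acc, rsa) {
  figs <- character(0)
  divmap <- function(m, file, main) {
    lim <- max(abs(m))
    grDevices::png(file, 480, 480)
    graphics::image(t(m[nrow(m):1, ]), col = grDevices::hcl.colors(65, "Blue-Red 3"),
                    zlim = c(-lim, lim), axes = FALSE, main = main)
    grDevices::dev.off()
    file
  }
  figs <- c(figs, divmap(unmod, file.path(out_dir, "fig_bias_annulus.png"),
                         "V - H bias, plain annulus"))
  figs <- c(figs, divmap(bias$radial, file.path(out_dir, "fig_bias_radial.png"),
                         "V - H bias, radial modulator"))
  figs <- c(figs, divmap(bias$angular, file.path(out_dir, "fig_bias_angular.png"),
                         "V - H bias, angular modulator"))

  f <- file.path(out_dir, "fig_preference_scatter.png")
  grDevices::png(f, 480, 480)
  graphics::plot(truth$preferred$radial, truth$preferred$angular,
                 xlab = "predicted preferred, radial (deg)",
                 ylab = "predicted preferred, angular (deg)",
                 xlim = c(0, 180), ylim = c(0, 180), pch = 16,
                 main = "Model: modulator flips preference")
  grDevices::dev.off()
  figs <- c(figs, f)

  f <- file.path(out_dir, "fig_predicted_vs_measured.png")
  grDevices::png(f, 480, 480)
  mrad <- prefs[prefs$modulator == "radial", ]
  graphics::plot(truth$preferred$radial, mrad$preferred_deg,
                 xlab = "model-predicted preferred (deg)",
                 ylab = "recovered preferred (deg)",
                 xlim = c(0, 180), ylim = c(0, 180), pch = 16,
                 main = "Radial modulator: prediction vs recovery")
  graphics::abline(0, 1, lty = 2)
  grDevices::dev.off()
  figs <- c(figs, f)

  f <- file.path(out_dir, "fig_decoding.png")
  grDevices::png(f, 480, 480)
  graphics::barplot(unlist(acc), ylim = c(0, 1),
                    names.arg = c("within", "across", "across+90"),
                    ylab = "accuracy",
                    main = "Orientation decoding")
  graphics::abline(h = 1 / 16, lty = 2)
  grDevices::dev.off()
  figs <- c(figs, f)

  f <- file.path(out_dir, "fig_mds.png")
  grDevices::png(f, 480, 480)
  emb <- rsa$embedding
  mods <- sub("_.*", "", rownames(rsa$dissimilarity))
  graphics::plot(emb[, 1], emb[, 2], pch = ifelse(mods == "radial", 16, 1),
                 xlab = "dim 1", ylab = "dim 2",
                 main = "MDS of population responses")
  grDevices::dev.off()
  figs <- c(figs, f)
  figs
}

# ---- session import/export (plain text) -----------------------------

#' Export a session to CSV + JSON
#'
#' Each run's voxels x volumes matrix goes to `run_<i>.csv`; run
#' designs and noise metadata go to `session.json`.
#'
#' @param session a session of runs.
#' @param dir target directory.
#' @return the directory, invisibly.
#' @export
export_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  designs <- lapply(seq_along(session$runs), function(i) {
    r <- session$runs[[i]]
    data.table::fwrite(data.table::as.data.table(r$values),
                       file.path(dir, sprintf("run_%02d.csv", i)),
                       col.names = FALSE)
    d <- r$design
    list(file = sprintf("run_%02d.csv", i),
         modulator_axis = d$modulator_axis, direction = d$direction,
         modulator_phase = d$modulator_phase, tr_s = d$tr_s,
         s_per_orientation = d$s_per_orientation,
         n_orientations = d$n_orientations, n_cycles = d$n_cycles,
         preprocessed = r$preprocessed)
  })
  jsonlite::write_json(list(runs = designs), file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Import a session from CSV runs + a JSON design sidecar
#'
#' The inverse of [export_session()]; also the entry point for real
#' data exported to per-run CSV matrices (voxels x volumes) with a
#' matching sidecar.
#'
#' @param dir directory containing `session.json`, or a path to the
#'   sidecar itself.
#' @param roi_mask optional logical or integer voxel subset applied to
#'   every run.
#' @return a session list (`$runs`) consumable by the analysis suite.
#' @export
import_real_session <- function(dir, roi_mask = NULL) {
  sidecar <- if (dir.exists(dir)) file.path(dir, "session.json") else dir
  if (!file.exists(sidecar))
    stop("missing design sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
  base <- dirname(sidecar)
  runs <- lapply(meta$runs, function(d) {
    vals <- as.matrix(data.table::fread(file.path(base, d$file),
                                        header = FALSE))
    dimnames(vals) <- NULL
    if (!is.null(roi_mask)) vals <- vals[roi_mask, , drop = FALSE]
    rd <- run_design(d$modulator_axis, d$direction, d$modulator_phase,
                     tr_s = d$tr_s, s_per_orientation = d$s_per_orientation,
                     n_orientations = d$n_orientations,
                     n_cycles = d$n_cycles)
    if (!isTRUE(d$preprocessed) && ncol(vals) != rd$n_volumes)
      stop("run ", d$file, ": volume count ", ncol(vals),
           " does not match design (", rd$n_volumes, ")")
    run_timeseries(vals, rd, preprocessed = isTRUE(d$preprocessed))
  })
  list(runs = runs)
}

#' @rdname import_real_session
#' @export
import_session <- import_real_session
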