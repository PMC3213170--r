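#' Apply a configuration patch
#'
#' Overrides for experiment specs: a named list whose entries patch
#' `protocol`, `meanfield`, `noise_sigma`, `seed`, or connection weights by
#' role (`weights = list(goal = ..., action = ..., ...)`); an
#' `action_asymmetry` entry multiplies the A&D-assembly summed weight (the
#' A-D and D-A directions) by the given factor.
#'
#' @param config an `stp_config`.
#' @param overrides named list (may be empty).
#' @return a validated patched config.
#' @export
patch_config <- function(config, overrides = list()) {
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    if (nm == "protocol") config$protocol <- modifyList(config$protocol, v)
    else if (nm == "meanfield") config$meanfield <- modifyList(config$meanfield, v)
    else if (nm == "weights") {
      for (role in names(v))
        config$connections$weight[config$connections$role == role] <- v[[role]]
    } else if (nm == "action_asymmetry") {
      sel <- config$connections$role == "action" &
        config$connections$pre %in% c("A", "D") &
        config$connections$post %in% c("A", "D")
      config$connections$weight[sel] <- config$connections$weight[sel] * v
    } else if (nm %in% c("noise_sigma", "seed", "variant")) config[[nm]] <- v
    else stop("unknown override field: ", nm)
  }
  validate_config(config)
  config
}

#' Run a named experiment protocol
#'
#' Reproducible bundles of the standard experiments: `baseline` (balanced
#' batch on the all-types network), `no_plasticity` (frozen synapses control),
#' `variant_dep` / `variant_fac` (single-plasticity-type networks),
#' `perturbation_sweep`, `activation_sweep`, `asymmetry_sweep` (transition
#' timing versus the swept parameter) and `meanfield_stability` (mean-field
#' trajectory plus attractor timeline).  When `out_dir` is given, the config
#' snapshot, seeds, per-trial results and summary tables are written there as
#' plain text, and rerunning the same spec reproduces them bit for bit.
#'
#' @param name experiment name (see above).
#' @param config base configuration (default [network_config()]).
#' @param overrides config patch applied via [patch_config()].
#' @param n_trials trials per condition.
#' @param seed master seed.
#' @param out_dir optional output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @param ... extra arguments for the underlying runner.
#' @return the experiment result (an `stp_batch`, sweep table, or mean-field
#'   stability bundle), invisibly when written to disk.
#' @export
run_experiment <- function(name = c("baseline", "no_plasticity",
                                    "perturbation_sweep", "activation_sweep",
                                    "asymmetry_sweep", "meanfield_stability",
                                    "variant_dep", "variant_fac"),
                           config = NULL, overrides = list(), n_trials = 40,
                           seed = 1L, out_dir = NULL, overwrite = FALSE, ...) {
  name <- match.arg(name)
  if (is.null(config))
    config <- switch(name,
      variant_dep = network_config("depression_only"),
      variant_fac = network_config("facilitation_only"),
      network_config("all_types"))
  config <- patch_config(config, overrides)
  result <- switch(name,
    baseline = , variant_dep = , variant_fac =
      run_batch(config, n_trials = n_trials, seed = seed, ...),
    no_plasticity =
      run_batch(config, n_trials = n_trials, seed = seed,
                freeze_plasticity = TRUE, ...),
    perturbation_sweep =
      sweep_transition(config, axis = "perturbation_onset",
                       values = c(700, 1100, 1500),
                       trials_per_value = n_trials, seed = seed, ...),
    activation_sweep =
      sweep_transition(config, axis = "activation_amplitude",
                       values = c(0.32, 0.35, 0.38),
                       trials_per_value = n_trials, seed = seed, ...),
    asymmetry_sweep =
      sweep_transition(config, axis = "asymmetry_ratio",
                       values = c(1, 1.05, 1.1),
                       trials_per_value = n_trials, seed = seed, ...),
    meanfield_stability = meanfield_stability_run(config, ...))
  if (!is.null(out_dir)) {
    write_experiment(result, name, config, seed, out_dir, overwrite)
    return(invisible(result))
  }
  result
}

#' Sweep a control parameter and measure transition timing
#'
#' For each value on the axis, runs a batch of trials and summarizes the
#' transition times.  Axes: `perturbation_onset` (ms; a 0.1 nS, 200 ms pulse
#' onto one action assembly), `activation_amplitude` (nS), and
#' `asymmetry_ratio` (multiplier on the A&D action-assembly weight, for which
#' the selection ratio toward A&D is also reported).
#'
#' @param config base configuration.
#' @param axis one of the three axis names.
#' @param values at least 3 axis values.
#' @param trials_per_value batch size per value.
#' @param seed master seed; every axis value reuses the same seed, hence the
#'   same network realization and noise streams, so differences along the
#'   axis are attributable to the swept parameter.
#' @param perturbation_amplitude pulse height for the onset sweep (nS).
#' @param ... passed to [run_batch()].
#' @return data frame, class `stp_sweep`: per value the number of
#'   transitioning trials, median/mean/SD transition time, median interval
#'   from perturbation to transition (onset sweep), and selection ratio toward
#'   A&D (asymmetry sweep).
#' @export
sweep_transition <- function(config, axis = c("perturbation_onset",
                                              "activation_amplitude",
                                              "asymmetry_ratio"),
                             values, trials_per_value = 10, seed = 1L,
                             perturbation_amplitude = 0.1, ...) {
  axis <- match.arg(axis)
  stopifnot(length(values) >= 3)
  rows <- list()
  for (i in seq_along(values)) {
    v <- values[i]
    cfg <- switch(axis,
      perturbation_onset = patch_config(config, list(protocol = list(
        perturbation_amplitude = perturbation_amplitude,
        perturbation_onset = v, perturbation_target = "A1"))),
      activation_amplitude = patch_config(config, list(protocol = list(
        activation_amplitude = v))),
      asymmetry_ratio = patch_config(config, list(action_asymmetry = v)))
    b <- run_batch(cfg, n_trials = trials_per_value, seed = seed, ...)
    tt <- b$results$transition_ms
    rows[[i]] <- data.frame(
      value = v,
      n_transitions = sum(!is.na(tt)),
      median_transition_ms = median(tt, na.rm = TRUE),
      mean_transition_ms = mean(tt, na.rm = TRUE),
      sd_transition_ms = sd(tt, na.rm = TRUE),
      median_interval_ms = if (axis == "perturbation_onset")
        median(tt - v, na.rm = TRUE) else NA_real_,
      selection_ratio_A1 = mean(b$results$action == "A1", na.rm = TRUE))
  }
  out <- do.call(rbind, rows)
  attr(out, "axis") <- axis
  class(out) <- c("stp_sweep", "data.frame")
  out
}

#' Mean-field run with attractor tracking
#'
#' Simulates the mean-field model for all four goal-by-perturbation
#' combinations (so the pooled trajectories cover both goal states and both
#' action states), fits the PC basis on the four trajectories, and tracks
#' the stable attractor set along the trajectory matching the configured
#' goal (with the configured perturbation target).
#'
#' @param config an `stp_config`.
#' @param rate_params transfer-function parameters.
#' @param stride_ms attractor-timeline sampling stride (ms).
#' @param ... passed to [simulate_mean_field()].
#' @return list of class `stp_mf_stability`: `trajectory` (the run matching
#'   the configured goal), `trajectories` (all four), `basis`, `timeline`
#'   ([track_attractors()] table), `counts` ([attractor_counts()]),
#'   `projection` (trajectory in PC coordinates).
#' @export
meanfield_stability_run <- function(config, rate_params = default_rate_params(),
                                    stride_ms = 100, ...) {
  runs <- list()
  for (g in c("G1", "G2")) for (a in c("A1", "A2")) {
    cfg <- config
    cfg$protocol$sensory_target <- g
    cfg$meanfield$perturbation_target <- a
    runs[[paste(g, a)]] <- simulate_mean_field(cfg, rate_params, ...)
  }
  basis <- fit_pca(runs, align = TRUE)
  main <- runs[[paste(config$protocol$sensory_target,
                      config$protocol$perturbation_target)]]
  timeline <- track_attractors(main, basis, stride_ms = stride_ms)
  structure(list(trajectory = main, trajectories = runs, basis = basis,
                 timeline = timeline,
                 counts = attractor_counts(timeline),
                 projection = project_pc(main, basis)),
            class = "stp_mf_stability")
}

write_experiment <- function(result, name, config, seed, out_dir, overwrite) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop("output directory ", out_dir, " is not empty (use overwrite = TRUE)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out_dir, "config.yaml"))
  info <- list(experiment = name, seed = seed,
               package_version = as.character(utils::packageVersion("stpnet")))
  jsonlite::write_json(info, file.path(out_dir, "run.json"), auto_unbox = TRUE)
  if (inherits(result, "stp_batch")) {
    write.csv(result$results, file.path(out_dir, "trials.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(result$pattern),
              file.path(out_dir, "patterns.csv"), row.names = FALSE)
    tr1 <- result$traces[[which(!result$results$failed)[1]]]
    write.csv(data.frame(time_ms = tr1$time, tr1$rates, tr1$readout,
                         tr1$efficacy),
              file.path(out_dir, "example_trace.csv"), row.names = FALSE)
  } else if (inherits(result, "stp_sweep")) {
    write.csv(as.data.frame(result), file.path(out_dir, "sweep.csv"),
              row.names = FALSE)
  } else if (inherits(result, "stp_mf_stability")) {
    mf <- result$trajectory
    write.csv(data.frame(time_ms = mf$time, mf$rates, s = mf$s, uF = mf$uF,
                         xF = mf$xF, uD = mf$uD, xD = mf$xD),
              file.path(out_dir, "meanfield_trace.csv"), row.names = FALSE)
    write.csv(result$timeline, file.path(out_dir, "attractor_timeline.csv"),
              row.names = FALSE)
    write.csv(result$counts, file.path(out_dir, "attractor_counts.csv"),
              row.names = FALSE)
  }
  invisible(out_dir)
}

#' Export a trial's spikes as delimited text
#'
#' Writes `time_ms,population,neuron` rows, the interchange format for spike
#' rasters.
#'
#' @param trial an `stp_trial` run with `keep_spikes`/default spike retention.
#' @param path output file.
#' @export
write_spikes <- function(trial, path) {
  write.csv(trial$spikes, path, row.names = FALSE)
  invisible(path)
}
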