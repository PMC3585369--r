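#' Experiment configuration
#'
#' Bundles every setting of the simulation pipeline: spherical-head geometry,
#' tissue conductivities, stimulation montage, neural-mass network, stimulus,
#' analysis band and trial structure, and the master seed from which all
#' per-condition, per-trial seeds are derived. Defaults encode the reference
#' study conditions: 66 cortical regions, 7 x 5 cm pads at PO9/PO10 carrying
#' 1.12 mA, sinusoidal tACS, 20 trials per condition, alpha band 8-12 Hz.
#'
#' @param subdivision_level icosphere subdivision for the cortical mesh
#'   (default 4: 5120 triangles).
#' @param cortical_radius,scalp_radius geometry radii (m).
#' @param perturbation_amplitude radial mesh perturbation (m).
#' @param geometry_seed seed for mesh perturbation and parcellation.
#' @param n_regions cortical macro-regions (default 66).
#' @param eeg_montage montage for the simulated EEG (`"10-20"` or `"10-10"`;
#'   the stimulation pads always use the 10-10 layout).
#' @param stimulation a [stimulation_config].
#' @param population a [population_params].
#' @param network a [network_config]; its `n_cortical` must equal
#'   `n_regions`.
#' @param lambda field-effect scaling constant (mV per V/m).
#' @param tacs_frequency tACS frequency (Hz).
#' @param n_trials trials per condition (default 20).
#' @param band alpha band edges (Hz).
#' @param field_n_terms,leadfield_n_terms series truncation orders.
#' @param moment_density dipole moment surface density (A m / m^2).
#' @param master_seed integer master seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(subdivision_level = 4L,
                              cortical_radius = 0.079,
                              scalp_radius = 0.092,
                              perturbation_amplitude = 0.002,
                              geometry_seed = 1L,
                              n_regions = 66L,
                              eeg_montage = "10-20",
                              stimulation = stimulation_config(),
                              population = population_params(),
                              network = network_config(n_cortical = n_regions),
                              lambda = 0,
                              tacs_frequency = 10,
                              n_trials = 20L,
                              band = c(8, 12),
                              field_n_terms = 200L,
                              leadfield_n_terms = 60L,
                              moment_density = 1e-3,
                              master_seed = 1L) {
  if (network$n_cortical != n_regions) {
    stop("network n_cortical must equal n_regions")
  }
  structure(list(subdivision_level = as.integer(subdivision_level),
                 cortical_radius = cortical_radius,
                 scalp_radius = scalp_radius,
                 perturbation_amplitude = perturbation_amplitude,
                 geometry_seed = as.integer(geometry_seed),
                 n_regions = as.integer(n_regions),
                 eeg_montage = eeg_montage,
                 stimulation = stimulation,
                 population = population,
                 network = network,
                 lambda = lambda,
                 tacs_frequency = tacs_frequency,
                 n_trials = as.integer(n_trials),
                 band = band,
                 field_n_terms = as.integer(field_n_terms),
                 leadfield_n_terms = as.integer(leadfield_n_terms),
                 moment_density = moment_density,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

#' Derive a per-condition, per-trial seed from the master seed
#'
#' Counter-based scheme: every (condition, trial) pair maps to a distinct
#' 31-bit seed, deterministically in the master seed.
#'
#' @param master_seed integer master seed.
#' @param condition integer condition counter (0 = baseline; the pipeline
#'   uses `round(10 * frequency)` for tACS conditions and values >= 10000
#'   for calibration streams).
#' @param trial integer trial counter (1-based).
#' @return An integer seed.
#' @export
derive_seed <- function(master_seed, condition, trial) {
  as.integer((as.numeric(master_seed) * 48271 + condition * 100003 +
                trial * 1009) %% 2147483647)
}

#' Precompute the stationary part of an experiment
#'
#' Builds the cortical mesh, parcellation, dipole layer, electrode layouts,
#' the 3-shell EEG leadfield, and the stimulation field map with its
#' per-region mean normal field. All downstream conditions reuse this
#' bundle; only the neural-mass simulations are re-run per trial.
#'
#' @param config an [experiment_config].
#' @param verbose print stage timings.
#' @return A list of class `experiment_setup` with elements `config`,
#'   `mesh`, `parcellation`, `dipoles`, `stim_layout`, `eeg_layout`,
#'   `leadfield`, `field`, `E_n`, `mean_normal_field` (per region, V/m).
#' @export
setup_experiment <- function(config, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  mesh <- generate_cortical_mesh(config$subdivision_level,
                                 config$cortical_radius,
                                 config$perturbation_amplitude,
                                 config$geometry_seed)
  parc <- parcellate(mesh, config$n_regions, seed = config$geometry_seed)
  dip <- dipole_layer(mesh, config$moment_density)
  say("geometry: %d triangles, %d regions [%.1f s]", nrow(mesh$triangles),
      parc$n_regions, as.numeric(Sys.time() - t0, units = "secs"))
  stim_layout <- standard_electrode_positions("10-10", config$scalp_radius)
  eeg_layout <- standard_electrode_positions(config$eeg_montage,
                                             config$scalp_radius)
  t1 <- Sys.time()
  A <- leadfield_3shell(default_eeg_shells(config$scalp_radius), eeg_layout,
                        dip, n_terms = config$leadfield_n_terms)
  say("leadfield: %d x %d [%.1f s]", nrow(A$values), ncol(A$values),
      as.numeric(Sys.time() - t1, units = "secs"))
  t2 <- Sys.time()
  sources <- pad_sources(config$stimulation, stim_layout,
                         config$scalp_radius)
  field <- efield_at(default_field_shells(config$scalp_radius), sources,
                     mesh$barycenters, n_terms = config$field_n_terms)
  E_n <- normal_field(field, mesh)
  coeff <- region_mean_field(E_n, parc, lambda = 1)
  say("field map: mean |E_n| %.3g V/m [%.1f s]", mean(abs(E_n)),
      as.numeric(Sys.time() - t2, units = "secs"))
  structure(list(config = config, mesh = mesh, parcellation = parc,
                 dipoles = dip, stim_layout = stim_layout,
                 eeg_layout = eeg_layout, leadfield = A, field = field,
                 E_n = E_n, mean_normal_field = coeff$mean_normal_field),
            class = "experiment_setup")
}

#' Simulate one condition and collect per-trial alpha powers
#'
#' Runs `n_trials` independent network simulations under the given stimulus,
#' projects each to scalp EEG through the precomputed leadfield, and returns
#' the per-trial, per-electrode alpha-band powers.
#'
#' @param setup an [setup_experiment()] bundle.
#' @param lambda field-effect scaling constant; 0 is the no-stimulation
#'   condition.
#' @param mode stimulus mode (`"none"`, `"dc"`, `"sinusoid"`); `lambda = 0`
#'   forces `"none"`.
#' @param frequency tACS frequency (Hz, sinusoid mode).
#' @param n_trials number of trials.
#' @param condition integer condition counter for seed derivation.
#' @param keep_eeg return the last trial's `eeg_record` as attribute
#'   `"eeg"`.
#' @return A `power_result` (trials x electrodes).
#' @export
run_condition <- function(setup, lambda = 0, mode = "sinusoid",
                          frequency = 10, n_trials = NULL,
                          condition = NULL, keep_eeg = FALSE) {
  config <- setup$config
  if (is.null(n_trials)) n_trials <- config$n_trials
  if (is.null(condition)) {
    condition <- if (lambda == 0) 0L else as.integer(round(10 * frequency))
  }
  offsets <- lambda * setup$mean_normal_field
  stim <- if (lambda == 0) {
    stimulus_spec("none")
  } else {
    stimulus_spec(mode, frequency = frequency, offsets = offsets)
  }
  eeg_last <- NULL
  powers <- matrix(NA_real_, n_trials, length(setup$eeg_layout$names))
  for (tr in seq_len(n_trials)) {
    seed <- derive_seed(config$master_seed, condition, tr)
    sim <- simulate_network(config$population, config$network, stim,
                            seed = seed)
    eeg <- project_eeg(setup$leadfield, setup$parcellation, setup$dipoles,
                       sim)
    powers[tr, ] <- eeg_alpha_power(eeg, config$band[1], config$band[2])
    if (keep_eeg && tr == n_trials) eeg_last <- eeg
  }
  out <- power_result(powers, setup$eeg_layout$names, config$band)
  if (keep_eeg) attr(out, "eeg") <- eeg_last
  out
}

#' Percent alpha-power change at one electrode
#'
#' Convenience experiment: baseline versus stimulated condition, percent
#' change of the mean alpha power at `electrode`.
#'
#' @inheritParams run_condition
#' @param electrode electrode label (must exist in the EEG montage).
#' @param base optional precomputed baseline `power_result` to reuse.
#' @return Percent change (scalar).
#' @export
percent_change_at <- function(setup, lambda, electrode = "POz",
                              frequency = 10, n_trials = NULL,
                              condition = NULL, base = NULL) {
  i <- match(electrode, setup$eeg_layout$names)
  if (is.na(i)) stop("electrode not in the EEG montage: ", electrode)
  if (is.null(base)) {
    base <- run_condition(setup, lambda = 0, n_trials = n_trials)
  }
  stim <- run_condition(setup, lambda = lambda, frequency = frequency,
                        n_trials = n_trials, condition = condition)
  100 * (mean(stim$powers[, i]) - mean(base$powers[, i])) /
    mean(base$powers[, i])
}

#' Run a full experiment and write its output bundle
#'
#' Executes the pipeline for the no-stimulation condition and the configured
#' tACS condition, compares alpha power per electrode and writes all
#' artifacts (field map, region coefficients, leadfield, per-trial power
#' tables, comparison table, one example EEG per condition, the config and
#' a log with seeds) into `outdir`.
#'
#' @param config an [experiment_config].
#' @param outdir output directory (created if missing).
#' @param verbose print progress.
#' @return The `comparison_result`, invisibly; the bundle on disk.
#' @export
run_experiment <- function(config, outdir, verbose = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  setup <- setup_experiment(config, verbose = verbose)
  write_field_map(setup$field, file.path(outdir, "field_map.tsv"))
  write_region_coefficients(
    region_mean_field(setup$E_n, setup$parcellation, config$lambda),
    file.path(outdir, "region_coefficients.tsv"))
  write_leadfield(setup$leadfield, file.path(outdir, "leadfield.tsv"))
  write_parcellation(setup$parcellation, file.path(outdir,
                                                   "parcellation.tsv"))
  write_experiment_config(config, file.path(outdir, "config.yaml"))
  base <- run_condition(setup, lambda = 0, keep_eeg = TRUE)
  stim <- run_condition(setup, lambda = config$lambda,
                        frequency = config$tacs_frequency, keep_eeg = TRUE)
  write_eeg_text(attr(base, "eeg"), file.path(outdir, "eeg_baseline.tsv"))
  write_eeg_text(attr(stim, "eeg"), file.path(outdir, "eeg_tacs.tsv"))
  utils::write.table(base$powers, file.path(outdir, "powers_baseline.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(stim$powers, file.path(outdir, "powers_tacs.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cmp <- compare_conditions(base, stim)
  write_results_table(cmp, file.path(outdir, "comparison.tsv"))
  log_lines <- c(
    sprintf("master_seed: %d", config$master_seed),
    sprintf("lambda: %g", config$lambda),
    sprintf("tacs_frequency: %g", config$tacs_frequency),
    sprintf("n_trials: %d", config$n_trials),
    sprintf("baseline seeds: %s",
            paste(vapply(seq_len(config$n_trials), function(tr)
              derive_seed(config$master_seed, 0L, tr), integer(1)),
              collapse = " ")),
    sprintf("tacs seeds: %s",
            paste(vapply(seq_len(config$n_trials), function(tr)
              derive_seed(config$master_seed,
                          as.integer(round(10 * config$tacs_frequency)), tr),
              integer(1)), collapse = " ")))
  writeLines(log_lines, file.path(outdir, "run.log"))
  invisible(cmp)
}

#' Miniature deterministic fixture for tests
#'
#' A small experiment setup (subdivision-2 mesh of 320 triangles, 8 regions,
#' 8 + 1 populations, 10 s trials, 3 trials per condition) that runs the full
#' pipeline in seconds.
#'
#' @param seed master seed.
#' @return An [experiment_config].
#' @export
generate_fixture <- function(seed = 1L) {
  experiment_config(
    subdivision_level = 2L,
    n_regions = 8L,
    eeg_montage = "10-10",
    network = network_config(n_cortical = 8L, duration = 12,
                             transient = 2),
    stimulation = stimulation_config(sources_per_pad = 9L),
    n_trials = 3L,
    field_n_terms = 140L,
    leadfield_n_terms = 40L,
    master_seed = as.integer(seed))
}

#' Write / read an experiment configuration as YAML
#'
#' The full nested configuration round-trips through a YAML file, so a
#' written config reloads to an equivalent experiment.
#'
#' @param config an [experiment_config].
#' @param path file path.
#' @export
write_experiment_config <- function(config, path) {
  ser <- list(
    subdivision_level = config$subdivision_level,
    cortical_radius = config$cortical_radius,
    scalp_radius = config$scalp_radius,
    perturbation_amplitude = config$perturbation_amplitude,
    geometry_seed = config$geometry_seed,
    n_regions = config$n_regions,
    eeg_montage = config$eeg_montage,
    stimulation = unclass(config$stimulation),
    population = list(
      P = unclass(config$population$P),
      I = unclass(config$population$I),
      Iprime = unclass(config$population$Iprime),
      C = as.list(config$population$C),
      tcs_gain = config$population$tcs_gain),
    network = unclass(config$network),
    lambda = config$lambda,
    tacs_frequency = config$tacs_frequency,
    n_trials = config$n_trials,
    band = config$band,
    field_n_terms = config$field_n_terms,
    leadfield_n_terms = config$leadfield_n_terms,
    moment_density = config$moment_density,
    master_seed = config$master_seed)
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  subp <- function(l) do.call(subpopulation_params, l)
  pop <- population_params(P = subp(y$population$P),
                           I = subp(y$population$I),
                           Iprime = subp(y$population$Iprime),
                           C = unlist(y$population$C),
                           tcs_gain = unlist(y$population$tcs_gain))
  net <- do.call(network_config, y$network)
  stim <- do.call(stimulation_config, y$stimulation)
  experiment_config(
    subdivision_level = y$subdivision_level,
    cortical_radius = y$cortical_radius,
    scalp_radius = y$scalp_radius,
    perturbation_amplitude = y$perturbation_amplitude,
    geometry_seed = y$geometry_seed,
    n_regions = y$n_regions,
    eeg_montage = y$eeg_montage,
    stimulation = stim,
    population = pop,
    network = net,
    lambda = y$lambda,
    tacs_frequency = y$tacs_frequency,
    n_trials = y$n_trials,
    band = unlist(y$band),
    field_n_terms = y$field_n_terms,
    leadfield_n_terms = y$leadfield_n_terms,
    moment_density = y$moment_density,
    master_seed = y$master_seed)
}
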