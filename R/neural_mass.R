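#' Neural mass model parameters
#'
#' `subpopulation_params()` describes one subpopulation: the synaptic gain of
#' its output kernel (mV), the two PSP rate constants of the bi-exponential
#' kernel (s^-1, `w2 > w1`), and the wave-to-pulse sigmoid (half-maximum
#' firing rate `e0` in s^-1, threshold `v0` in mV, slope `r` in mV^-1).
#'
#' `population_params()` bundles the three subpopulations of a cortical
#' population — pyramidal cells `P`, fast (soma-targeting) interneurons `I`,
#' slow (dendrite-targeting) interneurons `Iprime` — with the eight
#' connectivity constants (average synaptic contacts from subpopulation X to
#' Y, `C_XY`) and the per-subpopulation stimulation gain ratios `tcs_gain`
#' (defaults 1, 0, 0: the field acts on pyramidal cells only). The defaults
#' are the alpha-rhythm parameter set: A = 5.5, B = 8, G = 10 mV;
#' (a1, a2) = (40, 80), (b1, b2) = (20, 60), (g1, g2) = (150, 200) s^-1;
#' C_PP = 55, C_PI = 80, C_PI' = 90, C_IP = 20, C_II = 15, C_I'P = 25,
#' C_I'I = 20, C_I'I' = 40; e0 = 10 s^-1, v0 = 1 mV (P) / 4 mV (I, I'),
#' r = 0.7 mV^-1.
#'
#' @param gain synaptic gain in mV.
#' @param w1,w2 PSP rate constants in s^-1, `w2 > w1 > 0`.
#' @param coupling dimensionless input-rate coupling of the subpopulation's
#'   output kernel (synaptic efficacy per contact); the kernel input
#'   coefficient is `gain * coupling`. Defaults are calibrated so the
#'   population operates at a stable, weakly damped ~10 Hz (alpha) resonance
#'   (see the package vignette).
#' @param e0 half-maximum firing rate (s^-1); the sigmoid saturates at 2*e0.
#' @param v0 sigmoid threshold (mV).
#' @param r sigmoid slope (mV^-1).
#' @return A `subpopulation_params` / `population_params` list.
#' @export
subpopulation_params <- function(gain, w1, w2, e0 = 10, v0 = 1, r = 0.7,
                                 coupling = 1) {
  if (!(w2 > w1 && w1 > 0)) stop("PSP rate constants must satisfy w2 > w1 > 0")
  if (e0 <= 0 || r <= 0) stop("e0 and r must be positive")
  if (coupling <= 0) stop("coupling must be positive")
  structure(list(gain = gain, w1 = w1, w2 = w2, e0 = e0, v0 = v0, r = r,
                 coupling = coupling),
            class = "subpopulation_params")
}

#' @rdname subpopulation_params
#' @param P,I,Iprime [subpopulation_params] for the three subpopulations.
#' @param C named numeric vector of the eight connectivity constants
#'   `C_PP, C_PI, C_PI', C_IP, C_II, C_I'P, C_I'I, C_I'I'` (dimensionless,
#'   all >= 0).
#' @param tcs_gain length-3 stimulation gain ratios for (P, I, I').
#' @export
population_params <- function(
    P = subpopulation_params(5.5, 40, 80, e0 = 10, v0 = 1, r = 0.7,
                             coupling = 9.897),
    I = subpopulation_params(10, 150, 200, e0 = 10, v0 = 4, r = 0.7,
                             coupling = 86.580),
    Iprime = subpopulation_params(8, 20, 60, e0 = 10, v0 = 4, r = 0.7,
                                  coupling = 2.070),
    C = c(C_PP = 55, C_PI = 80, "C_PI'" = 90, C_IP = 20, C_II = 15,
          "C_I'P" = 25, "C_I'I" = 20, "C_I'I'" = 40),
    tcs_gain = c(1, 0, 0)) {
  need <- c("C_PP", "C_PI", "C_PI'", "C_IP", "C_II", "C_I'P", "C_I'I",
            "C_I'I'")
  if (!all(need %in% names(C))) {
    stop("C must contain: ", paste(need, collapse = ", "))
  }
  if (any(C < 0)) stop("connectivity constants must be non-negative")
  if (length(tcs_gain) != 3L) stop("tcs_gain must have length 3")
  structure(list(P = P, I = I, Iprime = Iprime, C = C[need],
                 tcs_gain = tcs_gain),
            class = "population_params")
}

#' Network configuration
#'
#' Wiring and integration settings for the `n_cortical + 1` population
#' network: the unidirectional coupling gain from the subcortical pacemaker's
#' pyramidal firing rate into each cortical excitatory kernel; the periodic
#' trapezoid drive to the subcortical population (period 2.5 s, i.e. 0.4 Hz,
#' with ramp-up / plateau / ramp-down inside the period); the Gaussian input
#' rate statistics; the Euler-Maruyama step; the simulated duration and the
#' discarded initial transient.
#'
#' @param n_cortical number of cortical populations (default 66).
#' @param subcortical_gain dimensionless coupling strength (default 8).
#' @param drive list with `period`, `ramp_up`, `plateau`, `ramp_down` (s) and
#'   `amplitude` (s^-1).
#' @param noise list with `mean` and `sd` of the Gaussian input rate (s^-1).
#' @param dt integration step in seconds (default 1/512).
#' @param duration simulated time in seconds (excluding nothing; the first
#'   `transient` seconds are discarded from the output).
#' @param transient discarded initial interval (s, default 2).
#' @return A `network_config` list.
#' @export
network_config <- function(n_cortical = 66L, subcortical_gain = 8,
                           drive = list(period = 2.5, ramp_up = 0.3,
                                        plateau = 0.5, ramp_down = 0.3,
                                        amplitude = 200),
                           noise = list(mean = 90, sd = 30),
                           dt = 1 / 512, duration = 32, transient = 2) {
  if (dt <= 0) stop("dt must be positive")
  if (drive$period <= drive$ramp_up + drive$plateau) {
    stop("drive period must exceed ramp_up + plateau")
  }
  if (duration <= transient) stop("duration must exceed the transient")
  structure(list(n_cortical = as.integer(n_cortical),
                 subcortical_gain = subcortical_gain, drive = drive,
                 noise = noise, dt = dt, duration = duration,
                 transient = transient),
            class = "network_config")
}

#' Stimulus specification
#'
#' How transcranial stimulation perturbs the network: `mode = "none"` (no
#' stimulus), `"dc"` (constant offsets, tDCS) or `"sinusoid"` (offsets
#' modulated by `sin(2 pi f t)`, tACS). `offsets` are the per-region
#' membrane-potential offsets in mV, usually `region_field_coefficients$offsets`.
#'
#' @param mode one of `"none"`, `"dc"`, `"sinusoid"`.
#' @param frequency tACS frequency in Hz (sinusoid mode only, > 0).
#' @param offsets numeric vector of per-region offsets (mV); recycled to the
#'   network size only if scalar.
#' @return A `stimulus_spec` list.
#' @export
stimulus_spec <- function(mode = c("none", "dc", "sinusoid"), frequency = 10,
                          offsets = 0) {
  mode <- match.arg(mode)
  if (mode == "sinusoid" && (!is.finite(frequency) || frequency <= 0)) {
    stop("frequency must be positive in sinusoid mode")
  }
  structure(list(mode = mode, frequency = frequency,
                 offsets = as.numeric(offsets)),
            class = "stimulus_spec")
}

#' Wave-to-pulse sigmoid
#'
#' Mean firing rate of a subpopulation as a function of its mean membrane
#' potential: `S(v) = 2 e0 / (1 + exp(r (v0 - v)))`, monotone increasing and
#' bounded in (0, 2 e0), with `S(v0) = e0`.
#'
#' @param v membrane potential (mV), vectorized.
#' @param sub a [subpopulation_params].
#' @return Firing rate(s) in s^-1.
#' @export
sigmoid_rate <- function(v, sub) {
  2 * sub$e0 / (1 + exp(sub$r * (sub$v0 - v)))
}

#' Bi-exponential PSP impulse response
#'
#' `h(t) = gain * coupling / (w2 - w1) * (exp(-w1 t) - exp(-w2 t))` for
#' `t >= 0`: the response of the synaptic kernel realized in the simulator as
#' the second-order ODE
#' `y'' = gain * coupling * x(t) - (w1 + w2) y' - w1 w2 y`.
#' The kernel peaks at `t* = log(w2 / w1) / (w2 - w1)` regardless of the
#' normalization (e.g. 17.33 ms for the excitatory pair 40, 80 s^-1).
#'
#' @param t time (s), vectorized, `t >= 0`.
#' @param gain synaptic gain (mV).
#' @param w1,w2 rate constants (s^-1), `w2 > w1`.
#' @param coupling input-rate coupling constant (see
#'   [subpopulation_params()]).
#' @return Kernel values in mV.
#' @export
psp_impulse_response <- function(t, gain, w1, w2, coupling = 1) {
  if (w2 <= w1) stop("w2 must exceed w1")
  if (any(t < 0)) stop("t must be non-negative")
  gain * coupling / (w2 - w1) * (exp(-w1 * t) - exp(-w2 * t))
}

#' Periodic trapezoid drive
#'
#' The slow excitatory input to the subcortical pacemaker: a periodic
#' ramp-up / plateau / ramp-down / zero waveform (default period 2.5 s,
#' i.e. 0.4 Hz) that paces the alpha bursts.
#'
#' @param t time (s), vectorized.
#' @param drive the `drive` list of a [network_config].
#' @return Drive rate(s) in s^-1, non-negative.
#' @export
trapezoid_drive <- function(t, drive) {
  tt <- t %% drive$period
  up <- drive$ramp_up
  pl <- drive$plateau
  dn <- drive$ramp_down
  a <- drive$amplitude
  out <- numeric(length(tt))
  i1 <- tt < up
  out[i1] <- if (up > 0) a * tt[i1] / up else a
  i2 <- tt >= up & tt < up + pl
  out[i2] <- a
  i3 <- tt >= up + pl & tt < up + pl + dn
  out[i3] <- a * (1 - (tt[i3] - up - pl) / dn)
  out
}

#' Stimulation membrane-potential offset
#'
#' The perturbation added to a region's pyramidal membrane potential at time
#' `t`: 0 in mode `"none"`, the constant regional offset in `"dc"`, and
#' `offset * sin(2 pi f t)` in `"sinusoid"`.
#'
#' @param t time (s), vectorized.
#' @param stim a [stimulus_spec].
#' @param region 1-based region index.
#' @return Offset(s) in mV.
#' @export
tcs_offset <- function(t, stim, region) {
  if (stim$mode == "none") return(rep(0, length(t)))
  off <- stim$offsets[region]
  if (stim$mode == "dc") rep(off, length(t))
  else off * sin(2 * pi * stim$frequency * t)
}

#' Simulate the coupled neural-mass network
#'
#' Integrates the `n_cortical + 1` population network with fixed-step
#' Euler-Maruyama integration: every population holds pyramidal, fast- and
#' slow-inhibitory subpopulations coupled through bi-exponential synaptic
#' kernels and the connectivity constants; each population receives an
#' independent Gaussian input rate; the subcortical pacemaker receives the
#' periodic trapezoid drive and its pyramidal firing rate feeds every
#' cortical population's excitatory kernel; the stimulus offsets are added
#' to the cortical pyramidal membrane potentials before the sigmoid. The
#' output per region is the net summed PSP at pyramidal cells
#' (EPSP - fast IPSP - slow IPSP) after discarding the initial transient.
#'
#' With `n_cortical = 1` and `subcortical_gain = 0` the model reduces to a
#' single isolated population.
#'
#' @param pop a [population_params].
#' @param net a [network_config].
#' @param stim a [stimulus_spec]; scalar offsets are recycled to
#'   `n_cortical`.
#' @param seed integer seed; identical seeds give bit-identical results.
#' @return An object of class `simulation_result`: `S` (n_cortical x
#'   n_samples matrix, mV), `subcortical_trace`, `fs` (Hz), `seed`.
#' @export
simulate_network <- function(pop, net, stim = stimulus_spec("none"),
                             seed = 1L) {
  offsets <- stim$offsets
  if (length(offsets) == 1L) offsets <- rep(offsets, net$n_cortical)
  if (length(offsets) != net$n_cortical) {
    stop("stimulus offsets length must equal n_cortical")
  }
  mode <- match(stim$mode, c("none", "dc", "sinusoid")) - 1L
  res <- with_seed(as.integer(seed), {
    .simulate_network_cpp(
      n_cortical = net$n_cortical,
      gains = c(pop$P$gain, pop$Iprime$gain, pop$I$gain),
      couplings = c(pop$P$coupling, pop$Iprime$coupling, pop$I$coupling),
      rates = c(pop$P$w1, pop$P$w2, pop$Iprime$w1, pop$Iprime$w2,
                pop$I$w1, pop$I$w2),
      sig_e0 = c(pop$P$e0, pop$I$e0, pop$Iprime$e0),
      sig_v0 = c(pop$P$v0, pop$I$v0, pop$Iprime$v0),
      sig_r = c(pop$P$r, pop$I$r, pop$Iprime$r),
      C = as.numeric(pop$C),
      tcs_gain = pop$tcs_gain,
      subcortical_gain = net$subcortical_gain,
      drive_period = net$drive$period,
      drive_ramp_up = net$drive$ramp_up,
      drive_plateau = net$drive$plateau,
      drive_ramp_down = net$drive$ramp_down,
      drive_amplitude = net$drive$amplitude,
      noise_mean = net$noise$mean, noise_sd = net$noise$sd,
      dt = net$dt, duration = net$duration, transient = net$transient,
      stim_mode = mode, stim_freq = stim$frequency,
      offsets = offsets)
  })
  if (any(!is.finite(res$S))) stop("instability: non-finite output")
  structure(list(S = res$S, subcortical_trace = res$subcortical_trace,
                 fs = 1 / net$dt, seed = as.integer(seed)),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d regions x %d samples at %g Hz (seed %d)\n",
              nrow(x$S), ncol(x$S), x$fs, x$seed))
  invisible(x)
}

#' Export a simulation result as delimited text
#'
#' Writes the region time courses as tab-separated text (rows = samples,
#' columns = regions, plus the subcortical trace as the last column) and a
#' YAML sidecar `<path>.meta.yaml` with sampling rate and seed.
#'
#' @param sim a `simulation_result`.
#' @param path file path.
#' @export
write_simulation <- function(sim, path) {
  m <- cbind(t(sim$S), sim$subcortical_trace)
  colnames(m) <- c(sprintf("region_%02d", seq_len(nrow(sim$S))),
                   "subcortical")
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(fs = sim$fs, seed = sim$seed, units = "mV"),
                   paste0(path, ".meta.yaml"), precision = 15)
  invisible(path)
}
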