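---
title: "Simulating scalp EEG under transcranial current stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating scalp EEG under transcranial current stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tacsim)
```

`tacsim` simulates what happens on the scalp EEG when a weak transcranial
current is injected through electrode pads: a volume-conductor model maps
the injected current to an electric field on the cortex, the field's
component along the pyramidal-cell axes perturbs a network of neural mass
populations generating alpha activity, and the resulting source dynamics
are projected back to scalp electrodes through an EEG leadfield. This
vignette explains each model, the choices behind every tunable parameter,
and what the synthetic setting can and cannot say about real recordings.

## The head model

All solvers run on concentric spherical shells (`shell_model`). The
stimulation field solver uses five tissues — white-matter core (0.065 m,
0.15 S/m), grey matter (0.079 m, 0.33 S/m), CSF (0.082 m, 1.79 S/m), skull
(0.087 m, 0.008 S/m) and scalp (0.092 m, 0.33 S/m) — while the EEG forward
model uses the classical three shells (brain/skull/scalp at 0.33, 0.008,
0.33 S/m). The radii follow the widely used spherical-head proportions; the
white-matter core radius is our own choice and only influences the field
solution weakly (the field is evaluated at the grey-matter surface). The
conductivities are standard DC/low-frequency literature values, and the
quasi-static approximation treats all tissues as purely resistive.

The cortical source surface is a recursively subdivided icosahedron
(`generate_cortical_mesh`), optionally perturbed by a smooth seeded radial
bump field so that triangle normals are not exactly radial — a minimal
stand-in for cortical folding. The default perturbation (2 mm) keeps the
surface strictly inside the innermost EEG shell. Triangles are grouped into
66 spatially contiguous macro-regions (33 per hemisphere) by seeded
spherical k-means with a contiguity repair step (`parcellate`); each region
hosts one neuronal population. One current dipole sits at each triangle
barycenter, oriented along the outward normal, with moment proportional to
triangle area (`dipole_layer`).

## The stimulation field

Each 7 x 5 cm pad is discretized as a grid of point current sources on the
scalp sphere (35 per pad by default), centred on the PO9 and PO10
electrodes of the 10-10 system and carrying 1.12 mA in total. For a point
source on a multi-shell sphere the potential has a closed Legendre-series
solution; per harmonic degree the two radial coefficients of each shell are
propagated across interfaces with closed-form 2 x 2 transfer matrices and
fixed by the insulating outer boundary. The electric field is the analytic
gradient of this series. Series are truncated at 120 terms by default (200
in the pipeline, where barycenters approach the shell boundary) with a
tail-ratio convergence warning at 1e-8. Both the potential and the field
are validated in the test suite against an independent finite-volume
Laplace solver on an axisymmetric grid, and the analytic gradient against
central differences of the potential.

The signed normal component `E_n = E . n` is averaged (unweighted) over
each region's triangles, and the membrane offset applied to region k is
`delta_k = lambda * mean(E_n, k)` in millivolts. `lambda` (mV per V/m)
absorbs the unknown biophysical coupling between field and mean membrane
polarization; it is meaningful only within a fixed geometry and is fixed by
calibration (below), not copied from any other head model.

## The neural mass network

Each cortical region holds three interacting subpopulations: pyramidal
cells `P`, fast soma-targeting interneurons `I`, and slow
dendrite-targeting interneurons `I'`. A subpopulation's synaptic output is
a bi-exponential post-synaptic potential kernel realized as the
second-order ODE

```
y'' = (gain * coupling) x(t) - (w1 + w2) y' - w1 w2 y
```

with the printed parameter set: gains A = 5.5, B = 8, G = 10 mV; rate pairs
(40, 80), (20, 60), (150, 200) s^-1; eight connectivity constants C_PP =
55, C_PI = 80, C_PI' = 90, C_IP = 20, C_II = 15, C_I'P = 25, C_I'I = 20,
C_I'I' = 40 scaling the firing rates entering each pathway; and the
wave-to-pulse sigmoid `S(v) = 2 e0 / (1 + exp(r (v0 - v)))` with e0 = 10
s^-1, r = 0.7 mV^-1, v0 = 1 mV for pyramidal cells and 4 mV for both
interneuron types. The per-source `coupling` constants (nu_E = 9.897 for
excitatory synapses, nu_G = 86.580 for fast inhibition, nu_B = 2.070 for
slow inhibition) are not printed anywhere and were calibrated once by
eigen-analysis of the linearized model so that, at the default Gaussian
input rate (mean 90 s^-1, SD 30 s^-1), the population sits at a *stable,
weakly damped resonance*: its lead oscillatory mode is 9.8 Hz at the
isolated operating point and 10.0 Hz at the coupled-network operating
point, with a half-width of about 2 Hz, all subpopulations inside the
active range of their sigmoids, a monotonically increasing stationary
firing rate under DC depolarization, and a sizeable mean-input-to-LFP
transfer. This operating regime reproduces the defining behaviours of the
model family: spontaneous alpha-band output, millivolt-scale sensitivity to
membrane offsets, and a stimulation response confined to the 8-12 Hz
neighbourhood of the resonance. The per-region output (the LFP) is the net
summed PSP at the pyramidal cells, EPSP minus fast and slow IPSPs.

Candidate normalizations in which the kernel's DC gain equals the printed
synaptic gain per unit rate (or simple rate-scaled variants thereof) were
analysed first; with the printed parameters each of them either saturates
the sigmoids at hundreds of millivolts, locks into a low-frequency
relaxation cycle, or loses the alpha resonance altogether, and none
responds to millivolt offsets. The calibrated-coupling realization is
therefore a considered design decision, not a convenience.

A 67th population paces the network: it receives a periodic trapezoid
drive (period 2.5 s, i.e. 0.4 Hz; ramps 0.3 s, plateau 0.5 s, amplitude
200 s^-1) instead of a stimulus, and its pyramidal firing rate feeds every
cortical population's excitatory kernel with gain 8. Drive amplitude and
gain are unprinted; they were chosen together so that (i) coupled regions
are substantially more correlated than uncoupled ones, (ii) the alpha-burst
envelope is entrained at the 2.5 s drive period (spindle-like bursts), and
(iii) the coupled network still resonates at 10 Hz. A larger amplitude
(300 s^-1) produces crisper bursts but makes per-trial alpha power
noticeably more variable; 200 s^-1 is the compromise.

Integration is fixed-step Euler-Maruyama at dt = 1/512 s (compiled code),
with an independent Gaussian input rate per population per step, a 2 s
discarded transient, and a divergence guard naming the step size. Identical
seeds give bit-identical output; halving dt moves the alpha-band spectral
centroid by less than 0.2 Hz.

Stimulation enters as a membrane-potential offset added to the pyramidal
sigmoid argument only (`tcs_gain = c(1, 0, 0)`): constant `delta_k` for
tDCS and `delta_k sin(2 pi f t)` for tACS. Field effects on interneurons
are deliberately neglected.

## EEG forward model and analysis

The scalp potential of each unit dipole in the three-shell head is the
truncated-series solution for a current dipole inside a layered sphere: the
primary (infinite-medium) expansion of the dipole is matched across shells
with the same transfer matrices as the field solver and closed by the
insulating boundary. The implementation reproduces the classical
closed-form potential of a central dipole in a homogeneous sphere exactly,
satisfies reciprocity against the stimulation-field solver, and matches the
finite-volume oracle within 2%. Columns are average-referenced by default
(the reference choice drops out of all relative power metrics).
`project_eeg` assigns every triangle of a region its region's time course
scaled by the triangle's dipole moment and applies `X = A S`.

Spectral analysis uses the plain rectangular-window periodogram
(`psd_periodogram`; it satisfies the discrete Parseval identity to 1e-9)
and alpha power is the rectangle-rule integral of the PSD over 8-12 Hz,
endpoints inclusive (`alpha_power`). Conditions are compared per electrode
by the relative change in mean alpha power and a two-sided Mann-Whitney
test across trials at alpha = 0.05 (`compare_conditions`); the full-scale
experiment uses 20 trials of 30 s per condition.

Three statistical design choices deserve note, all exposed as options:

* **Common random numbers.** When calibrating `lambda` and when
  re-measuring the calibrated effect, the baseline and stimulated trials
  are paired on identical noise streams, so the measured change isolates
  the stimulation effect. This roughly halves the spread of the calibrated
  percent change relative to fully independent arms. The frequency sweep
  does *not* use pairing, because the rank test assumes independent
  samples.
* **Shared-control sizing.** The sweep compares 13 stimulation frequencies
  against one no-stimulation condition; that shared arm uses twice the
  per-condition trial count so that a chance excursion of the control mean
  does not tilt all 13 comparisons at once.
* **Multiplicity.** `frequency_sweep` Bonferroni-corrects the per-electrode
  significance flags across the swept frequencies (13 simultaneous tests
  per electrode; `p_adjust = "none"` restores raw flags). Without the
  correction, small systematic off-band effects — sigmoid rectification
  under the pads and burst-envelope sidebands of the stimulated spectral
  line — intermittently reach raw p < 0.05.

## Calibration of lambda

`calibrate_lambda` evaluates a user-supplied experiment over a grid of
lambda values and inverts the response at a target percent change (default
14% at POz under 10 Hz tACS). The pipeline uses the default grid 0.25-3
mV/(V/m) with log-log interpolation between the bracketing grid
points (exact for a power-law response), and
averages the response curve over two independently seeded calibration
streams. The response grows monotonically with lambda over this grid. The
lambda scale is tied to the spherical surrogate's field magnitudes and is
not comparable across head models.

## A worked experiment

```{r}
cfg <- experiment_config(eeg_montage = "10-10")
setup <- setup_experiment(cfg, verbose = TRUE)
base <- run_condition(setup, lambda = 0)
stim <- run_condition(setup, lambda = 1, frequency = 10)
cmp <- compare_conditions(base, stim)
head(cmp[order(-cmp$pct_change), ])
```

The full pipeline (geometry, field map, leadfield, both conditions, the
comparison table, example EEG segments and a log of all derived seeds) is
written by `run_experiment(cfg, "outdir")`, and
`inst/cli/tacsim.R` exposes the stages as shell commands.

## Problem sizes and determinism

The default experiment uses a subdivision-4 icosphere (5120 triangles), 66
regions, 43 electrodes (extended 10-10 layout), 200 Legendre terms for the
field, 60 for the leadfield, and 20 trials of 30 s per condition; a full
calibration plus 13-frequency sweep completes in a few minutes on one core.
The test fixture (`generate_fixture`) shrinks this to 320 triangles, 8
regions and 3 trials of 10 s and runs in seconds. Every random quantity
derives from a single master seed through a counter-based scheme
(`derive_seed`), so whole experiments are bit-reproducible.

## What the synthetic setting does and does not show

The generator emulates the *structure* of the modelled experiment:
spatially heterogeneous field effects over a closed cortical surface,
resonant populations paced by a common subcortical input, volume-conducted
mixing at the scalp, and trial-to-trial variability from stochastic input.
It does not emulate cortical folding (our normal directions vary far less
than on a real cortex), realistic alpha topography (no cortico-cortical
connectivity, so the parieto-occipital dominance of real alpha is absent),
tissue anisotropy, electrode-skin interfaces, or measurement noise and
stimulation artifacts. Passing tests therefore demonstrate the internal
consistency of the modelling chain and the qualitative phenomena —
resonance-limited entrainment, posterior-dominant effects, band-limited
significance — not quantitative agreement with any particular subject.

## Known limitations

* The alpha operating point is a calibrated property of the unprinted
  kernel couplings; other couplings consistent with the printed parameters
  produce qualitatively different dynamics.
* With 20-trial conditions, the calibrated percent change carries an
  irreducible spread of roughly +-3 percentage points between independent
  realization sets.
* The spherical surrogate concentrates the strongest field effects in the
  regions directly under the pads; electrodes there (T5/T6, PO7/PO8) show
  small stimulation-frequency-independent alpha elevations that a
  realistic-geometry model may distribute differently.
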