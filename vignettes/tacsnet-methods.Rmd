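---
title: "Simulating tACS entrainment in spiking brain networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating tACS entrainment in spiking brain networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Transcranial alternating current stimulation (tACS) injects a weak
sinusoidal current through scalp electrodes, hoping to entrain endogenous
rhythms — most often the 8–12 Hz alpha rhythm at the subject's individual
alpha frequency (IAF). Outcomes in human experiments are notoriously
variable: some subjects show large alpha-power increases, others none, some
even decreases. One mechanistic candidate for this variability is cortical
*folding*. The somatodendritic axis of pyramidal cells runs perpendicular
to the cortical sheet, and the polarizing effect of an electric field on a
cell is governed by the field component along that axis — the *normal
component* E⊥ = E · n̂, with n̂ the unit normal of the white/gray-matter
boundary pointing toward white matter. On the crown of a gyrus the field
may depolarize cells (orthodromic, E⊥ > 0); on the opposing wall of a
sulcus the same field hyperpolarizes them (antidromic, E⊥ < 0). A strongly
folded region therefore receives a *bimodal distribution* of effective
stimulation amplitudes with near-zero mean, while a flat region aligned
with the field receives a unimodal, shifted distribution.

`tacsnet` implements a complete in-silico pipeline to study the
consequences of this geometry:

1. **fixtures** — synthetic inputs: gyrified sheet meshes, uniform field
   maps, log-normal structural connectomes, distance-decaying target
   phase-locking-value (PLV) matrices, the three prototypical amplitude
   distributions, and a cohort generator.
2. **efield** — projection of a field map onto mesh normals, per-region
   pooling, and distribution summaries (mean, squared mean, skewness,
   excess kurtosis, mode count).
3. **network** — multi-region spiking networks of adaptive exponential
   integrate-and-fire (aeif) neurons.
4. **engine** — the C++ integrator (spikes, conductances, delays, Poisson
   background, sinusoidal stimulation, LFP).
5. **metrics** — Welch spectra, band power, PLV, simulated functional
   connectivity, working-point selection.
6. **experiments** — single-node entrainment sweeps, intensity
   calibration, Wilcoxon/Holm comparisons, robust regression of
   stimulation efficacy.

## The neuron and synapse model

Each region is a balanced, fully connected population of 80 excitatory and
20 inhibitory aeif neurons:

C dv/dt = −g_L (v − E_L) + g_L Δ_T exp((v − v_th)/Δ_T) − w + I + I_noise −
I_syn + I_ext, with adaptation τ_w dw/dt = a (v − E_L) − w, spike detection
at v_peak = 0 mV, reset to v_reset, w → w + b, and a 2 ms refractory clamp.
The excitatory class reproduces regular-spiking pyramidal dynamics
(C = 104 pF, g_L = 4.3 nS, E_L = −65 mV, Δ_T = 0.8 mV, a = −0.8 nS,
b = 65 pA, τ_w = 88 ms, v_th = −52 mV), the inhibitory class fast-spiking
interneurons (C = 59 pF, g_L = 2.9 nS, E_L = −62 mV, Δ_T = 3 mV,
a = 1.8 nS, b = 61 pA, τ_w = 16 ms, v_th = −42 mV).

Synapses are conductance-based with alpha-function kernels
g(t) = ḡ (Δt/τ) exp(−(Δt − τ)/τ), peaking at exactly ḡ at lag τ
(τ_AMPA = 3.0 ms, E_AMPA = 0 mV; τ_GABA = 3.2 ms, E_GABA = −85 mV).
Within a region every neuron contacts every other (no autapses) with a
1 ms delay; between regions only excitatory neurons project, with maximum
conductance ω · w_kk′/max(w) · ḡ_AMPA (ω the global coupling factor, w the
connectome weights) and delay = fiber length / conduction speed (default
3.9 m/s, i.e. ≈ 4–46 ms for 15–180 mm tracts). Every neuron additionally
receives an independent 2.4 kHz Poisson train onto AMPA-type synapses with
conductance ḡ_noise; this background current is bookkept separately from
I_syn, so the region LFP — defined as the signed sum of recurrent synaptic
currents — reflects network interactions only. (An absolute-sum LFP
variant is available behind `lfp_absolute = TRUE`.)

### Sign conventions

I_syn enters the membrane equation with a minus sign and is computed as
g_AMPA (v − E_AMPA) + g_GABA (v − E_GABA): excitatory drive is
depolarizing, inhibitory drive hyperpolarizing, the standard
reversal-potential semantics. The background current is likewise
depolarizing, I_noise = −g_noise-kernel (v − E_AMPA).

## Numerical scheme

The integrator (`src/engine.cpp`) is fixed-step forward Euler at
dt = 0.1 ms. Two guards matter in practice: the exponential
spike-initiation term is evaluated with v clamped at v_peak, which bounds
the Euler update under arbitrarily strong stimulation, and any non-finite
state aborts with the failure time. Synaptic kernels are *not*
Euler-integrated: each receptor keeps the exact two-state propagation of
the alpha function (g ← (g + dt·h)·e^(−dt/τ), h ← h·e^(−dt/τ), spike
arrivals jumping h by ḡ·e/τ), so kernel peaks are exact regardless of dt.
Spike deliveries are quantized to the step grid; per-region ring buffers
carry the delayed spike counts, and a per-neuron flag ring excludes each
neuron's own delayed spike (no autapses). A single R-side seed initializes
the Poisson background; a simulation is a deterministic function of
(model, stimulus, duration, dt, seed), which the test suite enforces
bit-for-bit. Halving dt moves the baseline spectral peak by well under 2%.

## The working point

Four parameters are deliberately left open by the model family — the
excitatory and inhibitory bias currents and the three maximum conductances
— and were frozen once by a grid search over I_exc, I_inh, ḡ_AMPA, ḡ_GABA,
ḡ_noise requiring (i) an unstimulated single-region LFP spectral peak
inside 8–12 Hz, stable across seeds, with the peak a clean *fundamental*
(no subharmonic of comparable power), and (ii) mean firing rates in
1–20 Hz. The shipped values are I_exc = 12 pA, I_inh = 0,
ḡ_AMPA = 0.05 nS, ḡ_GABA = 1.0 nS, ḡ_noise = 0.08 nS, giving a
fluctuation-driven population rhythm at ≈ 10.5 Hz with excitatory rates
≈ 13 Hz. Two regimes were rejected during tuning: strongly adaptive
limit-cycle configurations whose "alpha" peak was the second harmonic of a
~5 Hz period-doubled burst rhythm (these fragment unpredictably under
stimulation), and high-rate configurations (~19 Hz excitatory) whose heavy
spike-triggered adaptation produced subharmonic switching instead of clean
entrainment.

For multi-region networks the coupling ω is chosen by
`select_working_point()`: among a ladder of candidate couplings, keep
those whose simulated mean PLV stays below a plausibility ceiling (default
0.8 — the criterion "not unrealistically synchronized" needs a number; 0.8
is configurable) and whose median regional peak stays in 8–12 Hz, then
maximize the Pearson correlation between simulated and target
connectivity (upper triangles). The synthetic cohort ships with ω = 0.1,
which preserves regional alpha peaks at modest PLV.

## Stimulation

A stimulus assigns each neuron of region k a current
I_ext(t) = A_i V sin(2πft), with A_i drawn i.i.d. from the region's
empirical normal-component distribution (inverse-CDF over the stored
samples, i.e. resampling), V a global intensity scaling in pA per field
unit, and f the stimulation frequency. Negative A_i means anti-phase
drive — the electrophysiological consequence of an antidromically oriented
cell. In single-node sweeps the prototypical distributions are
dimensionless and each sweep cell rescales them so the *maximum* injected
amplitude equals the cell's intensity on the 0–200 pA axis
(V = intensity / max|A|).

The three prototypical shapes are two-component Gaussian mixtures
(components at target mean ± 0.1, sd 0.03; symmetric weights 0.5/0.5;
asymmetric weights 0.65/0.35 with offsets −0.07/+0.13 so the mixture mean
is preserved) and a Gaussian with sd 0.05, each at mean 0 and mean 0.05.
Only the means are externally prescribed. The Gaussian's width is chosen
comparable to its canonical shift: the shifted Gaussian stands for the
regime in which most cells are driven in phase (the classical 1:1
entrainment regime of shifted distributions), which requires a
predominantly one-signed sample; a Gaussian as wide as the bimodal
mixtures would put a third of the neurons in anti-phase and reproduce the
zero-mean frequency-doubling phenomenology instead of the shifted one.

## Spectral and connectivity read-outs

The power spectral density is Welch's estimate: 2 s Hann-tapered segments
at 50% overlap, zero-padded to a ≤ 0.25 Hz grid over 0–45 Hz. `power` is
the one-sided density whose band integral matches time-domain variance
(verified to 2% on band-limited inputs); `power_norm` divides by total
2–45 Hz power for cross-trial comparisons. Band power is a trapezoidal
integral. PLV follows the mean-resultant definition
|⟨exp(iΔφ)⟩| with phases from the analytic signal (frequency-domain
Hilbert transform) after a zero-phase 4th-order Butterworth band-pass at
8–12 Hz; signals are decimated to ≈ 250 Hz first (the band-pass is
ill-conditioned at a 10 kHz rate) and 1 s is trimmed from each edge before
phase extraction. N in the PLV average is time samples pooled over the
analysis window — with one continuous simulated segment per trial, sample
pooling is the natural reading, and the choice is fixed here for
reproducibility.

The trial-specific IAF is defined per trial, not per region: the median
over cluster regions of the baseline LFP peaks in 8–12 Hz. This is the
frequency an IAF-locked protocol stimulates at, and alpha rise is measured
in the band IAF ± 0.5 Hz for every cluster region
(`alpha_rise()`; an `iaf` argument overrides it). A per-region band
definition would systematically miss the common stimulation frequency and
misreport entrainment as power loss.

## The experiments

**Single-node sweeps** (`single_node_sweep()`) scan stimulation frequency
(canonically 4–18 Hz) × intensity (0–200 pA) for a distribution shape,
recording the LFP peak frequency, its ratio to the stimulation frequency,
and power at both. `classify_sync_state()` names the regimes with a
deterministic tolerance (default 0.05): 1:1 entrainment (|ratio − 1| ≤
tol), 2:1 frequency doubling (|ratio − 2| ≤ 2 tol), "faster" in between,
"slower" below. The doubling arises because with a zero-mean symmetric
distribution half the population is driven in anti-phase: two cohorts
depolarize alternately within each stimulus cycle, so the population
discharges — and hence the LFP — run at twice the stimulation frequency.
Seeds are assigned per (intensity, rep) but not per frequency, so the
intensity-0 column of a sweep reproduces one baseline realization across
all frequencies. Each sweep also carries per-cell peaks of the
repetition-averaged spectrum (`sweep_cells()`): at desk-scale run lengths
the per-repetition Welch argmax can be tipped onto a harmonic of a locked
rhythm by estimator noise, while the averaged spectrum identifies the
fundamental; regime classification therefore reads the pooled cells.

**Intensity calibration** (`calibrate_intensity()`) grid-searches the
scaling constant V for a cohort: per subject and repetition, a baseline
run fixes the trial IAF and baseline band power; stimulated runs at each V
give the cluster alpha rise; V* minimizes the distance between the
group-mean rise and the target (8.02%, the empirical group-level effect
the model is calibrated against). The shipped V grid
(0, 80, 115, 121, 127, 133, 139, 147) spans the full response range and
refines near the operating point, the usual coarse-to-fine practice for a
monotone-flank calibration. Baseline runs are longer than stimulated runs
(`baseline_duration`): the baseline enters every rise both through the
normalizing band power and through the IAF, so extra baseline data buys
more precision per simulated second than extra stimulated data. The
synthetic cohort holds anatomy fixed (it is the study population) while
trial randomness follows the seed.

**Statistics** (`wilcoxon_holm()`, `robust_mlr()`): per-subject one-sided
Wilcoxon signed-rank tests (stimulated > baseline) with Holm's step-down
correction across subjects; W is the rank sum of unfavorable differences
(0 when every repetition increased), with rank-biserial correlation and
common-language effect size as companions. Stimulation efficacy is
modelled by Huber-weighted IRLS regression (tuning constant 1.345,
convergence 1e-8, ≤ 50 iterations) of percent alpha change on seven
standardized predictors — squared mean, skewness, kurtosis and mode count
of E⊥, log2 node strength, baseline mean PLV, and stimulation-frequency
mismatch — with backward elimination at p > 0.05. A separate model on the
power-lowering subset (`lowered_subset_mlr()`) asks which predictors drive
actual decreases. The log2/squared-mean transforms linearize the
heavy-tailed strength distribution and encode the expected sign-symmetry
of the mean's effect.

## What the synthetic data do and do not emulate

The gyrified sheet is a sinusoidally folded square with seed-jittered
interior vertices (irregular triangulation, as real surface meshes are;
`jitter = 0` restores the lattice) and contiguous parcel strips along the
folding axis. It reproduces the one mechanism under study — folding maps a
uniform field onto per-region amplitude distributions from unimodal-shifted
to bimodal-zero-mean — but not cortical curvature in two directions,
regional area differences, or realistic parcel shapes. The synthetic
cohort varies folding depth across subjects under a common montage
direction, so "responders" and "non-responders" emerge from anatomy alone;
real cohorts add sources of variance (skull conductivity, electrode
placement, neuromodulation) that are out of scope. The connectome is
log-normal with uniform 15–180 mm tract lengths; it has the right weight
tail but no spatial embedding or hemispheric structure. Passing tests on
these fixtures therefore demonstrate internal correctness of the
mechanisms, not empirical validity on human data.

Known discretization limits: facet normals of the jittered triangulation
deviate from the analytic surface normal by O(curvature × edge length)
(≈ 1.5° mean at the steepest cohort folds at resolution 64, halving with
each resolution doubling), and on steep folds the per-triangle projection
acquires secondary kernel-density structure beyond the two dominant
opposite-sign modes; mode counting is exact on the smooth prototypical
mixtures that feed the regression predictors.

## Problem sizes

Default protocols follow the reference conditions (50 s runs, 4 s
transient cut, 3 repetitions for sweeps, 30 per intensity for
calibration). The test suite and the acceptance script use the package's
desk-scale protocol: 12 s single-node runs with 2–3 seeds for the regime
checks, and a 4-subject, 4-region cohort for calibration (two repetitions on
the 8-point V grid; 12 s stimulated runs against 26 s baselines). At these sizes the entrainment-regime
medians are stable; single-trial alpha rises retain sampling noise of a
few percentage points, which the group mean averages down.
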