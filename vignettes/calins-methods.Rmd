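---
title: "Methods: classifying calcium responses to infrared neural stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying calcium responses to infrared neural stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

Pulsed 1875 nm infrared light deposits heat in cortical tissue and modulates
neural activity (infrared neural stimulation, INS). Under a two-photon
microscope, the effect on individual neurons is read out as GCaMP
fluorescence: excitatory (hSyn-labelled) neurons tend to show positive,
pulse-train-locked calcium transients, while GABAergic (mDlx-labelled)
interneurons often show a negative deflection during light delivery.
`calins` implements the full quantitative chain that turns raw ROI
fluorescence traces into that conclusion:

1. ΔF/F₀ conversion and trial averaging,
2. a correlation index against a top-intensity reference curve with ±0.2
   threshold classification into positive / negative / unclassified
   responders,
3. signed six-train peak-to-peak amplitudes and 3–10 s peak areas,
4. per-intensity classification fractions and a linear intensity-dependence
   fit,
5. a voxel-grid Monte Carlo model of the infrared light field that defines
   the illuminated region used to bin neurons, and
6. an 80/20 excitatory/inhibitory weighted population time course.

Because raw recordings of this kind are rarely shareable, the package ships
a seeded synthetic-data generator that emulates the two stimulation
paradigms and the statistical structure the analysis assumes, so every
stage is testable end to end.

## Stimulation paradigms

Two trial structures are modelled exactly:

* **multi-train**: 60 s trials; 10 s baseline; then six 0.5 s pulse trains
  (0.25 ms pulses at 200 Hz, 100 pulses per train) at 2.5 s intervals —
  an 18 s stimulation epoch — followed by 32 s of recovery. Train onsets
  fall at 10, 13, 16, 19, 22 and 25 s, partitioning the stimulation epoch
  into six equal 3 s train epochs.
* **long-train**: 30 s trials; 3 s baseline; a single 2 s train
  (400 pulses); 25 s recovery.

Radiant exposure is expressed per pulse at the fiber tip (J/cm²); the
standard intensity ladder is 0, 0.16, 0.29, 0.42, 0.50, 0.59, 0.68 and
0.76 J/cm², with 0 a sham control. All times are seconds from trial start
and all windows are half-open `[start, end)`.

## The synthetic-data generator

`simulate_trial()` builds a raw fluorescence trace as
`F = F0 (1 + ΔF/F0)` with four additive ΔF/F₀ components:

* **Evoked transients.** One calcium transient per pulse train:
  `response_sign × A(Q) × k(t − onset)`, where `k` is a
  difference-of-exponentials kernel normalised to unit peak with a 0.18 s
  rise and 1.5 s decay by default. Indicator kinetics are not constrained
  by any measurement here; the constants are parameters, not claims.
* **Intensity–amplitude law.** `A(Q) = gain × max(0, Q − θ)` with threshold
  θ = 0.1 J/cm². Only monotonicity of response with radiant exposure is
  established phenomenology; threshold-linear is the simplest law with a
  genuine sham (A(0) = 0) and is configurable.
* **Fluoro-thermal artifact.** Heating transiently dims GCaMP fluorescence
  regardless of calcium (dead-animal controls show dips during light
  delivery). The generator models this as a boxcar dip during each train
  whose depth scales linearly with intensity and is parameterised at the
  top 0.76 J/cm² intensity. Whether negative deflections in interneurons
  reflect suppressed spiking or this artifact is an open question
  experimentally; the generator exposes both mechanisms (`response_sign`
  and `artifact_depth`) as separate knobs and takes no stance. The artifact
  depth defaults to 0 so recovery tests isolate the classifier.
* **Spontaneous activity and noise.** A homogeneous Poisson event process
  (default 0.05 events/s, amplitude 0.2 ΔF/F₀) convolved with the same
  kernel, plus additive Gaussian noise on ΔF/F₀ (default SD 0.05). Reported
  spontaneous rates and noise levels are not available for this
  preparation, so these defaults are chosen once as values typical of
  cortical GCaMP6s imaging at ~30 Hz and are configurable.

What the generator does **not** emulate: pixel-level image formation and
photon shot noise (synthesis is at trace level), motion artifacts,
neuropil contamination, astrocytic or dendritic signals, bleaching, and
correlated network activity between neurons. Passing recovery tests
therefore show that the analysis chain is correct under its own assumed
signal model — not that it is robust to every failure mode of real data.

All randomness flows from one master seed: `simulate_dataset()` draws
sub-seeds (for the population, the randomised trial order, and each
neuron × trial trace) from the master seed via `sample.int`, so identical
config + seed gives bit-identical datasets while traces remain
independently reproducible.

## Trace processing

ΔF/F₀ is `(F − F0)/F0` with `F0` the mean over the pre-stimulus baseline —
pinned to the full baseline window (0–10 s multi-train, 0–3 s long-train)
and overridable. Non-positive `F0` is a hard error rather than a silent
division blow-up.

The display smoother is a scalar constant-level Kalman filter
(`estimate_t = estimate_{t−1} + k_t (obs_t − estimate_{t−1})`) with unit
measurement-noise variance, process-noise variance 0.05 and initial gain
0.5; `gain = 1` is an exact pass-through and the first output equals the
first input. This is a deliberate scalar re-expression of the image-stack
Kalman filters commonly used for display in this field. Whether published
correlation metrics of this kind are computed on smoothed or raw averages
is typically ambiguous; `calins` computes metrics on **raw** trial averages
by default and exposes `smooth = TRUE` in `average_responses()` to match
the other convention.

## Response metrics and classification

The **reference curve** is the pointwise mean, over all neurons of the
(excitatory) cohort with no pre-selection, of the trial-averaged ΔF/F₀ at
the top intensity, restricted to the stimulation window (10–28 s). No
pre-selection is applied because none is documented for this procedure, and
using one shared positive template for both cohorts is what makes
anti-phase inhibitory responses score *negative* correlations. The
**correlation index** is the Pearson correlation of a neuron's
trial-averaged curve with the reference over that window; classification is
strict (`> 0.2` positive, `< −0.2` negative, else none — exactly 0.2 is
"none"), and zero-variance curves are labelled undefined (classified
"none"), never silently zero.

The **amplitude** is the mean of six per-train peak-to-peak excursions
(max − min within each 3 s train epoch, onset to next onset, the last epoch
of equal duration), signed by the correlation index — a negative
correlation means the light-locked modulation is a decrease. Peak-to-peak
is used because a train-locked dip and a train-locked transient should
measure comparably.

The **3–10 s peak area** for the long-train paradigm follows the standard
peak-area rules of commercial curve-analysis software with its default
parameters: baseline fixed at 0; maximal contiguous above-zero segments
are candidate peaks; segments whose maximum is less than 10% of the
min-to-max distance (above the window minimum) are ignored; retained
segments are integrated trapezoidally with interpolated zero crossings.

Percentages in the per-intensity classification table are rounded to one
decimal, half away from zero, to match how such tables are printed (base R
`round()` would round half to even). The intensity-dependence fit is
ordinary least squares of mean correlation on radiant exposure, reported as
slope/intercept/R²/p with broom-style `tidy()`/`glance()` methods. Rank
tests (`rank_compare()`) delegate to `stats::wilcox.test`: exact null
distributions for small samples without ties, normal approximation with
tie and continuity correction otherwise; all-zero paired differences return
p = 1 and fully tied input is flagged undefined.

## Monte Carlo light transport

The tissue is a cube (default 4 mm side at 10 μm voxel pitch, 400³ voxels)
of three horizontal layers — ACSF, coverglass, cortex — stacked along z.
Because the medium varies only with depth, the photon walk uses exact
layered propagation (hop/drop/spin with boundary handling at z interfaces)
while depositing absorbed weight into the Cartesian voxel grid; for this
geometry that is equivalent to a per-voxel walk and substantially faster.
Specifically:

* dimensionless step `−ln ξ`, converted by the local `μa + μs`;
* partial-weight absorption `μa/(μa + μs)` deposited per interaction into
  the enclosing voxel;
* Henyey–Greenstein deflection with the local anisotropy `g`;
* Snell refraction with unpolarized-average Fresnel reflection (and total
  internal reflection) at layer interfaces;
* Russian roulette below weight 10⁻⁴ with survival probability 0.1.

Roulette creates and destroys weight with zero expectation; the run keeps
an exact ledger (`launched + created − destroyed = absorbed + escaped`)
that balances to floating-point precision for every seed, and in the
pure-absorber regime (no roulette events) the plain
`launched = absorbed + escaped` identity holds directly. Lateral cube
faces and the top/bottom are open boundaries: exiting weight is booked as
escaped.

Optical properties at 1875 nm for this preparation are not published;
defaults are literature-typical placeholders exposed in configuration —
water-dominated absorption μa = 3 mm⁻¹ in ACSF and cortex, cortical
scattering μs = 5 mm⁻¹ with g = 0.9, refractive indices 1.33/1.52/1.36 —
with layer thicknesses 0.5 mm ACSF and 0.17 mm (#1.5) coverglass, the
cortex filling the rest. The fiber (200 μm core, NA 0.37) is tilted 45° to
the horizontal in the x–z plane with its tip on the glass top surface;
launch positions are uniform over the tilted core disc and launch
directions have `sin θ` uniform in `[0, NA/n]` about the axis. A scalar
glass-transmission correction (default 1) multiplies the launch weight.

The **illuminated region** at an imaging depth is the fluence slice
thresholded at 10% of the plane maximum (the published delineation of such
regions is qualitative; 0.1 is a configurable convention), with an
equivalent geometric cone (apex at the tip, axis refracted into cortex,
half-angle `asin(NA/n_cortex)`) reported as a fallback. Neurons are binned
`illuminated` vs `weakly_illuminated` by mask membership at their plane;
out-of-grid neurons bin `weakly_illuminated` with a warning.

## Population model

`population_sum()` forms the pointwise convex combination
`w_e × excitatory + w_i × inhibitory` of the two cohort grand-mean ΔFF₀
curves, default 0.8/0.2 — the standard excitatory:inhibitory ratio of
cerebral cortex. The operation is intensity-agnostic; the pipeline uses the
0.42 J/cm² curves when present, as a mid-ladder intensity with robust
responses.

## Numerical conventions and degenerate inputs

* Sample k (1-based) is at time `(k−1)/fs`; windows are half-open, so the
  10–28 s window at 30 Hz covers samples 301–840.
* Strict threshold inequalities; correlation exactly at a threshold is
  unclassified.
* Undefined statistics (zero-variance correlation, fully tied rank tests)
  propagate as `NA` with explicit classification "none", never as 0.
* Empty trace lists, mismatched lengths, ragged tables, non-integer masks,
  non-positive F₀ and unknown paradigm kinds are named errors.
* Trial order randomisation, population sampling and per-trace noise are
  seeded independently from the master seed so subsets are reproducible.

## Problem sizes in tests and reproduction script

The test-suite and the reproduction script (`scripts/acceptance.R`) choose
problem sizes that give clear statistical signal while keeping a full run
in the minutes range on one core: Monte Carlo checks use a 2 mm cube at
20 μm pitch with 10⁵ photons (the Beer–Lambert depth profile and weight
ledger do not require the full 400³ default grid); responder-fraction
recovery pools 10–20 replicate cohorts of 200 neurons at the top intensity
(classification at 0.76 J/cm² is what the recovered fraction measures);
monotonicity uses one 100-neuron cohort across the full intensity ladder
with six trials per intensity. Recovery and monotonicity runs set the
spontaneous-event rate to zero — the "high SNR" condition that isolates
classifier behaviour from background transients.

## Known limitations

* Trace-level synthesis cannot validate segmentation, motion correction or
  neuropil handling; the pipeline deliberately starts from extracted ROI
  traces.
* The layered transport model cannot represent lateral tissue
  heterogeneity; a fully voxel-heterogeneous walk would be needed for
  e.g. blood vessels.
* Heat diffusion and temperature rise are out of scope; the light field is
  a proxy for where energy is deposited, not a thermal model.
* The intensity-dependence fit coefficients obtained on synthetic cohorts
  depend on the assumed amplitude law and noise level and are qualitative
  references only.
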