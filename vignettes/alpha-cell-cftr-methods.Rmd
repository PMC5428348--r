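---
title: "Methods: alpha-cell electrophysiology with a CFTR chloride current"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alpha-cell electrophysiology with a CFTR chloride current}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cftralpha)
```

## Scientific setting

Pancreatic alpha cells secrete glucagon, the body's main hyperglycemic
hormone. Their electrical activity is set by the balance between an
ATP-sensitive potassium conductance (`g_KATP`, which falls as glucose
rises and so acts as the model's glucose dial), a depolarizing leak, and
the voltage-gated Na^+^, Ca^2+^ and K^+^ channels that generate action
potentials. CFTR — the cAMP-activated chloride channel mutated in cystic
fibrosis — is present in alpha cells, and its activation adds a chloride
conductance reversing near −60 mV. Because that reversal sits close to
the alpha cell's operating range, CFTR acts mostly as a stabilizing
shunt: it slows firing in active cells and can silence cells that sit
near the activity threshold, which is the proposed mechanism by which
cAMP-activated CFTR restrains glucagon secretion and by which
CFTR-inhibition (or loss-of-function mutation) releases it.

This package implements that picture end to end: a conductance-based
alpha-cell model with a passive CFTR current, the in-silico protocols
that probe it, the patch-clamp and secretion-assay quantification
procedures used on the corresponding experiments, and seeded synthetic
generators for every input, so every estimator ships with a round-trip
test against known truth.

## The model

The membrane equation is

$$C_m \frac{dV}{dt} = -\big(I_{Na} + I_{CaT} + I_{CaL} + I_{CaPQ}
  + I_K + I_{KA} + I_{KATP} + I_L + I_{CFTR}\big),$$

with units fixed package-wide as mV, ms, nS, pA, pF (so nS·mV = pA and
pA/pF = mV/ms). Every gating variable follows first-order relaxation
$dx/dt = (x_\infty(V) - x)/\tau_x$ toward a Boltzmann steady state
$x_\infty(V) = 1/(1+\exp((V_x - V)/s_x))$; a negative $s_x$ encodes
inactivation. The CFTR current is strictly passive,
$I_{CFTR} = g_{CFTR}(V - V_{Cl})$ with defaults $g_{CFTR}$ = 0.100 nS
and $V_{Cl}$ = −60 mV, and with $g_{CFTR} = 0$ the system reduces
exactly — bitwise in the solver output — to the base model. The
store-operated-current variant of this model family is deliberately not
implemented (`soc_enabled` is pinned to `FALSE`).

The fixed kinetics follow the lineage of the Watts–Sherman mouse
alpha-cell model, with rate placements calibrated in-package so that the
three reference scenarios produce the canonical regime pattern (next
section). Two mechanisms coexist by design:

* a **hyperpolarized oscillator** around −50 mV baseline, driven by the
  T-type Ca^2+^ window current (slow inactivation, $\tau_h$ = 80 ms, is
  the cycling variable) with Na^+^ recruited for the overshoot — this is
  the low-glucose, large-spike regime;
* a **depolarized oscillator** around −40 mV baseline, carried by the
  high-voltage-activated L/PQ Ca^2+^ conductances against the delayed
  rectifier, with a broad Na^+^ window (inactivation slope −7 mV)
  keeping regenerative drive alive — this is the 6 mM-glucose,
  small-spike regime.

Because the chloride reversal (−60 mV) lies below both operating
points, adding `g_CFTR` both hyperpolarizes slightly and, more
importantly, loads the membrane with a passive shunt. Near the activity
boundary that shunt is decisive: at `g_KATP` = 0.300 nS the model cell
is silent with CFTR operating and fires once it is removed, while at
0.200 and 0.270 nS it fires in both states but faster without CFTR.

### Scenarios and glucose mapping

Glucose is represented only through anchor scenarios, never a continuous
map: `glucose6` (`g_KATP` = 0.200 nS, `g_L` = 0.200 nS), `glucose1`
(0.270, 0.150) and `glucose1_highkatp` (0.300, 0.150, still within the
experimental range at 1 mM glucose), all with `V_L` = 0 mV and
`g_CFTR` = 0.100 nS.

### Numerics

Integration uses `deSolve::lsoda` (stiff-capable, adaptive) at relative
tolerance 1e−8, absolute tolerance 1e−10, with the maximum internal
step capped at 1 ms so no action potential can be stepped over, and a
fixed 0.1 ms output grid for reproducible spike detection. The default
initial condition is V = −60 mV with gates at steady state, followed by
a 2 s burn-in that is discarded: analyses describe steady behaviour, not
transients. Parameter switches (CFTR inhibition) are instantaneous
conductance changes; integration restarts at the event with the state
carried over continuously. No inhibitor binding kinetics are modelled —
none are characterized.

Two runs with identical configuration are bitwise identical. Halving
the tolerances leaves the spike count of a 3 s run unchanged and moves
spike times by under 2 ms; pointwise voltage comparison between
tolerance levels is meaningful only for silent traces (where it agrees
to ~1e−11 mV), because on a 50 mV/ms upstroke a microsecond-scale
phase shift already produces tenth-of-millivolt pointwise differences.
The convergence tests are therefore phase-aware by design.

## Protocols and readouts

Spikes are upward crossings of −20 mV separated by at least 10 ms
(alpha-cell spikes here overshoot ~0 mV, so the threshold is
comfortably inside the waveform); frequency is count over window. The
switch protocol runs 10 s with the CFTR conductance removed at 5 s, and
analyses the final 2 s of each phase, excluding a 200 ms settling
margin after the switch. A trace is *silent* if and only if its
windowed frequency is zero.

The **secretion proxy** is a deliberately labelled construction, not a
measured quantity: the time average of a Hill function
(exponent 4, half-saturation 20 pA) of the total Ca^2+^-current
magnitude, gated to exactly zero on silent windows. The Hill form
rewards the large Ca^2+^ transients of full spikes over tonic window
currents, which is what makes the bell-shaped frequency/secretion
dependence on `g_KATP` expressible: at very low `g_KATP` the cell
depolarization-blocks (proxy 0 via the spike gate), at intermediate
values it fires with large Ca^2+^ entry, and above ~0.3 nS it is
silent. With CFTR operating the upper activity boundary shifts left —
`activity_boundary()` makes that one number. No quantitative secretion
claim attaches to the proxy.

## Analysis procedures

**Ramp I–V.** Slope conductance is the least-squares slope of I on V
inside a voltage window, default −100 to −50 mV (negative potentials,
where the chloride driving force is clean). Condition differences
isolate components: forskolin − control is the cAMP-activated current,
forskolin − inhibitor the CFTR-dependent current. The CFTR fraction is
defined on *slopes* (ratio of the two difference slopes), because
pointwise current ratios diverge near the reversal. The reversal
potential is the x-intercept of the line fitted to the CFTR-dependent
difference inside −90 to −30 mV; positive potentials are excluded
because inhibitor block there may be voltage dependent. Conductance
density is 1000·g/C_m (pS/pF). Cells are analysed individually and
summarized per-cell-then-average.

**Single channels.** Records (10 kHz) are low-pass filtered at 500 Hz
with a linear-phase FIR applied as a centred symmetric convolution
(zero net delay, so event times are unbiased). The closed baseline is
the mode of the amplitude histogram; the open level is the second
density peak below it (openings are downward); the amplitude is the
peak separation, reported as a positive magnitude. States are assigned
by half-amplitude threshold with 10% hysteresis, and p~o~ is the open
fraction of samples, assuming one channel per patch; when several open
levels are detected the result is flagged and reported as NPo. A
unimodal histogram returns p~o~ = 0 with an undefined amplitude rather
than an error.

**Capacitance trains.** Exactly ten per-pulse increments
(500 ms, −70 to 0 mV). The summaries are Σ~1–2~ (first two pulses,
readily releasable pool), Σ~3–10~ (latter eight) and their sum Σ~all~,
computed so the additivity identity holds exactly in floating point.

**Secretion tables.** Strictly descriptive (no hypothesis testing, by
design): technical quadruplicates are pooled into per-experiment means
first, and dispersion is always computed over independent donors or
experiments. Fold changes are ratios of those means within a
(hormone, species, glucose) block relative to the block's baseline,
with delta-method standard errors; cross-glucose folds are undefined.

**Imaging.** The membrane-to-cytosol ratio P1/P2 uses a Euclidean
distance transform of the (single, connected) cell mask: P1 is the mean
intensity in the band within 0.5 µm of the boundary (inward only —
signal outside the mask is ignored), P2 the mean over the remaining
interior. Pixel size must be supplied because the band is defined in
micrometers.

## Synthetic data: what it does and does not show

Each generator is seeded explicitly (no implicit RNG state), returns
its ground truth alongside the data, and defaults to the point
estimates the analyses are meant to recover, so default round-trips
double as end-to-end checks:

| quantity | default |
|---|---|
| CFTR conductance density | 61 pS/pF (C_m = 5 pF) |
| chloride reversal | −61 mV |
| CFTR share of activated current | 76% |
| single-channel amplitude | 0.7 pA (−50 mV, 10 kHz, 60 s) |
| open/close rates | 30 / 70 s⁻¹ (stationary p~o~ = 0.3) |
| human forskolin fold (2.8 mM glucose) | 2 |
| human forskolin fold under 50 mM K^+^ | 3 |
| mouse GlyH-101 increment over forskolin (1 mM) | +30% |
| membrane/cytosol intensity ratio | 2 (0.5 µm band) |

Dispersions are package choices, sized for informative n = 5 / N = 9
recovery rather than fitted to any published error bar: lognormal
cell-to-cell conductance jitter (sdlog 0.25, mean-corrected so the
population mean is exact), ±5 percentage-point share jitter, 2 pA ramp
noise, 0.2 pA channel noise, lognormal donor baselines (sdlog 0.4)
with 15% replicate CV and 10% per-experiment effect jitter. The mouse
forskolin fold (2.5) and the 50 mM K^+^-alone fold (1.5) have no
published point value; they are plausible scales and nothing is
asserted about them.

What the generators deliberately omit: voltage-dependent inhibitor
block (the ramp model is linear, matching the negative-potential
analysis window), baseline drift and multi-channel patches in
single-channel records, paracrine islet interactions, and assay
calibration effects. Passing round-trip tests therefore demonstrates
estimator correctness under the stated statistical structure, not
robustness to every artefact of real recordings.

## Problem sizes and known limitations

The shipped tests run the switch protocol at 10 s simulated time per
scenario (plus two tolerance-perturbed repeats), scans on coarse grids
at 2–4 s per point, a 60 s single-channel record, and 200-seed
Monte-Carlo estimator checks — sizes chosen to give clear statistical
verdicts on a single CPU in minutes.

Limitations worth knowing: the base-model kinetics are a calibrated
reconstruction of the published lineage, not a transcription of any
specific code release, so absolute firing rates should be read as
qualitative (the regime pattern, not the Hz values, is the validated
object and is stable to ±20% solver-tolerance perturbation); the
secretion proxy is a constructed readout; dwell-time (burst) analysis,
series-resistance artefacts and leak-subtraction protocols beyond
condition differencing are out of scope; and p~o~ reporting assumes one
channel per patch unless the level detector says otherwise.
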