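---
title: "ctcfit: models, fitting, and the in silico transforming clamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctcfit: models, fitting, and the in silico transforming clamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the two cell models
and the reductions applied to them, the numerical scheme, the
action-potential metrics and their conventions, the genetic algorithm, the
closed-loop clamp, and the synthetic-cell generator that stands in for
patch-clamp recordings. It also records the design choices made where the
published description leaves the design open, and what the package's tests
do and do not establish.

## The two cell models

### Target / target-canceling model: modified Pandit neonatal mouse

The native cell is represented by the Pandit rat left-ventricular
(epicardial) formulation adapted for neonatal mouse work. Membrane currents:
fast Na⁺ (`gNa`, gates m, h, j), L-type Ca²⁺ (`gCaL`, gates d, f11, f12 and
a Ca²⁺-inactivation gate), Ca²⁺-independent transient outward K⁺, the
steady-state outward K⁺ (`gss`, gates r_ss, s_ss), hyperpolarization-
activated current (`gf`, gate y), inward rectifier (`gK1`), three ohmic
backgrounds, the Na⁺/K⁺ pump, Na⁺/Ca²⁺ exchange, and a sarcolemmal Ca²⁺
pump. Forward-mode temperature is the formulation's native 295 K.

Three deliberate modifications define this package's variant:

1. **Fixed intracellular ion concentrations.** [K⁺]ₒ = 5.4, [Na⁺]ₒ = 140,
   [Ca²⁺]ₒ = 1.2, [Na⁺]ᵢ = 8.6, [K⁺]ᵢ = 142 mM, [Ca²⁺]ᵢ = 0.079 µM. With
   Ca²⁺ fixed, the sarcoplasmic-reticulum subsystem drops out and the
   Ca²⁺-dependent L-type inactivation gate relaxes to a constant (≈ 0.992).
   This is what makes single-beat evaluations cheap enough for during-
   experiment fitting, and it mirrors how the real-time variant of the
   model is run.
2. **The transient outward current is split into two independently scaled
   components**: a fast one (`gt`, inactivation gate s, weight 0.886) and a
   slowly inactivating one (`gKslow`, gate s_slow with a seconds-scale time
   constant, weight 0.114). Mouse ventricle expresses I_to,f and I_K,slow
   as distinct conductances, and the fitting method tunes them separately;
   at `gt = gKslow` the sum reproduces the parent model's single current
   exactly.
3. **Neonatal conductance rescaling.** `gt = gKslow = 0.00875 µS` (25% of
   the adult rat epicardial value), `gCaL = 0.015 µS`, `gNa = 0.8 µS`.
   Neonatal ventricular myocytes express far less transient outward and
   L-type current than adult rat epicardium; quantitatively, these values
   were calibrated — once, before any test was written — so that scaling
   `gss` and `gKslow` by a common factor sweeps APD₈₀ monotonically over
   ~20–164 ms, comfortably covering both the 40–120 ms template range and
   the ~40–160 ms reach the six-gene search box is designed to have. With
   adult rat conductances the transient outward current dominates
   repolarization and no setting of `gss`/`gKslow` produces an APD₈₀ above
   ~39 ms, so the published template construction would be impossible.

The stored initial condition is the unstimulated steady state, obtained by
relaxing the system for 120 s and frozen in the package source; a further
1 s of free-running integration moves V by less than double precision
resolution.

### Recipient model: reduced ten Tusscher–Panfilov human ventricle

The recipient is the ten Tusscher–Panfilov human ventricular formulation
(epicardial gating), reduced by fixing the intracellular concentrations at
diastolic values ([Na⁺]ᵢ = 11.6, [K⁺]ᵢ = 138.3 mM, [Ca²⁺]ᵢ = 0.2 µM),
leaving twelve state variables. Two closures make the reduction
well-behaved, both fixed before tests were written:

* **Effective submembrane Ca²⁺ in the L-type driving force**
  (`CaLdrive = 0.09 mM`). The GHK-like driving-force term evaluated at
  diastolic Ca²⁺ has no reversal below +140 mV; during a real AP the
  subspace Ca²⁺ under the channel reaches tens of µM and pulls the reversal
  to ≈ +60 mV. Without this closure the reduced model locks into a +57 mV
  plateau and never repolarizes.
* **Ca²⁺-dependent inactivation absorbed into the conductance.** In the
  parent model the fCa gate sits near 0.18 throughout the plateau; the
  reduction freezes that factor into `gCaL` (3.06 × 10⁻⁵, ≈ 0.175 × the
  parent value). Together with the 2006-revision delayed-rectifier and pump
  magnitudes (`gKr` 0.153, `gKs` 0.392, `pNaK` 2.724, `gpCa` 0.1238), this
  was calibrated once against the parent model's published epicardial
  behavior: APD₉₀ ≈ 300 ms at 1 Hz with the characteristic
  spike-notch-dome morphology (this build: APD₉₀ ≈ 299 ms, notch ≈ +12 mV,
  dome ≈ +29 mV).

## Numerical scheme

The membrane potential advances by forward Euler — dV/dt = −(î_ion +
î_applied), all currents capacitance-normalized (pA/pF) and
outward-positive — at 0.1 ms for the mouse model and 0.01 ms for the
recipient. Hodgkin–Huxley gates use the exact exponential (Rush–Larsen)
update: plain Euler is unconditionally unstable for them at these steps
(the mouse Na⁺ activation gate has τ ≈ 0.012 ms near rest, an order of
magnitude below the step), and the exponential update is the standard
choice in real-time dynamic-clamp rigs. Halving either step changes APD₈₀
and APD₉₀ by well under 0.5 ms (enforced by test).

An opt-in fast-exponential mode exists for speed measurements
(`sim_settings(fast_exp = TRUE)`). It uses a range-reduced degree-6
polynomial (relative error ~10⁻⁹). Bit-trick exponential approximations of
the Schraudolph type were evaluated and rejected: their ~3% error
qualitatively changes the mouse AP (repolarization failure), because the
model sits near a repolarization-reserve boundary. Correctness tests always
run exact.

## AP metrics and their conventions

* **Resting potential**: the sample immediately preceding the stimulus
  onset.
* **Upstroke onset**: the linearly interpolated time of the first upward
  crossing of −40 mV (avoiding the stimulus foot); a sample exactly at
  threshold counts as the crossing. The same time anchors every APD measure
  and the SSD alignment, giving one consistent convention.
* **APD₈₀ (mouse definition)**: time from onset to the first downward
  crossing of 0.8 × V_rest (80% of the way from 0 mV to rest).
* **APD₃₀/₅₀/₉₀ (amplitude definition)**: time from onset to repolarization
  by the stated fraction of the AP amplitude (peak − rest); used for
  CTC-converted beats, with V_rest taken per beat.
* **SSD**: both traces aligned at their own −40 mV crossings, resampled by
  linear interpolation onto the coarser of the two sample grids, squared
  differences summed over 300 ms. Symmetric, non-negative, zero iff the
  aligned windows agree.
* **Conversion accuracy** (`trace_supnorm_diff`): sup-norm in
  upstroke-aligned time over [−50, +500] ms around the crossing, excluding
  (−2, +5) ms. On the excluded steep segments (stimulus foot ~30 mV/ms,
  upstroke ~300 mV/ms, Na-spike peak), comparing trajectories integrated at
  0.1 vs 0.01 ms produces spikes of tens of mV that shrink linearly with
  the loop step and say nothing about conversion quality; outside that
  window the ideal conversion agrees to ≈ 1.1 mV at default steps.

## Template suite

The baseline canceling-model selection builds nine mouse models with APD₈₀
labels 40–120 ms. The published construction varies `gss` and `gKslow`; the
member-level values are not restated, so this package calibrates along a
one-dimensional path: both conductances scaled from baseline by a common
factor s ∈ [0.06, 12], on which APD₈₀ is monotone decreasing (verified at
run time; below s ≈ 0.05 the model stops repolarizing). Each label is found
by bisection in log s to ±0.5 ms and verified by a fresh paced simulation;
every verified member re-measures within ±1 ms of its label. Selection
takes the nearest label, with exact ties resolved toward the shorter APD —
an arbitrary but deterministic rule.

## Genetic algorithm

Six genes, expressed as fractional changes applied multiplicatively to the
starting-point model (the 60 ms template member): `gNa`, `gK1`, `gt` ∈
[−0.9, +0.9]; `gCaL` ∈ [−0.1, +0.1]; `gss`, `gKslow` ∈ [−0.9, +2.0].
Population 40, 15 generations (the random initial generation counts),
giving 600 single-beat evaluations per fit.

* **Selection**: tournament without replacement — two random
  pair-partitions of the population per generation; each pair's lower-error
  member enters the mating pool in win order, so the best individual enters
  exactly twice and the worst never. Equal errors: the first-drawn wins.
* **Crossover** (probability 0.9 per pair): simulated binary crossover with
  index 10. Per gene a spread factor β is drawn from the polynomial
  distribution (β = (2u)^(1/11) for u ≤ 0.5, else (2(1−u))^(−1/11)) and the
  blended values ((1±β)p₁ + (1∓β)p₂)/2 are assigned to the children,
  exchanged with the genewise swap probability 0.5. The description of the
  operator reads "parameter values are swapped in the progeny", naming the
  0.5 as a swap probability; the alternative reading (0.5 as a per-gene
  blend probability with non-blended genes copied) was implemented and
  compared — the swap reading also converges visibly better, consistent
  with it being the intended operator. Children are clipped to bounds.
  Non-crossing pairs become their own children.
* **Mutation**: polynomial, index 20, probability 0.1 per gene, centered on
  the current value, offset δ·(upper − lower), clipped.
* **Elitism**: after the children are evaluated, the previous generation's
  best (with its cached error — no re-evaluation) replaces the worst child.
* **Failure handling**: a candidate whose simulation blows up or whose AP
  has no measurable upstroke receives a finite worst-case sentinel error of
  10⁹ mV², so selection can proceed.
* **Reproducibility**: one R RNG stream per run, seeded from the config;
  draws are consumed in a documented order (initialization, then per
  generation: two tournament permutations, per-pair crossover decision,
  per-gene spread and swap draws, per-gene mutation decision and offset).

The phenotype is a single 1 Hz paced beat from the stored resting state at
0.1 ms — no pre-pacing, consistent with a 600-evaluation budget measured in
seconds. What the GA recovers is the *waveform*, not the genotype: the
model is sloppy, and distinct conductance combinations yield near-identical
APs. Tests therefore assert SSD and APD closeness only.

## The closed loop

Each loop cycle (default 0.1 ms): (1) read the target voltage, add the
liquid-junction-potential correction (0 in silico; −3 mV experimentally);
(2) advance the canceling model one loop step and the recipient model ten
sub-steps of 0.01 ms, both clamped at that voltage; (3–4) difference their
total currents. In capacitance-normalized units the published scaling by
K_c = C_target/C_cancel and K_r = C_target/C_recipient cancels identically,
so î_diff = î_recipient − î_cancel; the record-level identity and the
invariance of the normalized record to C_target are asserted exactly in
tests. (5) The pacing stimulus and the seal-leak compensation are added to
the difference current — the stimulus travels through the injection path,
not as a separate model input; (6) the result is injected into the
free-running target, which also carries the physical ohmic seal leak
V/R_seal when a finite seal is configured (compensation makes a finite,
compensated seal an exact no-op, which is also asserted). With R_seal = ∞
and zero LJP the loop is bit-identical to the default configuration.

When target and canceling model agree state-for-state, the injected current
cancels the target's ionic current exactly and the loop integrates the
recipient's membrane equation with the multirate scheme; the converted AP
then matches the free-running recipient to ≈ 1.1 mV (blanked sup-norm) and
≈ 0.4 ms in APD₉₀. A canceling model with a longer intrinsic APD than the
target (70 vs 60 ms) lacks repolarizing current where the target has it,
under-compensates, and yields a converted AP strictly shorter than the
ideal conversion — the package reproduces this failure direction.

The initial states are each model's stored resting state; the first ~50 ms
of a CTC run show the target relaxing from mouse rest (−80.4 mV) to the
recipient's resting dynamics (−85 mV), which is why the default stimulus
onset sits at 100 ms. The default stimulus amplitude is 1.5 × the
diastolic threshold of the model being paced (1.5 × the larger of target
and recipient thresholds in the loop), computed by bisection to 1 pA/pF and
cached; the experimental 0.9 nA figure is cell-specific and does not
transfer to the models.

## Pseudo cells

`generate_pseudo_cell()` emulates the recording protocol behind the fitting
objective: ten consecutive 1 Hz beats, averaged after alignment at the
stimulus onset. Variability has two components, both tunable defaults
rather than measured ground truth: per-beat lognormal multiplicative jitter
on the six key conductances (unit mean, CV 3%) and additive Gaussian
observation noise (SD 0.5 mV) on every sample. The hidden genotype is drawn
uniformly inside the GA bounds, rejection-sampled until its noiseless AP
has a measurable APD₈₀ in 40–120 ms — the span of the recorded population
the template suite was built around. Without that restriction the uniform
box produces cells no recording resembles, including ones that never
repolarize. Beats are simulated independently from the resting state, so
given the jitter they are i.i.d.

Features of real recordings deliberately *not* emulated: rate-dependent
beat-to-beat memory, correlated (1/f, line-frequency) noise, electrode
artifacts (series resistance, imperfect capacitance measurement), drift
over the recording, and the room-temperature/model-temperature kinetics
mismatch. A GA fit passing the recovery criterion on pseudo cells therefore
shows that the optimizer recovers waveforms generated *by the model family
it searches*, under calibrated noise — not that it fits any real myocyte.

The recovery experiment reports, per cell, the final best SSD against the
cell's beat-to-beat noise floor (the median SSD between individual beats
and their average); a fit at or below that floor is "within the naturally
occurring beat-to-beat variability". Under the default conditions (10 cells,
seeds 1–10, 600 evaluations each) the median final SSD is ≈ 0.6 × the
median floor.

## Problem sizes and runtime

The test suite runs in ~2.5 min on one CPU: the reference-equivalence
oracles integrate one mouse beat (10⁴ steps) and 400 ms of the human model
(4 × 10⁴ steps) in pure R; the recovery experiment fits 10 pseudo cells at
the full 40 × 15 budget; everything else is seconds. The acceptance script
evaluates 64 bound-box corners plus two coordinate-descent refinements
(~180 single-beat simulations, ~2 s).

## Known limitations

* Both models are transcriptions of the published formulations with the
  reductions described above; supplement-level per-member conductance
  values of the original template suite are not reproduced — the
  calibration path absorbs them by design.
* The Faber–Rudy guinea-pig recipient is not implemented; the loop accepts
  any model exposing the package's stepping contract (kind dispatch), which
  is the plugin seam.
* Fixed concentrations remove calcium-transient physiology entirely; the
  clamp transforms the voltage waveform only.
* The first paced beat from the stored resting state carries a ~2 ms
  slow-gate APD transient; quasi-stationarity holds from the second beat.
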