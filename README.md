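# ctcfit

Rapid genetic-algorithm fitting of a neonatal-mouse ventricular
action-potential model, and an in silico **cell-type transforming clamp
(CTC)** that uses the fitted model to make a mouse myocyte express a
human-like action potential.

## The problem

Murine ventricular action potentials (APs) are short and triangular; human
APs are long, with a spike-notch-dome plateau. Many questions about drugs
and mutations concern the human plateau, so results obtained in mouse
myocytes translate poorly. The CTC is a dynamic-clamp variant that bridges
the species gap in real time: a patched *target* myocyte is coupled to two
computational models evaluated at the measured membrane potential *V* —

* a **target-canceling model** of the native cell, with total
  capacitance-normalized current *î*<sub>cancel</sub>(V), and
* a **recipient model** of the desired cell type (here a reduced ten
  Tusscher–Panfilov human ventricular model), with current
  *î*<sub>recipient</sub>(V)

— and each cycle injects the difference current

> *î*<sub>diff</sub> = *î*<sub>recipient</sub> − *î*<sub>cancel</sub>

(plus stimulus and seal-leak compensation) back into the cell. If the
canceling model matches the cell's intrinsic currents exactly, the membrane
equation reduces to the recipient model's, and the mouse cell "becomes"
human-like. The quality of the conversion therefore hinges on a
cell-specific canceling model.

This package implements both approaches to obtaining that model:

* **Template selection** (the baseline): a suite of nine mouse models whose
  APD₈₀ spans 40–120 ms in 10 ms steps, built by varying the steady-state
  (g<sub>ss</sub>) and slowly inactivating (g<sub>Kslow</sub>) K⁺
  conductances; the member nearest the measured APD₈₀ is selected.
* **Genetic-algorithm fitting**: six conductance scale factors
  (g<sub>Na</sub>, g<sub>ss</sub>, g<sub>Kslow</sub>, g<sub>CaL</sub>,
  g<sub>K1</sub>, g<sub>t</sub>) of the mouse model are tuned to minimize
  the sum of squared differences

  > SSD = Σ<sub>t</sub> [V₁(t) − V₂(t)]²

  over a 300 ms window aligned at the −40 mV upstroke crossing, against an
  averaged recorded AP. The GA uses 40 individuals × 15 generations,
  tournament selection without replacement, simulated binary crossover
  (probability 0.9, index 10, genewise swap probability 0.5), polynomial
  mutation (probability 0.1 per gene, index 20), and elitism — about 600
  one-beat model evaluations per fit, a few seconds of compute.

Because no patched myocytes are available to a software package, a
**pseudo-cell generator** synthesizes the experimental objective: ten
consecutive 1 Hz-paced beats of a hidden mouse genotype with per-beat
conductance jitter and additive voltage noise, averaged exactly as recorded
APs are.

## Worked example

```r
library(ctcfit)

# a synthetic "recorded myocyte": 10 noisy beats and their average
cell <- generate_pseudo_cell(seed = 42)
cell
#> <pseudo_cell> seed 42 - 10 beats, jitter CV 3.0%, noise 0.50 mV
#>   noise-floor SSD: 2665 mV^2

# fit a cell-specific model with the rapid GA
fit <- fit_cell(cell$objective, ga_config(seed = 42))
fit
#> <ga_run_result> 15 generations x 40 individuals
#>   best SSD by generation (mV^2):
#>   206.9 206.9 206.9 206.9 206.9 206.9 206.9 83.26 83.26 83.26 83.26 83.26 83.26 83.26 49.32
#>   final best genotype (fractional change):
#>     gNa     gss  gKslow    gCaL     gK1      gt
#>  0.4498 -0.5079  0.9830  0.0633 -0.0767  0.4378
#>   wall time: 4.77 s
```

The final best SSD (49 mV²) is far below the cell's own beat-to-beat noise
floor (2665 mV²): the fit lies within the cell's natural variability. Note
that the genotype itself is not meant to be recovered — distinct
conductance combinations can produce near-identical APs; the claim is
waveform recovery.

An ideal in silico conversion (target and canceling model identical) then
reproduces the free-running human recipient AP:

```r
m60   <- neonatal_mouse_model(apd80 = 60)
ideal <- run_ctc(m60, m60, human_recipient_model(), ctc_config(), beats = 1)
ref   <- recipient_reference(human_recipient_model(), ctc_config(), beats = 1)

trace_supnorm_diff(ctc_trace(ideal), ref)
#> [1] 1.137          # mV, sup-norm in upstroke-aligned time
apd_comparison(ideal, ref)
#>   beat apd30_conv apd50_conv apd90_conv apd30_ref apd50_ref apd90_ref
#> 1    1   221.1606   271.3935   298.8305  246.1457  276.0405   299.171
```

The converted mouse AP tracks the ~300 ms human APD₉₀ to within half a
millisecond. Re-running with a deliberately mismatched canceling model
(`neonatal_mouse_model(apd80 = 70)`) shortens the converted AP — the
failure mode that motivates cell-specific fitting.

A command-line workbench wraps the same pipeline
(`exec/ctcfit fit|ctc|template|pseudo|validate`, JSON config); see
`?ctcfit_main`.

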