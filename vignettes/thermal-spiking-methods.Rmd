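---
title: "Methods: evoked-response features, neuron fates and unit classification under thermal challenge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evoked-response features, neuron fates and unit classification under thermal challenge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feverspike)
```

## The scientific problem

When brain temperature rises from housekeeping values toward the fever
range (above ~38 °C), cortical pyramidal neurons face two opposing
pressures: their spike threshold depolarises (spiking gets harder) while
synaptic and intrinsic conductances change (input resistance falls,
inhibition weakens, warmth-gated cation channels such as TRPV3 open).
The analyses in this package characterise how a population of neurons
resolves this tension:

* **intracellularly**, from stimulus-locked voltage sweeps recorded at
  30, 36 and 39 °C: spike threshold (the second-derivative criterion),
  PSP components, evoked spike counts, rheobase, input resistance;
* at the **cohort level**, classifying each cell as NEVER / STAY / STOP /
  START according to whether evoked spiking persists across the
  temperature ladder, and comparing cohort proportions with exact
  binomial tests;
* **extracellularly**, classifying curated single units into putative
  interneurons and principal cells from the trough-to-peak duration of
  their mean waveform (dip test for bimodality, then exact 1-D 2-means)
  and quantifying firing-rate changes across baseline / fever / recovery
  periods.

Because no raw recordings ship with the package, a seeded synthetic-data
generator produces inputs with the statistical structure these analyses
assume, together with ground-truth labels, so every stage is testable
end to end.

## The intracellular generator

Each synthetic cell draws a spike threshold at 30 °C
(`theta30`, default N(−42, 1.5²) mV, truncated 3.5 mV above the −50 mV
holding potential), an input resistance (`rin30`, N(150, 25²) MΩ) and an
inhibitory amplitude. An evoked sweep is

\[ V(t) = V_{hold} + A_E\,k_E(t-\delta_E) - A_I\,k_I(t-\delta_I) + \varepsilon(t), \]

with dual-exponential kernels \(k(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}\)
normalised to unit peak (EPSP: 2/20 ms with a 3-ms synaptic latency;
IPSP: 6/60 ms delayed 10 ms so the late window, 50–150 ms, is
inhibition-dominated) and i.i.d. Gaussian noise (`noise_sd`, default
0.2 mV). Temperature enters four ways:

| channel | default | effect |
|---|---|---|
| `theta_slope` | 0.32 mV/°C | threshold depolarises |
| `rin_q10` | 0.8 per 10 °C | input resistance falls; scales \(A_E\) |
| `stay_gain` | 0.10 per °C | extra excitatory gain for STAY/START cells (the TRPV3-like warmth current) |
| `ipsp_temp_factor` | 0.05 per °C | inhibition weakens |

Where a spike must occur, a stereotyped 4-ms action-potential template
(kinked linear upstroke to +30 mV, cosine repolarisation, −12 mV AHP)
replaces the trace from the first deterministic threshold crossing. The
crossing decision uses the noise-free trace, so the realized spiking
pattern is exactly the drawn fate label at any noise level; noise only
perturbs the measured waveforms. The kinked upstroke matters: the 5-SD
second-derivative criterion keys on the abrupt slope change at spike
onset, which is how the threshold estimate lands on the onset sample
(mean absolute error ≈ 0.15 mV at the default noise) rather than partway
up the spike.

**Fate calibration.** For each cell the generator computes the critical
excitatory amplitude \(A^*(T)\) at which the deterministic deflection
reaches threshold, then clamps the cell's drawn amplitude into the
interval consistent with its fate (NEVER: below every \(A^*\); STAY:
above every \(A^*\); STOP: between \(A^*(36)\) and \(A^*(39)\); START:
between \(A^*(39)\) and the smaller of the other two). STOP cells are
realized as the pattern spiking–spiking–silent and START cells as
silent–silent–spiking; the fate *classifier* itself handles all eight
flag patterns. The START fate only exists if the warmth gain outruns the
threshold rise and resistance drop — \((1+g)^{9}\,q_{10}^{0.9} >
(\mathrm{dep}_{30}+2.88)/\mathrm{dep}_{30}\) — which is why the default
`stay_gain` is 0.10/°C; with a weaker gain the generator stops with an
explicit infeasibility error rather than silently mislabelling cells.
This clamping also plants the positive correlation between PSP amplitude
and spike threshold among STAY cells (cells with higher thresholds need
larger excitatory drive), the generator analogue of the ST–PSP coupling
the evoked-response analysis quantifies with Pearson correlation and
Deming regression.

The F-I protocol is a leaky integrate-and-fire model from −80 mV:
passive charging toward \(V_{hold} + I R_{in}\) with \(\tau_m = R_{in}
C_m\), template insertion at threshold, reset 10 mV below threshold. Its
rheobase has the closed form \(I = (\theta + 80)/(R_{in}(1 -
e^{-T/\tau_m}))\), which the extraction code must reproduce on the step
grid.

## The extracellular generator

Unit durations come from the two-Gaussian mixture 0.221·N(0.35, 0.05²) +
0.779·N(0.90, 0.10²) ms — the narrow/wide (interneuron/principal) split
at the canonical 22%/78% ratio. Waveforms are zero-net-area biphasic
templates (trough then peak, lobe width duration/5) so the 300–6000 Hz
zero-phase Butterworth bandpass moves the extrema by less than one
sample at 30 kHz.

Spike trains are dead-time renewal processes: inter-spike interval =
2 ms + Exp(r′) with r′ = r/(1 − 0.002 r), so the refractory floor is
exact and the realized rate equals the nominal rate (a thinning
construction would bias rates low; the expected count of a 2-Hz unit
over 145 min must be 17,400). The session is three 45-min periods with
5-min ramps; the fever gain multiplies the rate between the two ramp
midpoints, and analysis windows (the last 25 min of each period) never
touch the ramps, so the planted gain is recovered exactly in
expectation.

Body temperature is sampled every 5 min as clipped AR(1) noise around
36.5 °C (bounded at ±0.5 °C), with optional planted fever bouts
(plateaus at 38.2–38.8 °C) or, in the infrared condition, a ramp within
~15 min to a sustained plateau above 38 °C.

## Statistical primitives

These are implemented from first principles because the analysis depends
on their exact conventions:

* **Dip statistic** — the minimal sup-norm distance between the
  empirical CDF and any unimodal CDF, computed in C by the iterative
  modal-interval algorithm (greatest convex minorant of the lower step
  corners, least concave majorant of the upper corners; the largest
  hull-to-hull gap locates the next modal interval; shed regions
  contribute half their maximal corner-to-hull deviation). The test
  suite validates it against a definitional oracle — bisection on the
  band half-width with convex/concave envelope feasibility checks per
  candidate mode, each claimed-feasible width verified by directly
  measuring the sup-distance of an assembled witness CDF — across
  hundreds of fuzz samples including heavy ties, plus closed-form
  anchors (a balanced two-point sample has dip exactly 0.25; evenly
  spaced distinct points attain the 1/(2n) lower bound). The p-value is
  a uniform bootstrap (the classical least-favourable unimodal null),
  2000 replicates by default, seeded through R's RNG; because the null
  depends only on n, `dip_null()` can be computed once and shared.
* **Exact binomial test** — two-tailed by the small-p-values convention
  (sum of all point probabilities not exceeding the observed one, with
  the customary 1e-7 relative tolerance); doubling available by flag.
* **Deming regression** — closed-form errors-in-variables fit for error
  variance ratio λ (default 1 = orthogonal); checked against a numeric
  minimiser of the weighted orthogonal residual criterion and the
  λ→∞ OLS limit.
* **Correlations** — product-moment and rank (average ranks for ties),
  two-sided p from the t transform on n−2 df.
* **Two-sample KS** — D by ECDF scan; exact p by lattice-path counting
  when the smaller sample has ≤10 observations and no cross-sample
  ties, otherwise the asymptotic Kolmogorov series with the standard
  finite-sample correction.

## Analysis conventions and tie-breaks

* The evoked-spike window starts 2.5 ms post-stimulus (the midpoint of
  the stated 2–3 ms) and runs 150 ms; both are arguments.
* "More than 3 of 5 consecutive sweeps" is implemented as ≥4 detections
  in the 5-sweep block (`min_hits = 4`, an explicit constant).
* The late-PSP window is fixed at 50–150 ms post-stimulus and measured
  as the signed window maximum (a "late PSP peak"); the bounds are
  exposed because only the concept, not the window, is standard.
* Spikes are excised before PSP measurement by linear interpolation
  across ±2 ms around each detected peak.
* Depolarisation-to-threshold is measured from the mean pre-stimulus
  baseline, not the nominal holding potential, so holding drift does not
  bias it.
* Fate classification keys on the state at the first temperature:
  (T,F,T) is STOP, (F,T,F) is START. The fever threshold for
  body-temperature bouts is 38.0 °C.
* Units with duration exactly at the cluster boundary take their 2-means
  cluster label; the 0.6-ms figure is a *description* of where the
  boundary lands for canonical mixtures, not a hard rule.
* The refractory criterion is operationalised as ≤1% of ISIs below 2 ms,
  and presence as all 10 equal session bins nonempty; both thresholds
  are arguments because the underlying criteria are qualitative.
* Rate normalisation divides each unit's period rate by its own baseline
  rate and then averages within animal; zero-baseline units are dropped
  with a warning.

## Problem sizes and what the tests show

The packaged checks run the full pipeline on a 200-cell cohort at the
default 0.2-mV noise (fate recovery ≥95%, per-cell threshold error
<1 mV), a 633-unit population (interneuron share within 3 points of the
planted 22.1%, boundary inside 0.5–0.7 ms, fever gain 1.5 recovered
within 5%), and statistical calibration at cohort scale (dip test:
p < 0.001 on ≥95 of 100 bimodal draws, ≤10 of 100 false rejections on
unimodal Gaussians; binomial type-I error within discreteness slack of
5% over 10,000 null draws). Smaller deterministic fixtures cover every
operation's worked examples and oracle equivalences.

Passing these tests shows the pipeline is correct *for data with this
structure*: stationary Gaussian noise, stereotyped spikes, stable
baselines, Poisson-like trains with a hard refractory floor. Real
recordings add drift, electrode artifacts, bursting, correlated (1/f)
noise and spike-sorting contamination that the generator deliberately
omits (an AR(1) hook is the obvious first extension), so recovery rates
here are upper bounds on what identical settings achieve on real data.

## A worked run

```{r, eval = FALSE}
report <- run_pipeline(pipeline_config(
  cohort = cohort_config(n_cells = 40, seed = 1),
  n_units = 200, unit_seed = 7, dip_n_boot = 500))
report$paper_analog$fate_percent
autoplot(report$classification)
```
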