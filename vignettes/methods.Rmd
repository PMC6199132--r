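---
title: "Burst synchrony and electrical coupling in a small motor network: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst synchrony and electrical coupling in a small motor network: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgsync)
```

## The scientific problem

The crustacean cardiac ganglion is a nine-neuron central pattern generator:
four Small Cell (SC) pacemaker interneurons drive five Large Cell (LC) motor
neurons that fire rhythmic, tightly synchronized bursts (cycle periods of a
few seconds). The LCs reach near-identical output despite widely variable
membrane conductances, in part because they are electrically coupled by gap
junctions. Neuromodulators such as serotonin (5HT) and dopamine (DA) excite
the network; the interesting contrast is that some modulators desynchronize
the LC burst waveforms while others — notably DA, which also increases gap
junctional conductance — do not, and can even protect the network against
desynchronizing perturbations such as the K⁺ channel blocker TEA.

`cgsync` implements the quantitative pipeline for this kind of experiment:

1. **Segmentation** — spike detection on the extracellular trunk recording,
   amplitude-based SC/LC classification, grouping into bursts, cycles
   anchored at pacemaker-burst starts, and marking of intracellular
   burst-waveform boundaries, including the special rules for
   "double-bursting" cycles.
2. **Synchrony** — per-burst waveform synchrony as the squared zero-lag
   Pearson correlation (R²) between two intracellular traces, its
   experiment-long time course, 10-burst epoch averaging, and acute-minimum
   localisation.
3. **Phase and burst statistics** — on/off phases as latency over cycle
   period, spikes per burst, intraburst frequency, duration, duty cycle,
   with 10-cycle averaging.
4. **Electrical coupling** — steady-state deflections from hyperpolarizing
   current steps, coupling coefficients, origin-free input/transfer
   resistance fits, and the Bennett two-compartment coupling resistance
   $R_c = (R_{in,1} R_{in,2} - R_{12}^2)/R_{12}$ with $G_c = 1/R_c$.
5. **Statistics** — paired t tests with Shapiro–Wilk screening and one-way
   repeated-measures ANOVA with Tukey post-hoc tests.
6. **Synthetic data** — generators for passive cell pairs with exactly known
   coupling and for small heterogeneous bursting networks with gap junctions
   and phenomenological modulator transforms, so every stage of the pipeline
   can be validated against ground truth without access to raw recordings.

No raw recordings are distributed with the studies this pipeline serves, so
the package treats the synthetic generators as first-class, tested code: the
analysis stages are validated against exact oracles and answer keys, and the
modulator contrasts are reproduced *qualitatively* on synthetic cohorts.

## The passive-pair generator and its exact oracle

The Bennett estimator assumes two compartments: two passive membranes
($R_m$, $C_m$, common rest) joined by an ohmic junctional resistance $R_c$.
For this circuit everything is available in closed form
(`analytic_passive_pair()`):

$$R_{in,1} = \frac{R_{m1}(R_c + R_{m2})}{R_{m1}+R_c+R_{m2}}, \qquad
  R_{12} = \frac{R_{m1}R_{m2}}{R_{m1}+R_c+R_{m2}}, \qquad
  cc_{12} = \frac{R_{m2}}{R_c+R_{m2}},$$

and one can verify algebraically that
$(R_{in,1}R_{in,2}-R_{12}^2)/R_{12} = R_c$ exactly — the estimator is
consistent on its own assumptions. `simulate_passive_pair()` integrates the
two-compartment ODE *exactly* (eigendecomposition of the $2\times2$ system
matrix, piecewise-constant inputs), so the only deviation from the analytic
solution at the sampled points is the optional measurement noise. The
default protocol injects −2, −4, −6, −8 nA alternately into the two cells
with 250 ms steps — tens of membrane time constants, far beyond the point
where the transient matters. Note that at exactly $5\tau$ the slow mode of
the coupled pair still holds ~0.5–1 % of the deflection; the protocol's long
steps are what make the 0.1 % recovery contract attainable.

Units are chosen so no conversion constants appear anywhere: MΩ × nA = mV,
and $G_c\,[\mu S] = 1/R_c\,[M\Omega]$.

## The network generator

Each LC is a minimal burster with exactly the ingredients the analysis
needs: a leak conductance, a fast exponential spiking mechanism with
threshold reset, a slow K-like adaptation current $w$ (strength $b$,
kinetics $\tau_w$) that shapes the intraburst spike pattern, and an
excitatory drive conductance gated by the shared pacemaker envelope.
Gap junctions are ohmic and non-rectifying,
$I_{gap}(i\leftarrow j) = g_c (V_j - V_i)$, with a symmetric matrix.
The integrator is a fixed-step explicit scheme at $dt = 0.05$ ms (compiled);
halving the step leaves spike counts unchanged and moves spike times by less
than 2 ms.

Two modelling points deserve emphasis:

* **Why threshold-reset rather than a conductance-based spike.** A
  Morris–Lecar-style oscillator was tried first; its limit cycle exists only
  in a narrow band of the (Ca-like, K-like, kinetics) space, and
  heterogeneous cohorts routinely wandered into oscillation death or
  depolarization block — silently producing spikeless plateaus. The
  threshold-reset burster belongs to the same minimal class (leak + fast
  spiking mechanism + slow K-like recovery) but spikes robustly over the
  whole draw box, with smooth, monotone parameter dependence. Any richer
  model can be substituted behind the same `network_spec()` contract.
* **What the recorded trace looks like.** LC somata record strongly
  attenuated spikes riding a slow burst depolarisation (spike excursions of
  one to a few tens of mV), not full axonal action potentials. The model
  caps the spike upswing 15 mV above threshold and superimposes a
  stereotyped ~4 ms somatic spikelet at the ground-truth spike times of the
  sampled trace, giving waveforms whose R² is sensitive to both envelope
  and spike-timing divergence — the regime the real analysis operates in.

Heterogeneity: per-cell adaptation strength and kinetics and drive
conductance are drawn from mean-preserving log-normal distributions with
CV `cv_g` (default 0.3, matching the several-fold conductance ranges
documented in these neurons). Independent per-cell background currents
(Ornstein–Uhlenbeck, 0.15 nA SD, 100 ms correlation time) make burst
waveforms fluctuate from cycle to cycle, as they do in real preparations;
they are what the gap junctions have to average away, so they also bound the
attainable synchrony at weak coupling.

The default gap-junction conductance is 1.25 μS — inside the experimentally
measured junctional-conductance range for the isolated LC4/LC5 pair
(≈0.46–1.29 μS) — and yields control-cohort epoch R² of ≈0.97, matching the
control synchrony level of real preparations.

The pacemaker drive is a periodic envelope (period 2.5 s ≈ 0.4 Hz). In
double-burst mode the envelope has two lobes per cycle with a 50 % floor
between them, so the membrane stays depolarised between the two LC bursts —
the hallmark used by the double-burst boundary rules — and the SC burst is
prolonged up to the second lobe. The extracellular channel is synthesised
from ground-truth spike times by summing small biphasic kernels for SC
spikes and large ones for LC spikes; its only job is to exercise detection
and classification with a known answer key, and it makes no claim to be a
field model.

## Modulator transforms

The transforms are phenomenological: the paper-level physiology constrains
*what the output should do* (5HT desynchronizes and double-bursts, DA
excites without desynchronizing and raises $g_c$ ~2.5-fold, TEA
desynchronizes, combinations with DA stay synchronized), not the molecular
targets. `apply_modulator()` therefore maps each modulator onto the model's
parameter classes:

* **5HT** — heterogeneous per-cell log-normal scalings (CV 0.3, clipped to
  the bursting regime): K-like adaptation strength × ~0.6, drive efficacy
  × ~1.3, adaptation kinetics retimed; drive switches to the double-envelope
  mode; gap junctions untouched. Because each cell receives a *different*
  scaling, the intraburst spike patterns diverge; that divergence, not any
  change in coupling, is what lowers R².
* **DA** — gap-junction matrix × 2.5 plus a mild *uniform* excitability
  increase (drive × 1.2, adaptation × 0.85): more spikes per burst and
  higher intraburst frequency with no cell-to-cell divergence.
* **TEA** — strong, heterogeneous block of the K-like adaptation
  (mean × 0.3) with slowed kinetics and a heterogeneous increase in drive
  efficacy. The drive component renders, in this minimal model, the
  heterogeneous postsynaptic excitability increase that the blocker produces
  in real LCs; without it a uniform-mean K reduction alone barely
  desynchronizes, because denser spike trains correlate *more* readily.
* Combinations compose multiplicatively and commute; per-cell draws are
  seeded from the effect name so composition order cannot change them.

During a simulated experiment the transform is ramped in exponentially
(default time constant 15 s) from the perfusion time, emulating bath
exchange.

## Analysis conventions and numerical choices

* **"Return to resting potential"** is operationalised as
  $V \le rest + tol$ with `tol = 2` mV (configurable); rest is the 10th
  percentile of the voltage over inter-burst windows (from 100 ms after each
  cycle's last LC spike to the next cycle start) and is re-estimated within
  each condition. In the synthetic cells this estimate sits 2–3 mV below the
  leak reversal because of the genuine afterhyperpolarisation inside the
  window; the waveform-boundary logic is insensitive to this bias.
* **Burst grouping**: maximal runs with ISI < `max_isi` (0.25 s for LC,
  0.5 s for SC by default; cycle periods are ~2–4 s and bursts sub-second).
* **Unit classification**: deterministic 1-D 2-means on log-amplitude with
  min/max initialisation. The log scale matters: synchronized LC spikes from
  two cells occasionally superpose into double-amplitude events, and
  raw-scale 2-means would split the LC class rather than SC from LC.
* **R²** is the square of the zero-lag Pearson r between the two voltage
  segments, resampled onto the coarser grid by linear interpolation and
  truncated to the overlap. Anti-correlated segments score high R² and are
  therefore flagged (`negative_r`) rather than silently reported. A
  diagnostic lag scan exists behind `max_lag` but never feeds R².
* **Double-burst slots** are reported separately (slots 1 and 2) and pooled
  for epoch means, since which slot is less synchronous varies across
  preparations.
* **Acute epoch**: `at_minimum` selects the 10-consecutive-burst window with
  the lowest mean R² after perfusion; the alternative fixed-window rules
  (`ending_at`, `centered_at`) are provided. `find_acute_minimum()` uses a
  centred 10-burst moving average, earliest time on ties.
* **ΔV extraction**: mean over the last 20 % of the step minus mean over the
  pre-step baseline window, after excising excursions >10 mV above the
  window median (spike contamination).
* **Resistances** come from origin-free least squares of ΔV against I across
  the −2..−8 nA family (slope standard errors reported); a single-amplitude
  fallback (flagged) supports in-network 1–6 nA measurements. Direction `d`
  uses its own transfer resistance with both cells' input resistances; a
  pooled estimate using the mean transfer resistance is also emitted.
* **Statistics**: sample SD throughout; paired t with Shapiro–Wilk screening
  (a Wilcoxon result is attached, never silently substituted, when normality
  is rejected at 0.05); one-way RM ANOVA from within-subject sums of squares
  with Tukey HSD on the RM error term; no sphericity correction by default
  (Greenhouse–Geisser behind a flag); α = 0.05 with all raw p values
  reported.
* **Spike frequency** uses the ISI-based $(n-1)/duration$ convention, and
  LC off phase is referenced to the last spike time (both recorded in the
  output metadata, so the alternatives can be toggled).

## Problem sizes

The simulated experiments use a compressed timeline — a 30 s control
baseline (12 cycles) followed by 60 s of modulated activity (~24 cycles),
with the modulator ramp at 15 s — standing in for the tens-of-minutes
protocols used at the rig; all epoch rules operate on burst counts, not
absolute times, so nothing in the analysis depends on the compression.
Cohort analyses use n = 8 preparations per condition, and the coupling
cohorts draw preparation-specific $R_m \in [3, 8]$ MΩ and
$R_c \in [1.5, 4]$ MΩ ($G_c \approx 0.25$–0.67 μS, the experimentally
reported range). Every random quantity derives from a single root seed.

## What the synthetic tests do and do not show

Passing the answer-key and cohort tests shows that the *pipeline* is
correct: segmentation recovers what the generator emitted, the coupling
estimator inverts the circuit it assumes, R² equals an independent Pearson
implementation, the statistics are calibrated, and the modulator transforms
produce the qualitative contrast structure (5HT/TEA desynchronize; DA does
not and protects; DA raises measured $G_c$ and coupling coefficient). It
does not show that the phenomenological transforms are mechanistically
correct for real LCs, nor can it reproduce the group means of real
preparations; the generator emulates rhythm structure, waveform
variability, and coupling magnitudes, but not spike-waveform diversity,
electrode artefacts, slow drift, or genuine biological covariation between
parameters.

## Known limitations

* The two-compartment estimator is exact only for the isolated
  (ligature-style) pair; applied in-network it inherits the usual bias from
  distributed coupling paths. The suspect-value flags (`cc` outside [0, 1],
  non-physical Bennett numerator) are the guard rails.
* Gap junctions are non-rectifying by construction; direction-resolved
  conductances differ only through measurement noise and the direction's own
  transfer resistance.
* The extracellular channel is a kernel sum, not a field model; it cannot
  exercise overlapping-unit resolution or spike-sorting failure modes.
* CSV (+ YAML sidecar) is the supported recording format; vendor binary
  formats are out of scope.
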