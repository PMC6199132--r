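# cgsync

Burst synchrony and electrical coupling analysis for crustacean cardiac
ganglion recordings — with a synthetic-data generator that makes every
stage of the pipeline testable against ground truth.

## The problem

The cardiac ganglion is a nine-neuron central pattern generator: four Small
Cell (SC) pacemakers drive five Large Cell (LC) motor neurons that fire
rhythmic, tightly synchronized bursts. The LCs vary widely in membrane
conductances yet produce near-identical waveforms, largely because they are
electrically coupled. Neuromodulators perturb this balance: serotonin (5HT)
and the K⁺ blocker TEA desynchronize LC burst waveforms, while dopamine
(DA) excites the network *without* desynchronizing it — and increases gap
junctional conductance enough to protect synchrony when co-applied with
either desynchronizer.

`cgsync` implements the quantitative machinery for such experiments, for
electrophysiologists working with paired intracellular + extracellular
recordings of small rhythmic networks:

* spike detection, amplitude-based SC/LC classification, burst and cycle
  segmentation, and intracellular burst-waveform boundaries — including the
  boundary rules for "double-bursting" cycles in which the membrane never
  returns to rest between two LC bursts;
* per-burst waveform synchrony as the squared zero-lag Pearson correlation
  (R²), its experiment-long time course, 10-burst epoch averaging, and
  acute-minimum localisation;
* phase relationships (SC off, LC on/off as latency ÷ cycle period) and
  burst statistics with 10-cycle averaging;
* electrical-coupling estimation from hyperpolarizing current steps:
  coupling coefficients, origin-free input/transfer resistance fits, and
  the Bennett two-compartment coupling resistance
  `Rc = (Rin1·Rin2 − R12²)/R12`, `Gc = 1/Rc`;
* paired t tests with Shapiro–Wilk screening and one-way repeated-measures
  ANOVA with Tukey post-hoc tests;
* synthetic generators: passive cell pairs with exactly known coupling (an
  analytic oracle solves the circuit in closed form) and small
  heterogeneous bursting networks with gap junctions, pacemaker drive, and
  phenomenological 5HT / DA / TEA transforms.

Units throughout: seconds, mV, nA, MΩ, μS (so MΩ × nA = mV and
μS = 1/MΩ with no conversion factors).

## Worked example

Recover a known junctional conductance from a simulated step protocol:

```r
library(cgsync)

spec <- passive_pair_spec(Rm1 = 5, Rm2 = 5, Rc = 10)   # MOhm; Gc = 0.1 uS
analytic_passive_pair(spec)$cc12                        # 0.3333333
rec <- simulate_passive_pair(spec, seed = 1)            # -2..-8 nA protocol
coupling_from_protocol(rec, c("LC4", "LC5"))
#> <coupling_result>
#>   cc:  1->2 0.3333, 2->1 0.3333
#>   Rin: 3.75 / 3.75 MOhm; R12: 1.25 / 1.25 MOhm
#>   Gc:  1->2 0.1, 2->1 0.1 uS (pooled 0.1)
```

Simulate a modulator experiment and analyse it end to end:

```r
prep <- simulate_preparation("5HT", seed = 1001)  # 30 s control, then perfusion
prep$epochs
#>     label t_center   mean_r2       sd_r2 n_bursts
#> 1 control 17.87505 0.9575268 0.009645731       10
#> 2   acute 79.62947 0.9323562 0.029030066       10
#> 3    late 79.62947 0.9323562 0.029030066       10
```

The control epoch averages the 10 bursts before perfusion; the acute epoch
is the minimum-mean 10-burst window afterwards — here 5HT lowers burst
synchrony from R² ≈ 0.958 to ≈ 0.932 in this single preparation, with the
acute minimum 50 s after perfusion onset (in this run the acute window
coincides with the last 10 bursts, so the late epoch repeats it).

The numbered scripts under `analysis/` run the full study on synthetic
data: `01` validates the coupling estimator against the exact circuit
oracle, `02` checks segmentation against the generator's answer key, `03`
computes synchrony time courses under 5HT and DA, `04` measures the
DA-induced coupling-conductance increase on isolated pairs (control
0.455 ± 0.154 μS → DA 1.137 ± 0.387 μS, +150 %, one-sided paired
p = 3.6 × 10⁻⁵), and `05` runs eight preparations per condition and prints
the verdict table for the headline contrasts (5HT and TEA desynchronize;
DA does not; DA + 5HT and DA + TEA stay synchronized; DA raises the
coupling coefficient and Bennett conductance). Each writes its tables under
`results/`.

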