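# arquant

Detection and quantification of **asynchronous release (AR)** — the
delayed, low-rate tail of quantal neurotransmitter release that follows
the large synchronous EPSC after a presynaptic stimulus — from
stimulus-evoked voltage-clamp recordings.

The package is aimed at synaptic electrophysiologists comparing AR
across conditions (e.g. wild type vs *Syt3*, *Syt7* and double-knockout
mice at cerebellar climbing-fiber, parallel-fiber→MLI and hippocampal
CA1→O-LM synapses). It implements the full measurement chain:

* **Synchronous EPSC analysis** — baseline 1 ms before the stimulus,
  peak search with artifact blanking, bi-exponential fit of the decay
  from 90 % of the peak
  (`I(t) = A₁e^(−t/τ₁) + A₂e^(−t/τ₂)`, weighted
  `τ̄ = (A₁τ₁+A₂τ₂)/(A₁+A₂)`), and subtraction to expose delayed
  quantal events.
* **Filtered-derivative event detection** — 0.8 kHz zero-phase low-pass,
  first derivative (pA/ms), threshold `max(2×RMS, 20 pA/ms)` for
  interneuron presets or fixed 35 pA/ms + 35 pA for Purkinje cells,
  20 pA amplitude floor, 1 ms refractory rule, and synapse-specific
  exclusion windows (5/10/20 ms) after the EPSC peak.
* **AR metrics** — spontaneous rate from baseline windows (500 ms
  pre-stimulus, 1 s post onwards), spontaneous-corrected AR events per
  stimulus, normalization per nA of synchronous EPSC, PSTHs, and
  exponential time-course fits `r(t) = Σ Aᵢ e^(−t/τᵢ)`.
* **Statistics** — Shapiro–Wilk, Student's *t* / one-way ANOVA with
  pairwise *t*-tests against a corrected critical alpha (α/m default,
  exact Šidák optional), percent reductions between conditions, and the
  2^−ΔCt qPCR transform.
* **Synthetic sweeps with ground truth** — an inhomogeneous-Poisson AR
  generator (exponential rate transient over a spontaneous floor,
  difference-of-exponential quantal kernels, shaped noise) so the whole
  pipeline is validated by parameter recovery.
* **snRNA-seq co-detection** — depth-binned detection fractions for two
  genes and a binomial transcript-dropout null
  (`p(T) = 1−(1−f)^T`) testing whether single-positive nuclei are
  explained by dropout alone.

## Worked example

Simulate paired wild-type and double-knockout parallel-fiber cohorts,
run detection and quantification end to end, and compare:

```r
library(arquant)

res <- run_ar_pipeline(list(synapse = "parallel_fiber_MLI",
                            genotypes = c("WT", "DKO"),
                            n_cells = 3, n_sweeps = 20, seed = 42))
cat(pipeline_summary(res), sep = "\n")
#> synapse: parallel_fiber_MLI
#> seed: 42
#> cohort: 3 cells x 20 sweeps
#> WT: events/stim 0.4199, per nA 0.6152, spont 0.567 Hz, AR tau 26.7 ms
#> DKO: events/stim 0.0199, per nA 0.0273, spont 0.567 Hz, AR tau 27.9 ms
#> reduction DKO vs WT (normalized): 95.56%

print(res$stats)
#> <GroupComparison: 2 groups; Student t-test p = 0.00247; critical alpha 0.0500 (per_comparison)>
#>   group1 group2           p significant
#> 1     WT    DKO 0.002467812        TRUE
```

Reading the output: each genotype line reports the
spontaneous-corrected AR events per stimulus, the same rate normalized
per nA of synchronous EPSC (the metric used at multi-fiber synapses),
the estimated spontaneous rate, and the fitted AR decay constant. At
this small cohort size the DKO reduction (95.6 %) scatters around its
generator ground truth (71 %); the acceptance-scale cohorts below
use 8 cells × 50 sweeps, where recovery lands within a few points.
Identical spontaneous rates across genotypes are expected: cohorts
generated from one master seed are paired (common random numbers) and
differ only in accepted AR events.

Single steps are available as ordinary functions (`generate_cohort`,
`measure_epsc`, `fit_epsc_decay`, `subtract_epsc_fit`, `detect_events`,
`build_psth`, `fit_ar_decay`, `compare_groups`, `bin_by_depth`,
`fit_dropout_null`, ...); see the methods vignette
(`vignettes/ar-quantification.Rmd`) for the model, parameter defaults
and design rationale.

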