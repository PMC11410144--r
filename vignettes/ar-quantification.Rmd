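---
title: "Quantifying asynchronous release: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying asynchronous release: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arquant)
```

## The problem

At many central synapses a presynaptic action potential triggers two
phases of transmitter release: a large synchronous excitatory
postsynaptic current (EPSC) within a millisecond of the stimulus, and a
low-rate tail of *asynchronous release* (AR) — delayed single-vesicle
(quantal) events driven by residual presynaptic Ca²⁺ that persist for
tens to hundreds of milliseconds. Quantifying AR from voltage-clamp
recordings is hard because the delayed quantal events ride on the
decaying phase of an EPSC that can be two orders of magnitude larger,
and because they must be separated from ongoing spontaneous release.

`arquant` implements the complete measurement chain: synchronous-EPSC
measurement and subtraction, filtered-derivative event detection,
spontaneous-corrected AR rates with peristimulus time histograms (PSTHs)
and exponential time-course fits, and group-level statistics for
comparing genotypes (wild type against *Syt3*, *Syt7* and double
knockouts). Because raw recordings of this kind are rarely shareable,
the package also contains a synthetic sweep generator with full ground
truth, so every stage is validated by parameter recovery rather than by
eyeballing traces.

## The analysis procedure

Each sweep is a current trace (pA, inward negative) sampled at 20–50 kHz
around one stimulus; all windows below are stimulus-relative.

1. **Baseline** — mean current over the 1 ms immediately before the
   stimulation artifact (`measure_baseline`).
2. **Synchronous EPSC** — the most negative sample within 10 ms of the
   stimulus, skipping a 0.5 ms artifact-blanking interval; amplitude is
   the positive magnitude relative to baseline (`measure_epsc`). The
   10 ms search window and 0.5 ms blank are package defaults: these
   synapses peak within a few milliseconds, and artifact width is
   rig-dependent.
3. **Decay fit and subtraction** — from the first post-peak sample at
   90 % of the peak, the decay is fit with
   $I(t) = A_1 e^{-(t-t_0)/\tau_1} + A_2 e^{-(t-t_0)/\tau_2}$ over a
   200 ms window and subtracted, leaving a residual trace on which
   quantal events are detectable (`fit_epsc_decay`,
   `subtract_epsc_fit`). The reported weighted time constant is
   amplitude-weighted, $\bar\tau = (A_1\tau_1 + A_2\tau_2)/(A_1+A_2)$.
   Each sweep is fit individually; fitting the averaged EPSC instead is
   a possible variant we did not adopt, because per-sweep fits track
   trial-to-trial amplitude fluctuations.
4. **Event detection** (`detect_events`) — the residual is low-pass
   filtered at 0.8 kHz (zero-phase second-order Butterworth, applied
   forward and backward) and differentiated (central differences,
   pA/ms). For interneuron presets (MLI, O-LM) the detection threshold
   is $\max(2\times\mathrm{RMS}, 20\ \mathrm{pA/ms})$, with the RMS of
   the differentiated trace measured 1–5 s after the stimulus; for
   Purkinje-cell (climbing-fiber) recordings the thresholds are fixed at
   35 pA/ms and 35 pA. Each contiguous segment of derivative below
   threshold nominates a candidate at the derivative minimum; the event
   peak is the most negative residual sample within 1 ms after it, and
   its amplitude is measured against the median of the preceding 1 ms of
   residual (a robust local baseline the published rule leaves
   unspecified). Events below the amplitude floor (20 pA, or 35 pA for
   Purkinje) are dropped; of events closer than 1 ms the earlier is kept
   (the alternative reading — drop both — is available via
   `refractory_drop_both`); events within the exclusion window after the
   EPSC peak (5/10/20 ms for MLI/O-LM/climbing fiber) are omitted
   because they cannot be resolved on the decaying EPSC.
5. **AR metrics** (`analyze_recording`) — the spontaneous rate is
   estimated from 500 ms before the stimulus plus 1 s after it to the
   end of the sweep, and subtracted everywhere. AR events per stimulus
   are counted from the end of the exclusion window to 500 ms (the AR
   window; configurable — AR has decayed to the spontaneous floor well
   before that at these synapses). At synapses where many fibers are
   stimulated (parallel fiber, CA1), rates are normalized per nA of
   synchronous EPSC as a proxy for the number of activated synapses;
   climbing fibers are all-or-none single inputs and use raw counts.
   PSTHs use 10 ms bins and are fit with
   $r(t) = \sum_i A_i e^{-t/\tau_i}$ (one component by default; two for
   conditions such as Sr²⁺ substitution with a fast and a slow phase).
6. **Statistics** (`compare_groups`) — Shapiro–Wilk normality per group,
   Student's *t*-test for two groups or one-way ANOVA followed by all
   pairwise *t*-tests, judged against a corrected critical alpha. The
   default correction is $\alpha/m$, which reproduces the conventional
   printed critical levels (0.0167 for $m=3$, 0.025 for $m=2$); the
   exact Šidák formula $1-(1-\alpha)^{1/m}$ is available — the two are
   nearly indistinguishable at small $m$, and published critical levels
   are sometimes labeled with one and computed with the other.

## The synthetic sweep generator

`generate_sweep` emulates the statistical structure of stimulus-evoked
recordings: a synchronous EPSC at $t=0$ (bi-exponential decay under an
exponential rise), quantal events as difference-of-exponentials kernels
($\tau_\mathrm{rise}$ 0.2 ms, $\tau_\mathrm{decay}$ 2 ms) with lognormal
amplitudes (mean 40 pA, CV 0.3 — most events clear the 20 pA floor while
a tail is censored, as in real data), and Gaussian noise (3 pA RMS)
shaped by a 2.9 kHz low-pass mimicking the acquisition Bessel filter.

Event times follow an inhomogeneous Poisson process
$\lambda(t) = r_\mathrm{spont} + (n_\mathrm{AR}/\tau_\mathrm{AR})
e^{-t/\tau_\mathrm{AR}}$ for $t \ge 0$, sampled exactly by thinning.
Genotypes scale the AR expectation by a multiplier encoding the reported
percent reductions (climbing fiber: Syt3KO 0.20; parallel fiber: Syt3KO
0.77, Syt7KO 0.51, DKO 0.29; CA1→O-LM: 0.51/0.39/0.08) and set the AR
decay constant (WT 40 ms, Syt3KO 60 ms, Syt7KO 25 ms, DKO 70 ms —
magnitudes are package defaults chosen to respect the reported ordering,
since no values are published).

Three generator choices deserve explanation:

* **Coupled genotype cohorts.** Thinning is exact for *any* envelope at
  least as large as the peak rate. `generate_sweep` therefore uses a
  synapse-level envelope ($r_\mathrm{spont} +
  n_\mathrm{AR}^\mathrm{WT}/\tau^\mathrm{WT}$), draws candidate times
  *and amplitudes* before acceptance, and `generate_cohort` derives
  per-cell and per-sweep seeds deterministically from the master seed.
  Cohorts of different genotypes generated from the same master seed
  then share candidate events, amplitudes and noise, and differ only in
  which AR candidates are accepted — a common-random-numbers coupling
  that makes between-genotype comparisons paired. Without it, Poisson
  fluctuations of a few hundred AR events per cohort would dominate the
  recovered percent reductions at realistic cohort sizes (8 cells × 50
  sweeps); with it, recovery is limited by the irreducible thinning
  noise.
* **Spontaneous rates.** Defaults are 0.5 Hz (climbing fiber, where the
  35 pA floor excludes most spontaneous quanta), 0.5 Hz (parallel
  fiber → MLI) and 0.3 Hz (CA1 → O-LM): spontaneous events *of
  detectable size* are sparse at these synapses. A design power analysis
  fixed these once: background subtraction noise enters the recovered
  percent reduction with coefficient
  $(a_\mathrm{WT}-a_\mathrm{KO})/a_\mathrm{WT}^2$, and at several Hz it
  would swamp the effect-size recovery the generator exists to validate.
  Higher rates remain fully supported (`spont_rate` in the preset) —
  the spontaneous-rate estimator itself is validated separately at
  10 Hz.
* **Sweep geometry.** Cohort sweeps span 0.5 s before to 2.5 s after the
  stimulus at 20 kHz — shorter than the 8 s inter-stimulus interval used
  experimentally, so the 1–5 s RMS/baseline windows are clipped to the
  sweep end (with a warning) but all analysis windows still fit. This
  keeps a full multi-genotype cohort comparison to tens of seconds of
  compute; the per-cohort problem size used throughout the tests and the
  acceptance script is 8 cells × 50 sweeps per genotype.

What the generator does **not** emulate: vesicle-pool depletion and
sensor kinetics (the AR rate model is phenomenological), stimulation
artifacts, series-resistance and capacitance errors, overlapping-event
pileup beyond what the Poisson model produces, electrode drift, and
correlated (non-Gaussian) noise. Passing recovery tests therefore show
that the measurement chain is unbiased under the stated statistical
structure — not that detection is robust to every pathology of real
recordings.

A known, quantifiable feature of the recovery design: the genotype
multipliers scale *total* AR content, but measured counts start at the
end of the exclusion window, and the surviving fraction
$e^{-t_\mathrm{excl}/\tau_\mathrm{AR}}$ differs between genotypes
because $\tau_\mathrm{AR}$ differs. The recovered percent reductions are
therefore expected to deviate from the nominal multipliers by a few
points in a predictable direction (e.g. the CA1 Syt7 knockout, with its
fast $\tau$ and 10 ms exclusion window, reads a few points high). This
mirrors the real measurement, which is equally blind to the excluded
interval.

## The co-detection dropout model

The companion module asks a transcriptomic question: when single-nucleus
RNA-seq finds nuclei positive for only one of two genes, is that
evidence of single-expressing cells, or just transcript dropout at
finite sequencing depth? Nuclei are sorted by total detected transcripts
and binned (20 000 transcripts per bin for granule cells, 10 000 for
CA1 pyramidal and Purkinje neurons), and per-bin detection fractions are
computed for each gene. Under the *universal co-expression null*, every
nucleus expresses both genes and each captured transcript is gene $g$
with probability $f_g$, so detection is
$p_g(T) = 1-(1-f_g)^T$ at depth $T$, double-positives occur at
$p_a p_b$ and single-positives at $p_a(1-p_b)+p_b(1-p_a)$ — dropout
alone. `fit_dropout_null` estimates $f_a, f_b$ by maximum likelihood from
per-nucleus marginal detection and compares observed single-positive
counts per bin to the null via a chi-square statistic (df = bins − 2).
One numerical point matters here: the likelihood and the null
expectations are evaluated at each nucleus's actual depth, not at the
bin midpoint — $p_g(T)$ is strongly nonlinear across a
10 000–20 000-transcript bin, and the midpoint approximation by itself
is enough to reject a true null. Midpoint depths appear only in the
summary table and expectation curves. The binomial capture model and
between-gene independence are the simplest well-posed formalization of
the dropout argument; correlated capture is out of scope. The
generator's `co_express_fraction` controls ground truth, with
non-co-expressing nuclei split evenly between the two single-expressing
classes.

## Numerical choices

* EPSC decay fits start from $A_1 = 0.7\,\hat A$, $\tau_1 = 3$ ms,
  $A_2 = 0.3\,\hat A$, $\tau_2 = 30$ ms with positivity bounds
  (Levenberg–Marquardt) — a robust two-scale start; the fit grid is
  decimated to ≤ 1000 points (stride far below $\tau_1$).
* Sub-threshold derivative segments separated by < 0.2 ms are merged to
  avoid double-triggering on noisy shoulders.
* Degenerate inputs fail loudly: flat traces flag rather than fit,
  pure-noise decay fits error with diagnostics, empty RMS windows and
  zero-duration baseline windows are errors, and a negative corrected
  AR count beyond sampling noise of the spontaneous correction sets a
  flag on the profile.
* All randomness flows from explicit integer seeds; cohort generation
  derives per-cell and per-sweep seeds deterministically, and repeated
  runs are bit-identical.

## Limitations

The detector is a single-pass threshold method: it does not decompose
overlapping events (within ~1 ms) or recover events inside the exclusion
window, and amplitudes of events riding on decay tails are measured
against a local median rather than a deconvolved baseline. The AR
time-course fit is least squares on binned rates; at very low event
counts (e.g. double-knockout cohorts) the pooled $\tau$ estimate is
noisy, and maximum-likelihood fitting on raw event times would be more
efficient. Statistics are per-cell; hierarchical sweep-within-cell
models are deliberately out of scope.
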