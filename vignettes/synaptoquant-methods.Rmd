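---
title: "Models and methods behind synaptoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synaptoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptoquant)
```

`synaptoquant` packages the quantitative chains used to characterize
presynaptic function at the *Drosophila* larval neuromuscular junction:
quantal analysis of spontaneous miniature EPSPs, larval crawling metrics,
paired-scan fluorescence ratios, label-free co-IP enrichment, and Mendelian
cross expectations. This vignette explains each model, its assumptions, the
tunable parameters, and the numerical conventions, and says what the
synthetic-data generators do and do not establish about real data.

## Quantal analysis

### The model

Neurotransmitter is released in quanta (single vesicles). An mEPSP composed
of $i$ quanta is assumed to have amplitude $\mathcal N(i\,q,\ \sigma_i)$,
where $q$ is the quantal size (mV) and $\sigma_i$ the peak SD, and the
quantal content follows a binomial law with $n$ releasable quanta and
release probability $p$:

$$P(i) = \binom{n}{i} p^i (1-p)^{\,n-i}.$$

The predicted histogram content of a bin is the event count times the
binomial-weighted Gaussian mass falling in that bin, pooled over peaks —
a binomial × Gaussian convolution whose peaks sit at integer multiples of
$q$.

Two conventions exist for how the peak SD grows with quantal content. If
quanta vary independently, variances add and $\sigma_i = \sqrt{i}\,
\sigma_0$; an alternative convention scales the SD linearly,
$\sigma_i = i\,\sigma_0$. Both appear in the quantal-analysis literature, and
the linear form sometimes appears where the square-root form is meant. We
expose the choice as `peak_sd_exponent` ∈ {0.5, 1} and default to **0.5**
(variance additivity of independent quanta); every fit object records the
exponent used, so reported quantal sizes are always attributable to a stated
convention.

Spontaneous events necessarily contain at least one quantum, so the binomial
is truncated to $i \ge 1$ and renormalized by $1 - (1-p)^n$ by default
(`truncate = FALSE` restores the full law).

### Fitting

* **Histogram.** Half-open bins $[k w, (k+1) w)$ anchored at 0 mV with
  $w = 0.01$ mV by default. A value exactly on an edge belongs to the right
  bin; the bin index is computed with an epsilon guard so that values such
  as 1.8 mV at $w = 0.01$ are not misplaced by floating-point rounding.
* **Per-bin expectation.** Gaussian mass per bin is computed from CDF
  differences, not midpoint densities, because $\sigma_i$ for small
  $\sigma_0$ can be comparable to the bin width. In the degenerate limit
  $\sigma_0 = 0$ each peak becomes a point mass assigned to the bin
  containing $i\,q$.
* **Objective.** Poisson negative log-likelihood over bins (bin counts are
  Poisson-like at these event numbers); a least-squares mode is available
  for comparison. No objective is canonical in the literature, so the choice
  is stated in the fit output.
* **Optimization.** Outer grid over integer $n \in [1, 10]$; for each $n$,
  multi-start Nelder–Mead plus BFGS polish over $(\log q, \log\sigma_0,
  \operatorname{logit} p)$. Starting values for $q$ come from the first
  autocorrelation peak of the lightly smoothed counts (the dominant peak
  spacing) and from the histogram mode; start jitter is drawn under the
  caller's seed, so fits are deterministic given `seed`. Ties in the
  objective break toward smaller $n$. Non-convergence returns
  `status = "failed"`, never a silent default.
* **Floor.** Fits require ≥ 30 events (`min_events`); below that, amplitude
  histograms are too sparse for the peak structure to be identifiable.

On noiseless expected-count histograms the fit recovers the generating
parameters to better than $10^{-3}$ in $q$; on simulated 500-event
recordings the median relative error of $q$ across seeds is well within
10%. Recovery degrades, as it must, when $\sigma_0/q$ grows toward the
point where neighboring peaks merge.

Event detection from raw voltage traces is out of scope: inputs are event
amplitude lists (CSV with `cell_id, amplitude_mV[, time_s]`).

## Locomotion

The projected area of a crawling larva oscillates once per peristaltic
contraction cycle, so the wave count is the number of area peaks after
denoising:

* **Smoothing.** Savitzky–Golay filter (`signal::sgolayfilt`), default
  window 11 frames (≈ 0.9 s at 12.5 frames/s) and polynomial order 3 —
  wide enough to suppress frame noise, narrow enough to preserve waves at
  the ≥ 2 s periods larvae actually produce. Both are configurable.
* **Peak criterion.** A wave is a local maximum whose prominence is at least
  0.25 × IQR of the smoothed series **and** at least 5% of the series
  median. The IQR term adapts to the oscillation amplitude; the median term
  encodes the physiological fact that a peristaltic contraction modulates
  projected area by tens of percent, so sub-percent ripples that survive
  smoothing in a motionless larva are noise, not waves. Both terms are
  invariant under positive rescaling of the area series (unit or gain
  changes), which is the invariance that matters for tracker output.
* **Metrics.** Distance is the summed Euclidean centroid displacement;
  stride size = distance / waves; stride duration = recording time
  (default 120 s) / waves. Zero waves yields flagged `NA` metrics rather
  than an error. Body length and width are time averages of the spine
  length and mid-spine width columns.
* **QC.** "Escaped" = centroid leaves the arena bounds. "Burrowed" is a
  proxy — projected area below 50% of its median for ≥ 2 s — because a
  buried larva presents little area to the camera; the original exclusions
  were made by eye, so this flag is a conservative automated stand-in.

## Imaging quantification

All quantification is condition-agnostic arithmetic on single-channel
images; the quench/collapse biology lives in the generator (below).

* Z-stacks are reduced by maximum-intensity projection.
* The pH-probe readout is the fraction of pixels **strictly above** a fixed
  threshold, and the ratio of that fraction in the second scan (modified
  solution) over the first (standard saline). The threshold is a required
  input applied identically to both scans — an Otsu-style suggestion is
  available (`suggest_threshold_otsu`) but never applied silently. Area
  fractions are invariant under any strictly monotone intensity transform
  applied with a correspondingly transformed threshold, so the ratio is
  robust to gain and offset differences between sessions (not between the
  two scans of a pair, which must share acquisition settings).
* The FM-dye readout is the dye intensity within the GFP mask:
  released fraction $= 1 - \text{unloaded}/\text{loaded}$. Whether the
  original analyses used summed or mean intensity within the mask is not
  determinable, so both ratios are reported; they coincide for a common
  mask.
* Bouton size: fraction of diameters strictly greater than the 4 μm cutoff
  ("superior to" is read as strict; a bouton at exactly 4 μm is excluded).

## Co-IP enrichment

The chain mirrors vendor label-free quantification and is order-enforced
(each stage checks the object's processing stage and refuses to run out of
order):

1. **TOP3**: protein abundance per (experiment, group) is the mean of the
   three highest peptide intensities; with fewer than three peptides the
   mean of those present is used and flagged — the vendor fallback; the
   original description is silent on this case.
2. **Presence filter**: keep proteins observed in ≥ 1 group in ≥ 2 distinct
   experiments.
3. **Imputation**: missing cells take the minimum observed abundance of
   their experiment. "Of the experiment" is read as the global minimum over
   all proteins and both groups in that experiment (vendor behavior); a
   per-group mode is available behind `scope = "group"`.
4. **Ratios**: per-experiment $\log_2(\text{bait}/\text{control})$.
5. **Call**: enriched ⇔ $\log_2 R_e \ge 1$ in *every* experiment — the
   boundary is inclusive ("at least 2-fold").
6. **Annotation**: enriched proteins matching the bundled V-ATPase subunit
   list (or the `Vha` prefix) are flagged; the immunoprecipitation bait is
   flagged separately and excluded from the subunit count.

The packaged 12-protein log₂-ratio table enters the chain at stage 4 (its
upstream peptide data are not reconstructible), and the loader normalizes
the one decimal-comma cell present in the source table. The vendor's
"background-based" *t* test is proprietary and not reimplemented; the
fold-change-in-all-experiments rule is what defines the enriched set here.

## Cross genetics

`expected_progeny()` enumerates all gamete combinations (one allele per
chromosome per parent, equal segregation, no recombination within
chromosomes — balancers suppress it — and free assortment between
chromosomes), applies lethal rules, and renormalizes over survivors. Lethal
rules are allele-count predicates with optional rescue exemptions, e.g.
`TM6B ≥ 2` (balancer homozygote) or `mutant ≥ 1 & Df ≥ 1 unless UAS`
(unrescued hemizygote). Balancer lethality is an explicit rule, not
hard-coded. In the packaged rescue cross the X-linked driver is carried by
every progeny (homozygous driver mothers), so the rescue predicate reduces
to presence of the autosomal UAS effector; the engine still models the X
when a spec declares it. Expected percentages are exact rationals up to
floating point; reports round to one decimal while comparisons use
unrounded values. The observed sub-Mendelian rescue rate (delayed onset of
driver expression) is a biological interpretation, not something the engine
models — partial-penetrance rescue is out of scope.

## Synthetic-data generators

Every generator embeds its generating parameters (`ground_truth`) so each
downstream stage has a recovery test. Design choices:

* **mEPSPs** — the exact generative process of the fitted model (truncated
  binomial content, Gaussian peaks, optional baseline noise, Poisson event
  times). Amplitudes are redrawn while non-positive, a negligible
  truncation at realistic parameters.
* **Crawler** — area = baseline 6 mm² + 0.8 mm² sinusoid completing exactly
  `n_waves` interior peaks over the 120 s recording, plus Gaussian noise
  scaled to the oscillation amplitude; the centroid advances at constant
  speed along a slowly drifting heading so the path length equals
  `n_waves × stride_mm` by construction. Values emulate a third-instar
  larva (≈ 4 mm long) crawling at typical wave rates.
* **NMJ image pairs** — 2-D Gaussian puncta (σ ≈ 1.6 px) placed on a
  jittered grid so above-threshold footprints never overlap, making the
  programmed area ratios exact up to background noise; the test threshold
  is 3× the background SD and is recorded with each pair. The quench
  condition retains a `vesicular_fraction` of puncta in the second scan;
  the collapse condition reveals a vesicular pool
  `vesicle_membrane_ratio` (default 2) times the membrane pool, so the
  control collapse ratio is ≈ 3.
* **FM pairs** — the unloaded scan is the loaded signal scaled by
  (1 − released fraction) plus background noise; the mask covers the bright
  punctum cores, as a GFP mask would.
* **Co-IP tables** — log-normal protein baselines (median 10⁶, ln-SD 1),
  1–8 peptides per protein with a response gradient and ln-SD 0.25 scatter,
  bait-group abundances multiplied by per-experiment spike folds.
  Missingness is detection-limit dropout: the probability a measurement is
  missing is `missing_rate × (10⁵ / intensity)^1.5` (capped), so
  near-limit measurements drop out while confidently quantified ones are
  essentially always present — the regime in which a protein enriched in
  every experiment is reliably observed there, which is what the
  fold-change rule presumes.

**What passing these tests shows — and does not.** Recovery on synthetic
data demonstrates that the quantification chains are correct implementations
of their stated models at realistic parameter values. It does not establish
performance on real recordings, whose deviations are deliberately absent
here: baseline drift and event-detection errors in electrophysiology,
tracker identity switches and collisions, optical blur, bleaching and
registration error between paired scans, and structured (batch-correlated)
missingness in proteomics. The published group differences (residual
quench signal near 37% in knock-down larvae, ≈ 3-fold collapse in controls,
halved traveled distance) depend on the original raw recordings; they are
represented here only as generator scenarios with those effect sizes, not as
reproducible numbers.

## Problem sizes and determinism

The test suite validates the binomial law exhaustively for $n \le 12$,
compares the theoretical distribution against a 10⁶-event Monte-Carlo
histogram within per-bin Poisson bands, and runs 20-seed recovery studies at
500 events (quantal), 1500 frames (crawler), 192² px image pairs, and
40–60-protein tables — sizes at which the relevant asymptotics already hold
while the full suite runs in a couple of minutes. All stochastic components
take explicit integer seeds through R's default generator, and generator
outputs are bit-identical across runs under a fixed seed.
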