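---
title: "Quantifying proteins by shifting intensity traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying proteins by shifting intensity traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

traceLFQ treats label-free quantification as a single geometric
operation performed twice. Every object to be corrected — a sample, or
one ion of one protein — is a *trace*: a vector of log2 intensities over
a shared feature axis, with `NA` for unobserved features. Systematic
biases (sample loading, spray stability, ionization efficiency) are
multiplicative in linear intensity, hence additive constants in log2.
The model is therefore

\[ t_i = p + s_i + \varepsilon_i, \]

a common shape \(p\) plus one offset \(s_i\) per trace plus noise, and
fitting means recovering the \(s_i\) without ever altering a trace's
shape. Between-sample normalization fits this model with samples as
traces over the ion axis; protein intensity estimation fits it per
protein with ions as traces over the sample axis, taking the per-sample
median of the aligned traces as the relative protein profile. The
profile is rescaled into linear space by one factor — total ion
intensity of the protein divided by the total of the back-transformed
profile — so each protein conserves its summed ion signal exactly.

## The alignment engine

Each pair of traces is compared on the features observed in both:
the median of the element-wise difference estimates the pairwise shift,
the variance of that difference measures shape divergence. The engine
keeps a variance and a median half-matrix, repeatedly merges the
comparable pair with the smallest variance (the second member is shifted
onto the first by the pairwise median), replaces it by an averaged
trace, and recomputes only the matrix entries involving the new trace.
Merging the most similar traces first keeps each individual shift
estimate as precise as possible, and the averaged trace both suppresses
noise and fills missing features from whichever member observed them.
Shifts applied to an averaged trace are propagated to all underlying
original traces.

Since the pairwise stage is quadratic, it is capped: with more than
`nmax` traces, the `nmax` traces with the fewest missing values are
merged as above, and every remaining trace is shifted independently
toward the frozen anchor average by one pairwise median. The package
counts comparisons between *measured* traces — the initial half-matrix
plus one comparison per remaining trace, bounded by
\(n_{max}(n_{max}-1)/2 + (n-n_{max})\) — as the unit of the
linear-scaling contract; the per-merge row/column updates involve one
derived averaged trace each, are reported separately
(`n_update_comparisons`), and scale with the same bound.

## Parameters that matter

* `nmax_samples = 50` and `nmax_ions = 10` — caps on the pairwise stage
  for normalization and protein estimation. Robustness of the result to
  this cap (checked from 5 to 100 in the test suite) rests on the most
  complete traces already being an excellent alignment basis.
* `min_ions = 1` (dimensionless count) — minimum ion evidence for a
  protein to be reported. There is no inherent reason to discard
  single-ion proteins, so the default keeps them; raising it trades
  coverage for stability.
* `stat = "median"` — the pairwise shift statistic. The median assumes
  the majority of co-observed features are unregulated. The `"mode"`
  option (kernel-density peak of the difference distribution) relaxes
  that assumption at the cost of stability in noisy data and is
  off by default.
* `subset_proteins` — housekeeping set: normalization traces are built
  only from these proteins' ions while the factors are applied to the
  whole table; the escape hatch when the unregulated-majority
  assumption is known to fail.

## Numerical choices

* Variance of a difference distribution uses the conventional \(n-1\)
  denominator. Pairs overlapping in a single feature keep a defined
  median but get variance `Inf`, so they merge last; pairs with no
  overlap are incomparable (`NA`) and are never merged.
* Ties in the minimum variance resolve to the lowest (row, column) pair
  in the current matrix order; with identical inputs the engine is
  bit-for-bit deterministic and contains no randomness.
* Averaged traces weight members by their `n_members` count, which
  makes the average of \(k\) complete traces independent of merge
  order.
* Shifts are defined only up to one global constant. Normalization
  fixes the gauge by re-centering factors to median 0, preserving the
  dataset's overall intensity scale; protein profiles inherit their
  scale from the conservation rescaling instead.
* Zero, negative or absent linear intensities are treated as missing
  before the log2 transform. Duplicate (ion, sample) records are summed
  in linear space at ingestion (total-signal semantics); ions assigned
  to several protein groups are dropped, since protein grouping belongs
  to the upstream search engine.
* Trace sets whose overlap graph is disconnected never fail a run: the
  largest merged component defines the result, all other traces keep
  shift 0 and a flag (if nothing can be merged at all, every trace is
  flagged).
* The conservation factor divides by the sum over samples of the
  protein's own back-transformed profile; the alternative reading
  (summing over all proteins) would break per-protein conservation and
  is rejected.

## What the simulator emulates — and what it does not

`sim_config()` / `simulate_lfq()` generate two-condition mixed-species
spike-in designs with full ground truth: per-protein base log2
intensities uniform over 18–30 (four orders of magnitude), per-ion
ionization offsets (Gaussian, sd 2 log2 units), species-block fold
changes applied to condition 1, per-sample loading offsets (uniform on
±1 log2 by default), additive Gaussian noise in log2 space (log-normal
multiplicative error, the standard model for MS intensity noise), and
left-censored missingness: records drop with a logistic probability in
their log2 intensity, calibrated by root finding so the marginal
missing fraction matches the configuration. DIA-style acquisition is
emulated by giving each precursor one MS1 trace plus a configurable
number of fragment traces, each an independent ion.

Not emulated: chromatographic distortion (nonlinear, retention-time
dependent biases), peptide interference and mis-identification, isotope
patterns, and protein-grouping ambiguity. Passing tests on these
simulations therefore demonstrate correctness of the estimator under
multiplicative bias, log-normal noise and left-censoring — not immunity
to nonlinear artefacts, which a single factor per sample cannot correct
by construction.

## Known limitations

* **One linear factor per sample.** Intensity-dependent or
  retention-time-dependent distortions are not corrected; only the
  linear component of such effects is removed.
* **Median contamination bias.** The pairwise median is robust to a
  minority of regulated features only in the limit of small noise. When
  a fraction \(f\) of co-observed features is regulated in one
  direction, the median of the cross-condition difference distribution
  is displaced by approximately
  \(\Phi^{-1}\!\big(0.5/(1-f)\big)\,\sigma_d\), where \(\sigma_d\) is
  the noise spread of the unregulated differences. The displacement
  vanishes as \(\sigma_d \to 0\) (the noise-free pipeline is exact to
  float precision, which the test suite asserts at 1e-9) but is
  material for heavy one-sided designs: the simulated DDA benchmark
  (one third of ions spiked 6-fold, noise sd 0.3) shows the expected
  \(\approx 0.674\sqrt{2/3}\cdot 0.3 \approx 0.17\) log2 displacement
  in the recovered species medians, which the benchmark tests measure.
  Balanced up/down regulation largely cancels the effect, and the
  housekeeping subset or the mode statistic avoid it when the
  contamination is known or extreme.
* **Ions, not proteoforms.** Quantification inherits the upstream
  engine's protein groups; peptide-level interference filtering and
  proteoform resolution are out of scope.

## Problem sizes in the test suite

The bundled checks run at desk scale by design: benchmark simulations
use 600 proteins (DDA: 2–6 precursors each; DIA: 2–4 precursors with
1 MS1 + 3 fragment traces) over 3 + 3 samples; the nmax-robustness check
normalizes 100 samples; the linear-scaling bound is instrumented at 60,
200 and 1000 sample traces; oracle equivalence fuzzes 200 trace sets of
up to 8 traces against a naive full-recomputation reference. The
complete suite and the benchmark script each finish in well under a
minute on one CPU.
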