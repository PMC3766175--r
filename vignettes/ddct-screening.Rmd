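---
title: "Two-stage ΔΔCt screening: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage ddCt screening: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddctscreen)
```

## The measurement model

A low-density qPCR array reports, per well, the cycle Ct at which
fluorescence crosses threshold; each extra cycle corresponds to a doubling,
so Ct is a log2-scale abundance measurement (lower = more template). Three
nuisance structures dominate such data: per-sample loading differences
(every Ct in a sample shifts by a constant), technical noise that is
approximately normal in Ct (not in linear abundance), and left-truncation
of weak signals — a run of 40 cycles cannot report Ct ≥ 40, so those wells
come back "Undetermined".

The pipeline mirrors the classical relative-quantification algebra:

* **ΔCt**: `delta_ct()` subtracts the mean Ct of the sample's detected
  endogenous-control wells. Because loading acts additively on every well
  of a sample, ΔCt is exactly loading-invariant (a property the test suite
  checks on perturbed data).
* **ΔΔCt / RQ**: `delta_delta_ct()` anchors each assay at one designated
  calibrator sample and reports RQ = 2^−ΔΔCt, so the calibrator has RQ = 1
  for every assay detected in it.
* Non-detected wells stay missing through every stage. We deliberately do
  not impute Ct at the detection limit: imputation at 40 would fabricate
  the strongest possible "low expression" values exactly where the
  instrument is least informative.

### Calibrator policy

Group summary tables of this kind show control-group mean RQs that are not
1, which rules out calibrating each group on its own mean. The default is
therefore a single designated calibrator sample (the first control), with
`calibrator = "control_mean"` available when a per-assay control-group
anchor is preferred. The choice only rescales every RQ of an assay by a
common factor, so fold-changes and both test statistics are unaffected;
what changes is the interpretation of an individual RQ value.

### Aggregation choices

Replicate wells and endogenous-control wells are collapsed by the
arithmetic mean of the *detected* members (median selectable). Mean
aggregation in Ct space corresponds to a geometric mean in linear
abundance, the conventional choice for qPCR.

## Flags and retention

Within each sample, `classify_sample()` ranks all detected assays by ΔCt
and labels the strongest quartile `good`, the weakest `low`, the middle
half `normal`. Two conventions make this bit-reproducible:

* quantiles use linear interpolation between order statistics (R's default
  type 7), and both boundaries are inclusive (`ΔCt ≤ Q1` is `good`,
  `ΔCt ≥ Q3` is `low`);
* with fewer than 4 detected assays, or when Q1 = Q3 (massive ties), the
  affected assays are `normal` — the quartile has no meaning there, so the
  conservative label is used.

The quartile population is *within a sample across assays* ("this miRNA is
among the strongest expressed in this sample"), not within an assay across
samples; the alternative reading is possible but would measure
between-sample consistency rather than expression strength, and the `good`
and `low` wording ("strong/weak expression") points at the former. The
fraction `q = 0.25` is configurable.

`retention_filter()` keeps assays detected in at least 2 samples per group
— the minimum for a sample SD — and `confidence_tier()` triages candidates:
any `low` flag anywhere demotes to `low`; `good` flags in both groups with
no `low` promotes to `top`; everything else is `medium`. Assays with `good`
flags in exactly one group sit between the two published definitions; they
are assigned `medium`, the conservative option.

## The composite screen

Group statistics and fold-changes are computed on the linear RQ scale,
matching the magnitudes such tables print (means near 1). Fold-changes use
the signed convention r ↦ r if r ≥ 1 else −1/r, which makes up- and
downregulation symmetric (|fc| ≥ 1 always, and fc(1/r) = −fc(r)).

The Welch unequal-variance t-test also runs on RQ by default. Linear-scale
RQ values are lognormal under the noise model, so the t-test is not exact
there; the suite verifies that its null rejection rate at the 0.1 threshold
stays within [0.08, 0.12] under the study design (10+10 samples). Analysts
who prefer an exactly-normal test scale can set `scale = "ddct"` to test
the log2 values instead — fold-changes and summaries stay on the RQ scale
either way.

The differential-expression rule is an inclusive union — p ≤ 0.1, or
|mean fc| ≥ 2, or |median fc| ≥ 2 — designed for high intra-group
variability, where a fold-change criterion can rescue assays a small-n
t-test misses, and vice versa. It applies no multiple-testing correction;
`q_bh` (Benjamini–Hochberg) is emitted as a clearly separate column for
readers who want it, and plays no role in the call.

Degenerate inputs follow documented conventions: zero variance in both
groups gives p = 1 when the means agree and p = 0 when they differ, which
makes the noiseless limit of the simulator behave sensibly (planted effects
are called, nulls are not).

## The validation stage

`run_validation()` aggregates triplicates, normalizes against the panel's
endogenous control (RNU6B on the custom card), and compares groups with a
two-sided Mann–Whitney–Wilcoxon test; significance is strict (p < α with
α = 0.05). Mode selection:

* **exact** (nx·ny ≤ 64, no ties): p from the exact U distribution;
* **approximation** otherwise: normal with tie-corrected variance and
  continuity correction, plus — for tie-free data — an Edgeworth term using
  the closed-form excess kurtosis of U,
  γ₂ = −(6/5)(nx² + ny² + nx·ny + N) / (nx·ny(N + 1)).

The kurtosis term is what lets the approximation track the exact p to
within about 5·10⁻⁴ already at 8 + 8 samples; the plain corrected normal
is off by up to 0.011 there, which is material when screening near a 0.05
cutoff. Far in the tails, where the expansion can leave [0, 1], the plain
normal CDF is used. When every pooled value is tied the test is
uninformative and p = 1 by convention.

Median RQ summaries are reported per group as `median (min–max)` strings,
mirroring the usual validation-table format.

## The synthetic-data generator

`generate_dataset()` draws Ct values as

Ct(i, j, r) = B_i + L_j − log2(f_i)·[j is a case] + ε_ijr

with assay baselines B ~ U(22, 35), loading L ~ N(0, 0.5²), noise
ε ~ N(0, 0.4²) (all in cycles), endogenous-control wells at Ct 20 with
f = 1 under the same noise, and censoring at 40 cycles. Additivity in Ct
makes ΔΔCt an unbiased estimator of the planted log2 fold-change, so the
noiseless limit recovers planted effects exactly — the suite asserts this.
The discovery defaults (667 assays, 10+10 samples, 8 endogenous-control
wells, single wells per assay) and validation defaults (15 assays + RNU6B,
21+25 samples, triplicates) reproduce the two-stage design the package
targets. The noise magnitudes are round values chosen so that intra-group
CVs of the simulated RQ values fall in the tens of percent, the range such
screens report; with them, planted |f| = 4 effects are recovered with
essentially full power at 10+10.

What the generator does **not** emulate: PCR efficiency different from 2,
card/batch effects and the A/B card split, correlated miRNA co-regulation,
and any dropout mechanism other than threshold censoring. Passing tests on
synthetic data therefore demonstrate the correctness of the pipeline's
algebra and decision rules under its stated model — not robustness to
efficiency bias or batch structure in real cards.

## Problem sizes and determinism

The test suite and the acceptance script run the generator at the study's
design sizes (667 and 2,000 assays, 10+10 samples; validation 15 assays at
21+25×3), which keeps a full run in the tens of seconds. All randomness
flows through a single integer seed per generated dataset (`withr`-scoped,
no global RNG state), and `run_all()` writes a manifest with the full
configuration and MD5 checksums — identical configuration reproduces every
output byte for byte.

## Known limitations

* Quantification assumes perfect doubling; no Pfaffl-style efficiency
  correction.
* The screen's p ≤ 0.1 criterion is intentionally uncorrected for multiple
  testing; it is a triage rule, not an inference, and the validation stage
  carries the confirmatory burden.
* Exact Mann–Whitney p-values are unavailable under ties (the approximation
  is used); this matches standard practice.
* The flag quartile population and the t-test scale are field conventions
  left configurable because published methods sections rarely pin them
  down; defaults are documented above.
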