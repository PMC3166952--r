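---
title: "Calibrated copy-number calling and case-control analysis with the paralogue ratio test"
author: "prtcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated copy-number calling and case-control analysis with the paralogue ratio test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prtcnv)
```

## The measurement problem

Multiallelic copy-number variants — loci such as the CCL3L1/CCL4L1
copy-variable region, where diploid genomes carry anywhere from 0 to about
9 copies — are among the hardest variants to genotype accurately. The
paralogue ratio test (PRT) addresses this with a single primer pair that
co-amplifies a copy-variable *test* locus and a copy-constant paralogous
*reference* locus in one reaction; after capillary electrophoresis, the
ratio of test to reference peak areas estimates the copy number. Because
both products share primers and reaction conditions, most amplification
artefacts cancel in the ratio.

Accuracy matters beyond the individual genotype. In a case–control
association study, a *systematic* shift of the raw measurements between
case and control sample batches ("differential bias", typically traceable
to DNA extraction chemistry) can push samples across integer boundaries
asymmetrically and manufacture a false-positive association. A central
goal of this package is therefore not only to call integer copy numbers
but to quantify measurement precision and to screen explicitly for
differential bias before any association test is interpreted.

`prtcnv` implements the full analysis chain:

1. **Calling** (`callCopyNumbers()`): peak-area ratios → per-plate linear
   calibration → unrounded copy numbers per PRT system → combined value →
   integer call with concordance classification.
2. **Error model** (`classStatistics()`, `misclassProbability()`,
   `normalityCheck()`): per-class precision and Gaussian misassignment
   probabilities.
3. **Bias detection** (`biasScan()`, `biasTest()`, `systemHomogeneity()`):
   per-class case-vs-control comparison of raw values with cumulative
   frequency curves.
4. **Association and power** (`associationTest()`, `powerSimulation()`):
   count-table Welch tests and a per-copy odds-ratio power simulation.
5. **Synthetic data** (`PRTSimConfig()`, `sampleGenotypes()`,
   `generatePeakTable()`): a generator that emulates the statistical
   structure of real PRT peak-area tables, so every stage is testable
   without instrument data.

## Calibration and integer calling

Each 96-well plate carries, per PRT system, reference DNA standards of
established copy number (CN 1–4, in triplicate) alongside the unknowns.
For each plate and system the standards' ratios are regressed on their
known copy numbers by ordinary least squares,

$$\mathrm{ratio} = a\,\mathrm{CN} + b,$$

and the unknowns' ratios are inverted through the fitted line,
$\widehat{\mathrm{CN}} = (\mathrm{ratio} - b)/a$. Calibration is kept
strictly per plate: the standards ride in every PCR, so plate-level
efficiency differences are absorbed by the line rather than leaking into
the calls.

Design choices worth knowing:

* **Regression direction.** The ratio (the noisy quantity) is the
  response and the known integer the predictor; the fit is then inverted.
  Regressing the noisy variable on the exact one is the standard
  calibration orientation.
* **Negative values are kept.** Zero-copy samples scatter slightly below
  zero after calibration (the class-0 mean of a large real dataset is
  around −0.03); clamping happens only at integer assignment, never in
  the statistics.
* **Tie rule.** Values exactly half-way round away from zero and are
  flagged (`boundary_call`); real data essentially never sit on the
  boundary, but the rule must be deterministic.
* **Combination.** The unrounded values of all usable systems (and of
  repeat runs of the same sample) are combined by arithmetic mean; a
  sample with every system failed is reported as *missing*, not silently
  dropped.
* **Concordance.** Systems are compared against the consensus integer
  (the call derived from the combined mean). If all per-system values lie
  within 0.5 of it the call is `concordant_05`; within 0.75,
  `concordant_075`; otherwise `discordant`. The categories are nested
  (within-0.5 implies within-0.75), matching how cumulative concordance
  percentages are reported in practice. Discordant samples are left
  unresolved — in the laboratory workflow they would go to an orthogonal
  assay such as microsatellite genotyping, which enters here only as an
  optional externally supplied resolution table.

```{r calling-example}
cfg <- PRTSimConfig(
  controlFrequencies = c("1" = 0.2, "2" = 0.6, "3" = 0.2),
  nCases = 60, nControls = 60, seed = 101
)
calls <- callCopyNumbers(generatePeakTable(sampleGenotypes(cfg), cfg))
calls
```

## The Gaussian error model

Germline copy numbers are integers, so the unrounded values of a
well-behaved assay cluster tightly around integers and the spread of each
cluster measures precision. For each class $n$, `classStatistics()`
reports the sample mean $\mu_n$, SD $\sigma_n$ ($n-1$ denominator), and
the *normalised* SD $\sigma_n/n$, which makes precision comparable across
classes. Under the assumption that measurements of a true $n$-copy sample
are $\mathcal{N}(\mu_n, \sigma_n)$, the probability of assigning a wrong
integer is the mass outside the rounding window:

$$P_n = \Phi\!\left(\tfrac{n-0.5-\mu_n}{\sigma_n}\right) + 1 -
  \Phi\!\left(\tfrac{n+0.5-\mu_n}{\sigma_n}\right),$$

with only the upper term for $n = 0$ (negatives clamp to 0, so there is
no lower boundary; the class-0 probability is reported but flagged
`one_sided` and is not comparable with the others). Classes with fewer
than 5 samples get no probability — a fitted normal on 1–4 points is not
evidence. The normality assumption itself is checkable per class with
`normalityCheck()` (one-sample Kolmogorov–Smirnov against the fitted
normal, plus Q–Q coordinates); note the KS p-value is approximate because
the parameters are estimated from the same data.

```{r error-example}
misclassProbability(2.021, 0.142, 2L)
misclassProbability(4.977, 0.346, 5L)
```

With a class SD near 0.14 at two copies the misassignment probability is
a few in ten thousand; at five copies, with SD ~0.35, it rises to ~15% —
precision has to be judged per class, not globally.

## Differential bias

`biasTest()` compares the case and control unrounded values *within one
integer class* by a two-tailed Welch t-test and returns both empirical
cumulative-frequency curves. `biasScan()` runs this over every class with
enough samples in both groups and flags the most populated class as
primary — it has the greatest power to show a shift; the remaining
classes corroborate (their p-values are reported unadjusted and labelled
as such — the workflow treats them as secondary evidence, not independent
discoveries). `systemHomogeneity()` applies the same logic across the PRT
systems within a class, which must agree before their values may be
pooled.

Welch's unequal-variance form is used for every t-test in the package:
with near-equal variances it is asymptotically identical to the pooled
test, and it is robust when batch effects also inflate one group's
variance.

Two properties are worth stating precisely. A shift applied equally to
both groups is invisible by construction — the test is differential. And
a shift small relative to half a copy (e.g. 0.12 copies at class 2 with
SD ~0.14) barely moves any sample across an integer boundary, so integer
calls and downstream association tests are essentially unchanged even
when the raw-value test is overwhelmingly significant; this is exactly
why bias screening must look at raw values, not at calls.

## Association and power

`associationTest()` expands a copy-number count table to one integer per
individual and compares case and control means by a Welch t-test; a
`PRTCallSet` is first tabulated from its resolved calls. The package
ships the published count tables of three European case–control cohorts
(`cohortCounts("crohn")`, `"rheumatoid"`, `"psoriasis"`) as plain-text
fixtures; all three reproduce the negative published findings
(p > 0.05).

Power for such a design is estimated by simulation under a per-copy
multiplicative odds model: the case distribution is the control
distribution tilted by $\mathrm{OR}^c$ and renormalised
(`caseDistributionUnderOR()`). Each replicate draws multinomial cohorts
and applies the same Welch test used on real tables (computed from counts
for speed; the count form is verified against the expanded form in the
test suite). The per-copy trend model is the standard convention when the
effect mechanism of a multiallelic CNV is unspecified, and it is isolated
behind `caseDistributionUnderOR()` so a threshold-dichotomised exposure
could be added without touching the simulator.

```{r power-example, eval = FALSE}
ctrl <- setNames(cohortCounts("crohn")$control_count / 252,
                 cohortCounts("crohn")$cn)
ctrl <- ctrl[ctrl > 0]
powerSimulation(ctrl, n_cases = 616, n_controls = 252,
                odds_ratio = 1.5, n_replicates = 10000, seed = 1)
```

At OR 1.5 this design exceeds 90% power at $\alpha = 0.05$; at OR 1.3 it
drops to roughly 70%, and at OR 1 the rejection rate sits at the nominal
5% — the null calibration is part of the test suite.

## What the synthetic generator emulates — and what it does not

The generator works backwards through the measurement model. For a
sample with true copy number $c$, every measurement's unrounded value is

$$c + b\,[\mathrm{case}] + \epsilon_{\mathrm{sample}} +
  \epsilon_{\mathrm{system}},$$

where $b$ is the configured differential-bias shift and the error SD is
$s(c) = \sqrt{\sigma_f^2 + \sigma_0^2\,c}$. The value is then mapped
through a per-plate, per-system linear response (slope ~0.5 with ~5%
plate-to-plate log-normal scatter, small non-negative intercept) to a
ratio, and rendered as a reference peak area (log-normal jitter, sigma
`refAreaCV`) and a test peak area. Standards (CN 1–4 × 3) are added per
plate with the same noise law. Defaults:

| parameter | default | rationale |
|---|---|---|
| `sigma0` | 0.10 | per-class SDs of a large real dataset track $0.10\sqrt{c}$ (0.097, 0.142, 0.178, 0.203 for CN 1–4) |
| `sigmaFloor` | 0.068 | the observed zero-copy class SD; $s(c)$ cannot vanish at $c=0$ |
| `sigmaSystemFrac` | 0.2 | fraction of $s(c)$ that is system-specific (see below) |
| `biasShift` | 0 | set to e.g. −0.12 to emulate the psoriasis-style case shift at two copies (case/control class-2 means 1.91 vs 2.03) |
| `referenceBaseArea`, `refAreaCV` | 5000, 0.15 | typical fluorescence scale; cancels exactly in the ratio |
| `plateSize` | 84 | 96 wells minus 12 standard wells |

**Why the error is split into sample and system components.** Observed
per-class SDs describe the *combined* (mean-of-systems) value, yet each
single-system measurement is also about that noisy — if the three
systems' errors were independent, the combined SD would be
$\sqrt{3}$-fold smaller than the per-system SD, which is not what real
duplicate and concordance data look like. The generator therefore draws
one sample-level error (SD $s(c)\sqrt{1-\rho^2}$, shared by all systems
*and by repeat runs of the same DNA*) plus an independent per-system
error (SD $s(c)\rho$), with $\rho$ = `sigmaSystemFrac` = 0.2. Each
single measurement then has SD exactly $s(c)$, the combined value has SD
$s(c)\sqrt{1-2\rho^2/3} \approx 0.99\,s(c)$, and inter-plate duplicates
of one sample agree far more closely than two different samples — as
internal duplicates do in practice. The bias shift is likewise applied
uniformly to all systems of a case sample, since the physicochemical
property that causes it belongs to the DNA preparation, not to one PCR
system.

Numerical fine print, established empirically in the test suite:

* With all noise parameters at 0 the pipeline inverts the generator
  exactly (to ~1e-15): calibration + inversion is the exact inverse of
  the forward map.
* Calibrated class SDs recovered from synthetic cohorts are inflated a
  few percent at CN 1 by calibration-line prediction error at the edge of
  the standards range (CN 1 and 4 are the high-leverage points of a
  12-point line); this is a real property of per-plate calibration, not a
  bug, and it is why precision estimates from small plates should be read
  with their standard errors.
* Grouping values by *assigned* integer truncates each class's tails at
  the rounding boundaries and therefore understates the class SD when
  $s(c)$ approaches 0.25; parameter-recovery checks use the generator's
  ground truth for grouping.

The generator does **not** emulate: electropherogram traces, stutter or
other peak-shape artefacts (peak areas are taken as given, mirroring the
position of this analysis downstream of the fragment-analysis software);
assay dropout or DNA-concentration failures (failed records can be
injected by construction); plate-position effects within a plate;
copy-number discordance between the test loci of different systems; and
any haplotype structure — genotypes are multinomial on diploid totals,
which is all the diploid-level analysis consumes. Passing tests on
synthetic data therefore demonstrate the *statistical machinery*
(calibration, combination, error model, bias detection, power), not
robustness to raw-trace artefacts.

## Problem sizes and reproducibility

The test suite and examples use cohorts of a few hundred to ~1500
samples, 1000-replicate bias simulations and 10,000-replicate power
runs — sizes chosen to keep every Monte-Carlo standard error an order of
magnitude below the tolerances being asserted while the whole suite runs
in seconds. All randomness flows from explicit seeds: the generator from
`PRTSimConfig@seed`, `powerSimulation()` from its `seed` argument, and a
pipeline run (`runPrtPipeline()`) from the single seed recorded in its
manifest, so a configuration reruns to byte-identical call tables.

## Known limitations

* Integer calling is nearest-integer on the combined mean; no mixture
  model or posterior class probability is fitted. At the precision the
  error model documents (misassignment ~5×10⁻⁴ at two copies) this is
  adequate below ~5 copies, but the same model predicts ~15% error at
  five copies — high-copy calls should be treated as estimates, and the
  per-class probabilities are the honest statement of that.
* Bias is detected, not corrected: the remedy for a detected shift is
  upstream (sample pre-treatment, re-extraction), and the scan's job is
  to stop a biased dataset from reaching the association stage
  unexamined.
* The per-copy odds model is one convention; a different exposure model
  (e.g. any-amplification threshold) would give different power numbers.
* Secondary class p-values in `biasScan()` carry no multiplicity
  adjustment and are labelled accordingly.
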