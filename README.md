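# prtcnv — paralogue ratio test copy-number calling and case–control analysis

`prtcnv` is an R package for genotyping multiallelic copy-number variants
(CNVs) from **paralogue ratio test (PRT)** data and for running the
quality-control and association analyses such genotypes feed into. The
motivating locus is the CCL3L1/CCL4L1 copy-variable region (0 to ~9
diploid copies in Europeans), measured by three multiplexed PRT systems
(CCL3C, CCL4A, LTR61A), but nothing in the package is specific to that
locus.

A PRT co-amplifies a copy-variable test locus and a copy-constant
paralogous reference locus with one primer pair; after fragment analysis,
the test/reference peak-area ratio estimates copy number. The package
implements the full downstream chain:

* **Calibration and calling.** Per plate and per PRT system, the ratios of
  reference standards of known copy number (CN 1–4 in triplicate) are
  regressed on CN (`ratio = a·CN + b`, OLS) and unknowns are inverted
  through the line. Per-system unrounded values are combined by arithmetic
  mean, rounded to the nearest non-negative integer, and classified as
  concordant (all systems within 0.5 / 0.75 of the consensus integer) or
  discordant (left unresolved unless externally resolved).
* **Gaussian error model.** Per integer class *n*: mean μₙ, SD σₙ,
  normalised SD σₙ/n, and the misassignment probability
  `P = Φ((n−0.5−μₙ)/σₙ) + 1 − Φ((n+0.5−μₙ)/σₙ)`
  (one-sided for n = 0), plus a Kolmogorov–Smirnov normality check.
* **Differential-bias detection.** Within each integer class, case and
  control *unrounded* values are compared by a two-tailed Welch t-test
  with empirical cumulative-frequency curves — the screen that catches
  systematic case-vs-control measurement shifts (from, e.g., different
  DNA extraction chemistry) before they can masquerade as association.
* **Association and power.** Welch t-tests on integer count tables, and a
  power simulation under a per-copy odds-ratio model (case class
  probabilities ∝ control probabilities × ORᶜ). The published count
  tables of three European case–control cohorts (Crohn's disease,
  rheumatoid arthritis, psoriasis) ship as plain-text fixtures.
* **Synthetic data.** A generator that inverts the measurement model —
  true genotypes → noisy unrounded values → per-plate peak areas with
  calibration standards — with a configurable noise law
  `s(c) = sqrt(sigmaFloor² + sigma0²·c)` and an optional injected
  case-vs-control shift, so the entire pipeline is testable end to end.

See the methods vignette (`vignettes/prt-copy-number.Rmd`) for the model,
parameter defaults and design rationale.

## Worked example

Simulate a psoriasis-style scenario — identical genotype distributions in
both cohorts, but case measurements systematically shifted down by 0.12
copies — then call, QC, and test:

```r
library(prtcnv)

cfg <- PRTSimConfig(
  controlFrequencies = c("0" = 0.016, "1" = 0.194, "2" = 0.591,
                         "3" = 0.179, "4" = 0.02),
  nCases = 200, nControls = 200, biasShift = -0.12, seed = 11
)
calls <- callCopyNumbers(generatePeakTable(sampleGenotypes(cfg), cfg))
calls
#> PRTCallSet with 400 samples, 3 PRT systems
#>   systems: CCL3C, CCL4A, LTR61A
#>   concordance: concordant_05=398, concordant_075=2, discordant=0, missing=0
#>   resolved integer calls: 400 of 400
#>   integer classes: 0:9 1:82 2:244 3:63 4:2
```

All 400 samples are called, 398 with every system within 0.5 of the
consensus integer. Per-class precision:

```r
classStatistics(calls)
#>   integer_cn n_samples  mean     sd normalised_sd probability_of_error
#>            0         9 0.018 0.1159            NA             0.000016
#>            1        82 0.970 0.1563        0.1563             0.001676
#>            2       244 1.944 0.1562        0.0781             0.002438
#>            3        63 2.920 0.1927        0.0642             0.015875
#>            4         2 3.959 0.0845        0.0211                   NA
```

Class means sit within 0.1 of their integers and the class-2
misassignment probability is ~2×10⁻³: the injected shift is far too small
to move calls across integer boundaries. The bias scan, which looks at
the *raw* values, sees it immediately — while the integer-level
association test (correctly) finds nothing:

```r
biasScan(calls)$table
#>   integer_cn case_n control_n case_mean control_mean t_statistic  p_value primary
#>            1     39        43     0.887         1.04       -5.27 1.12e-06   FALSE
#>            2    131       113     1.896         2.00       -5.49 1.00e-07    TRUE
#>            3     26        37     2.847         2.97       -2.68 9.70e-03   FALSE

a <- associationTest(calls)
#> association: t = -0.66, p = 0.51
```

That is the package's central point in one screen: a 0.12-copy
differential shift is overwhelmingly detectable in the raw measurements
(class 2: p = 1e-07) long before it perturbs integer calls — and a
measurement method precise enough to show this is what keeps such shifts
from ever surfacing as false associations.

The published cohort tables reproduce their negative findings, e.g.:

```r
associationTest(cohortCounts("crohn"))$p_value
#> [1] 0.1484525
```

A full configured run (simulate → call → qc → bias → assoc, with a JSON
manifest) is one call:

```r
runPrtPipeline(system.file("extdata", "psoriasis_scenario.yaml",
                           package = "prtcnv"), "out/")
```

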