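# morphopool

Precision analysis for **cluster scanning**: quantifying the test-retest
measurement error of MRI-derived brain morphometric estimates and the
precision gained by averaging ("pooling") estimates from several
~1-minute compressed-sensing (CS) structural scans instead of relying on
one traditional ~5-minute scan.

It is written for neuroimaging methodologists and study designers who
work with FreeSurfer-style regional outputs (subcortical volumes,
Desikan-Killiany cortical thickness and gray-to-white signal intensity
ratio) and need to answer questions like: *how much error does one scan
carry, how fast does pooling drive it down, does a repositioning break
or mixing scan resolutions help, and what does a given precision buy me
in longitudinal sample size?*

## The statistics at its core

* **Percent error** of a measure across a test-retest pair:
  `100 · |v₁ − v₂| / ((v₁ + v₂)/2)`, applied to single-scan or pooled
  session estimates.
* **√k benchmark**: with uncorrelated per-scan errors, pooling `k` scans
  is expected to reduce error to `e₁/√k` (a 65% reduction at `k = 8`).
* **Equicorrelation closed form**: with pairwise error correlation ρ the
  pooled error SD is `σ·√((1 + (k−1)ρ)/k)`; shared session/block error
  components generate ρ and dampen the pooling benefit.
* **Autocorrelation estimation**: `E[Δ²ₖ] = a + b/k` fitted over
  pooling depths, `ρ̂ = a/(a+b)`, with a subject-level bootstrap CI.
* **Precision → power**: the half-normal link `SD = mean error · √(π/2)`
  feeds a standard normal-approximation sample-size formula for
  detecting longitudinal change.

A hierarchical multiplicative noise simulator (subject, session, block,
scan and resolution components) emulates the full two-session protocol —
per session one ADNI reference scan, eight CS 1.0 mm scans split by a
break, and eight multi-resolution CS scans — over three participant
groups (12 younger adults, 18 cognitively unimpaired older adults, 10
MCI/AD), so every stage is testable without any imaging data. See
`vignettes/cluster-scanning-precision.Rmd` for models, calibration and
limitations.

## Worked example

```r
library(morphopool)

model  <- defaultNoiseModel()      # calibrated: e1 ~3.0% CS / 2.9% ADNI, rho 0.2
design <- defaultStudyDesign()     # 40 subjects, 2 sessions, 17 scans/session
study  <- simulateStudy(model, design, seed = 11)

curve <- poolingCurve(study)       # first-k CS pooling vs the ADNI reference
curve$summary[, c("k", "mean_pct", "expected_sqrt_pct", "duration_s",
                  "reduction_vs_reference_pct", "fraction_improved_pct")]
#>   k mean_pct expected_sqrt_pct duration_s reduction_vs_reference_pct fraction_improved_pct
#> 1 1     2.99              2.99         72                      -2.16                  45.4
#> 2 2     2.26              2.11        144                      22.67                  94.1
#> 3 4     1.88              1.49        288                      35.91                  99.3
#> 4 8     1.50              1.06        576                      48.61                 100.0
```

Reading the table: a single CS scan (72 s) is slightly noisier than the
ADNI reference (2.99% vs 2.93%), but pooling four CS scans — still less
scan time than one ADNI (288 s vs 312 s) — cuts the mean error by ~36%,
and it improves nearly every one of the 152 measures. The observed
decline is slower than the `expected_sqrt_pct` overlay because the
model's errors are autocorrelated (ρ_same = 0.2); the estimator recovers
that:

```r
set.seed(11)
rho <- estimateRho(study)
#> rho-hat = 0.163 (95% CI 0.149-0.177)   # between rho_cross 0.1 and rho_same 0.2
```

Precision translates into design numbers:

```r
requiredN(annualChange = 3, perTimepointError = 2.5)   # AD-rate atrophy, ADNI-like error
#> [1] 9
requiredN(annualChange = 3, perTimepointError = 1.42)  # error after pooling 8 CS scans
#> [1] 3
precisionBudget(312, rho = 0.2, e1 = 3.0)  # best use of one ADNI scan's 312 s
#> $k 4   $expectedError 1.90   $durationUsed 288
```

(These `n` are measurement-error floors; add `sdBiological` for
between-subject heterogeneity in change rates.)

Real data enter through `readLongCsv()` (one row per subject × session ×
scan × measure) or the FreeSurfer readers `readAsegStats()` /
`readAparcStats()`; `runSimulate()` / `runAnalyze()` (and the thin CLI in
`inst/cli/morphopool.R`) drive the whole pipeline from a YAML config and
write a report bundle.

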