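---
title: "Measurement precision from pooled rapid scans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement precision from pooled rapid scans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphopool)
```

## The problem

MRI-derived brain morphometric estimates — regional subcortical volumes,
cortical thickness, and gray-to-white matter signal intensity ratio (GWR)
— carry test-retest measurement errors of roughly 2–5%. Because annual
hippocampal atrophy in Alzheimer's disease is about 3–6% (1–2% in
cognitively unimpaired older adults), a year of true change is about the
size of the measurement error of a single standard scan, which throttles
the statistical power of longitudinal and case-control studies.

Compressed-sensing (CS) acceleration makes a T1-weighted structural scan
about a minute long, so several can be acquired back to back ("cluster
scanning") and their morphometric estimates averaged ("pooling"). If the
per-scan errors were independent, the error of the mean of $k$ scans
would fall as $1/\sqrt{k}$; shared error components (head position,
shimming, session state) make errors correlated and dampen the benefit.
`morphopool` implements the full precision analysis around this idea:
the percent-error statistic, pooling schemes and their paired contrasts,
the $\sqrt{k}$ benchmark and equicorrelation closed forms, estimation of
the inter-scan error autocorrelation, and translation of precision into
longitudinal design quantities.

## The percent-error statistic

For a measure estimated in each of two sessions (test-retest), the
percent error is

$$ e = 100 \cdot \frac{|v_1 - v_2|}{(v_1 + v_2)/2}, $$

the absolute session difference divided by the mean of the two
estimates. It is symmetric, non-negative and scale-invariant, so it is
comparable across measures of very different magnitude (a 4000 mm$^3$
hippocampus and a 2.5 mm cortical ribbon). For a pooled estimate, each
session's selected scans are averaged first and the same statistic is
applied to the two pooled values; the denominator is the mean of the two
pooled session estimates, consistent with the single-scan definition.

Aggregation convention: a summary ("mean error 3.0%, SD 0.35%") averages
each measure across subjects first and then reports mean/SD/SEM across
the 152 measures. Whether a published overall SD is taken across
measures, across subjects, or across subject-by-measure records is
generally ambiguous; the two-stage choice is the package default and the
alternatives (`grouping = "records"`, `"measure"`, `"group"`) are
exposed in `summarizeErrors()`. Sample SDs use the $n-1$ denominator
everywhere; the SD of a singleton is defined as 0 with a warning.

## The generative error model

`simulateStudy()` draws, for subject $i$, measure $m$, session $s$,
block $b$ (before/after the mid-session repositioning break) and scan
$j$:

$$ y = T_{im}\,(1+\delta_{ism})\,(1+\beta_{isbm})\, b_{res}\,
      (1+\epsilon_{isjm}\, c_{res}), $$

where $T_{im}$ is the subject's true value (drawn once per measure
around a region mean with between-subject CV 0.1, times any group
shift), and $\delta$, $\beta$, $\epsilon$ are independent Normal
multiplicative errors at the session, block and scan level with SDs
$\sigma_{sess}$, $\sigma_{block}$, $\sigma_{scan}$ (a separate
$\sigma_{scan}$ for the ADNI protocol); $b_{res}$ and $c_{res}$ are a
per-resolution bias and noise scale (both default 1). All error
components are drawn **per measure**: measures are independent
replicates of the same error process, which is what makes per-measure
significance tests and Monte-Carlo averages across measures behave as
independent draws. Shared components induce equicorrelation among the
relative errors of scans in one session:

$$ \rho_{same} = \frac{\sigma_{sess}^2 + \sigma_{block}^2}
   {\sigma_{sess}^2 + \sigma_{block}^2 + \sigma_{scan}^2}, \qquad
   \rho_{cross} = \frac{\sigma_{sess}^2}
   {\sigma_{sess}^2 + \sigma_{block}^2 + \sigma_{scan}^2}. $$

Multiplicative (relative) errors keep the model scale-free across
measure classes, matching the percent-error statistic. Values that come
out non-positive are redrawn cell-wise, at most 100 passes, then the
simulation fails; at realistic SDs (~0.03) this never triggers.

### Calibration of the defaults

Write $\sigma_{tot}^2 = \sigma_{sess}^2+\sigma_{block}^2+
\sigma_{scan}^2$. The session difference of a single scan's relative
value is Normal with SD $\sqrt{2}\,\sigma_{tot}$, so the mean percent
error of a single scan is $100\sqrt{2}\,\sigma_{tot}\sqrt{2/\pi} =
100\,(2/\sqrt{\pi})\,\sigma_{tot}$ (the half-normal mean). The default
model solves this for a single-CS-scan mean error of 3.0%
($\sigma_{tot} \approx 0.0266$) and an ADNI error of 2.9%, with
$\rho_{same} = 0.2$ split equally between session and block
components ($\rho_{cross} = 0.1$). The 3.0%/2.9% anchors are tuning
targets in the neighbourhood of published single-scan errors; the true
within-session error correlation of real scanners is not publicly
reported, so $\rho_{same}=0.2$ is a package choice, selected because it
reproduces the qualitative pattern seen empirically — pooled errors
decline slightly more slowly than $1/\sqrt{k}$. Under these defaults
the closed-form pooled errors at $k=2,4,8$ are 2.32%, 1.90% and 1.50%.

Group shifts (MCI/AD: −15% hippocampal/amygdala volume, −8%
temporal-lobe thickness) only move true values between groups and are
invisible to the scale-invariant error statistics; they are placeholders
for realism, configurable in `defaultGroupShift()`. A per-group
multiplier on all error SDs (`groupNoiseScale`) models noisier patient
groups; scaling all components keeps the mean error proportional to the
multiplier at any $\rho$.

### What the generator does and does not emulate

Emulated: the two-session test-retest structure; one ADNI + eight CS
1.0 mm + eight multi-resolution CS scans per session with the pre/post
break blocks; hierarchical error with controllable autocorrelation;
group composition 12/18/10. Not emulated: image content and artifacts,
motion and its group dependence, FreeSurfer segmentation failures,
scan-order effects (the real protocol counterbalanced order; the
simulator fixes one order and assumes order effects are nil), spatial
correlation between neighbouring measures, and heavy-tailed error
distributions. Passing tests therefore demonstrate the statistical
machinery under the stated error model, not properties of any real
scanner or processing pipeline.

### Seeding

One master seed; each subject's draws come from a substream seeded by a
fixed linear mix of the master seed and the subject index, so enlarging
the cohort never reshuffles existing subjects, and identical
(model, design, seed) give bit-identical tables.

## Pooling schemes and contrasts

A `PoolingScheme` selects scans by type, resolution, block and type
index; first-$k$ selection uses the protocol's scan labels (type
indices), not acquisition order. Subjects missing any selected scan in
either session are dropped with a warning, never imputed. Standard
schemes: `adniScheme()` (the 5'12" reference), `csPoolingScheme(k)`
(first $k$ CS 1.0 mm scans, 1'12" each), `serialPairScheme()` /
`breakPairScheme()` (scans {1,2} vs {1,5}), and `multiresScheme()`
(one scan each at 0.8/0.9/1.1/1.2 mm, 5'05" total).

`compareSchemes()` performs, per measure, a two-sided paired test across
subjects on the per-subject percent errors. The default is the Wilcoxon
signed-rank test (exact for $n \le 25$, normal approximation with
continuity correction beyond), chosen for robustness to the skewed,
non-negative error distribution; a paired $t$-test is available.
P-values are reported uncorrected — the "fraction significant at
$\alpha$" summary is a descriptive screen, not a corrected inference —
with an optional, clearly labelled Benjamini–Hochberg column. In the
"fraction improved" summary, exact ties count as half improved, which
keeps `compareSchemes(A, A)` at 50% and makes the statistic symmetric.

## Autocorrelation estimation

Under equicorrelation, the mean squared session difference of the
$k$-scan pooled relative value is $E[\Delta_k^2] = a + b/k$ with
$a = 2\rho\sigma^2$, $b = 2(1-\rho)\sigma^2$. `estimateRho()` pools
$\Delta_k^2$ over subjects and measures, fits the line in $1/k$ by least
squares over $k = 1..k_{max}$ and reports $\hat\rho = a/(a+b)$, clipped
to $[0,1]$ with the unclipped value kept in the diagnostics and a
subject-level bootstrap CI. When pooling crosses the break and a block
component exists, the shared variance is itself a mixture, so $\hat\rho$
lands between $\rho_{cross}$ and $\rho_{same}$ (the default-protocol
simulation gives $\hat\rho \approx 0.16$ against
$\rho_{cross}=0.1$, $\rho_{same}=0.2$); with the correlation carried by
the session component alone the model is exact and recovery is unbiased.

## Precision to power

`errorToSD()` inverts the half-normal link: a mean percent error $e$
corresponds to a session-difference SD of $e\sqrt{\pi/2}$, hence a
per-timepoint SD of $e\sqrt{\pi/2}/\sqrt{2} = e\sqrt{\pi}/2$.
`requiredN()` uses the standard normal-approximation sample size for a
two-timepoint change (one-group, or per-group for a two-group difference
in change):

$$ n = \left\lceil \frac{(z_{1-\alpha/2}+z_{power})^2\, m\,
   \sigma_\Delta^2}{(\text{rate}\times\text{years})^2} \right\rceil,
   \qquad \sigma_\Delta^2 = 2\sigma_{tp}^2 + \sigma_{bio}^2. $$

z-formulas (not $t$) are used for transparency; they understate $n$
slightly for $n < 10$. The default $\sigma_{bio} = 0$ quantifies the
measurement-error floor only — real sample sizes also depend on
biological heterogeneity in change rates, which is exposed as
`sdBiological` but deliberately not defaulted. `precisionBudget()`
converts a per-session scan-time budget into the largest feasible $k$
and the equicorrelation-predicted pooled error.

## Numerical and design choices

* GWR input: FreeSurfer emits a white-minus-gray percent contrast
  (`w-g.pct.stats`), not a ratio; the reader converts
  $gwr = 1/(1 - pct/100)$ by default, toggleable, because extraction
  conventions differ between pipelines.
* Long CSV values are written with 17 significant digits so
  write-then-read is bit-exact; duplicate keys and non-finite values are
  integrity errors, not warnings.
* The FreeSurfer label table ("Left-Thalamus-Proper" → Thalamus/left) is
  shipped as data (`inst/extdata/aseg_structure_map.tsv`), not code.
* Degenerate inputs: all-zero SDs make `impliedRho()` error (undefined
  correlation); an all-equal error vector gives a Wilcoxon p of 1 by
  convention; `estimateRho()` errors on a degenerate fit ($a+b \le 0$).

## Problem sizes used in the test suite

Simulation-based checks use cohorts chosen to keep Monte-Carlo error
well inside the asserted tolerances while remaining quick on one CPU:
200 subjects × 152 measures for the $\sqrt{k}$ law (±3% relative),
1000 subjects × 16 measures for the equicorrelation SDs (±3%),
200 subjects × 16 volume measures for $\hat\rho$ recovery (±0.05),
500 replicate 40-subject studies × 20 measures for the null calibration
of the paired test (significant fraction within [3.5%, 6.5%]), and
200 subjects × 16 measures for the null moderator contrasts. All checks
use fixed seeds and are deterministic.

## Known limitations

The equicorrelation closed forms are first-order in the error SDs (the
percent-error denominator is itself noisy; at 3% error the bias is
negligible). The simulator's Gaussian multiplicative errors cannot
produce the heavy-tailed outliers real segmentation failures cause, so
robustness claims about the Wilcoxon default rest on the skewness of
|Normal| differences only. No reliability coefficients (ICC) are
computed — the percent-error statistic is the package's precision
currency. Vertex-wise surface analyses are out of scope; the generic
long-format operations will accept vertex tables if supplied, but no
surface resampling or smoothing is implemented.
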