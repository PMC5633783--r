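---
title: "Methods: region-wise atrophy statistics for TBI cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-wise atrophy statistics for TBI cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortatrophy)
```

## The model

The pipeline analyses cohorts in which cortical thickness (mm) has been
measured over a Destrieux-style parcellation — 74 gyri and sulci per
hemisphere, 148 regions in total — at two timepoints: an acute baseline a
few days after a traumatic brain injury, and a chronic follow-up about six
months later. The response of interest is relative regional atrophy

$$a_{ij} = \frac{\text{acute}_{ij} - \text{chronic}_{ij}}{\text{acute}_{ij}},$$

a dimensionless fraction in which positive values mean thinning. This
orientation is chosen so that the atrophy–outcome correlations of step 2
come out negative for the clinically expected direction (more thinning,
poorer outcome).

**Step 1.** For each region $j$, the model is a linear regression of
$a_{\cdot j}$ on two acute severity indicators: the Glasgow Coma
Score-Extended (GCS-E, an ordinal consciousness score, lower = worse) and
a binary indicator of acute epileptic seizures, giving $q = 2$ predictor
columns beside the intercept. Both predictors are observational ("random
effects" in the multiple-correlation sense: their values are not set by
the experimenter). Age at injury and sex are treated as nuisance
variables and are regressed out of the response beforehand (see *Design
choices*). With $B = (X^\top X)^{-1} X^\top Y$, the residual and
regression sums-of-squares-and-cross-products matrices are

$$E = Y^\top Y - B^\top X^\top Y, \qquad
  H = B^\top X^\top Y - N \bar{Y}^\top \bar{Y},$$

and the omnibus statistic is Wilks' $\Lambda = \det(E)/\det(E + H)$ with
hypothesis d.f. $\nu_H = q$ and error d.f. $\nu_E = N - q - 1$. Rao's
transformation converts $\Lambda$ to an F statistic with
$d_1 = p\,\nu_H$ and $d_2 = w t - (p\,\nu_H - 2)/2$ degrees of freedom,
where $w = \nu_E + \nu_H - (p + \nu_H + 1)/2$ and
$t = \sqrt{(p^2\nu_H^2 - 4)/(p^2 + \nu_H^2 - 5)}$. The shipped analyses
use a single response ($p = 1$), for which the transformation is exact:
$t$ degenerates (see *Numerical choices*), $d_1 = 2$, $d_2 = N - 3$, and
the statistic coincides with the classical overall regression F — at
$N = 33$, an $F_{2,30}$. The test suite verifies this equivalence against
an independent least-squares oracle on a thousand random instances, and
checks the $p > 1$ machinery against the multivariate-anova route in
base R.

Each region receives a parametric p-value from the central F tail and an
empirical p-value from a permutation scheme that randomly permutes the
predictor rows of the design matrix jointly — keeping each subject's
GCS–seizure pairing intact and the intercept untouched — and recomputes F
(10,000 permutations by default). Multiplicity across parcels is handled
by Benjamini–Hochberg FDR at $\alpha = 0.05$.

**Step 2.** Per region, the Pearson correlation $r$ between relative
atrophy and the 6-month Glasgow Outcome Score-Extended (GOS-E), tested
with

$$t = \frac{r}{\sqrt{(1 - r^2)/(N - 2)}}$$

on $N - 2$ d.f., one-sided by default for the directional hypothesis
$r < 0$, with its own FDR correction across parcels (the two steps'
p-value families are corrected separately; they are distinct analyses
over the same cortex).

**Effect size and power.** Effects are quantified as Cohen's
$f^2 = R^2/(1 - R^2)$; for $p = 1$, $R^2 = 1 - \Lambda$. The power of a
level-$\alpha$ F test is the noncentral-F mass beyond the central
critical value, with noncentrality $\lambda = n f^2$ — the sample size
$n$ itself, not the $(u + v + 1)$ textbook variant, which is numerically
identical here since $n = \nu_H + \nu_E + 1$. Solvers invert this map:
`min_effect_size()` bisects on $f^2$, `min_sample_size()` searches the
integer $n$ with $d_2 = n - q - 1$ tracking $n$; both are post-verified
and cross-checked in the tests against a Monte-Carlo noncentral-F oracle
built from the defining ratio of chi-squares.

## Missing data

Regions containing lesions lose gray/white contrast and yield no usable
thickness measurement; such cells are missing at both timepoints. Two
rules govern their treatment:

- **Availability gate.** A region's null hypothesis is tested only when
  atrophy values exist for at least 90% of subjects (boundary inclusive:
  30/33 passes, 29/33 does not). Untested regions are carried through all
  result tables with status `untested` and empty statistics.
- **Mean substitution.** Within tested regions, missing atrophy values
  are replaced by the region's observed mean. The imputation acts on the
  atrophy value, not on each timepoint's thickness separately: the
  regression consumes atrophy, and imputing the response directly is the
  minimal reading of mean substitution. It preserves the region mean,
  never inflates variance (both property-tested), and mildly
  *understates* residual variance — a known, accepted bias of mean
  substitution at the ≤10% missingness the gate allows.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_fraction` | 0.9 | availability gate (fraction of subjects) |
| `n_perm` | 10,000 (pipeline) | permutations per region |
| `alpha` | 0.05 | FDR rejection level |
| `fdr_on` | `"param"` | p-value family entering the FDR |
| `two_sided` | `FALSE` | step-2 tail convention |
| `target_power` | 0.8 | power solvers |

The permutation comparison serves as a validity check on the parametric
tail; by default the FDR acts on parametric p-values (they are continuous
rather than granular at $1/(n_\text{perm}+1)$), with `fdr_on = "perm"`
available when the empirical family is preferred.

## The synthetic cohort generator

`default_config()` encodes the reference study design: $N = 33$ subjects
(23 male), ages with mean 33.6 and SD 16.5 years on 18–62, GCS-E with
mean 6.15 and SD 3.36 on 3–15, an acute-seizure probability of 15/33,
and a GOS-E targeting mean 5.43 and SD 2.51 on 1–8. Bounded quantities
are drawn from scaled beta distributions moment-matched to the stated
mean and SD: a normal truncated to the stated range cannot attain these
SDs (on [18, 62] the truncated-normal family tops out near the uniform's
12.7, well short of 16.5), and the beta shapes this forces —
young-adult-heavy ages with a secondary mass near the elderly boundary,
GCS clustered at the severe end — are clinically plausible for TBI
cohorts. The GCS continuous draw targets a variance reduced by 1/12 so
the integer-rounded score hits the configured SD.

True relative atrophy in an *affected* region (a configurable fraction of
the registry, default 25%) is

$$a = a_0 + \beta_g\,(g_{\max} - \text{GCS-E}) + \beta_s\,\text{seizure}
      + \beta_a\,\text{age}_c + \beta_x\,\text{sex} + \varepsilon,$$

so that deeper coma and seizures both drive thinning; unaffected regions
carry zero severity betas (the nuisance age/sex terms and noise apply
everywhere, so nuisance residualization is exercised on null regions
too). Defaults $\beta_g = 0.005$, $\beta_s = 0.025$,
$\sigma_\varepsilon = 0.03$ put region-level $f^2$ near 0.4, the middle
of the 0.35–0.83 band the analysis is meant to resolve; no published
region-level ground truth exists, so these magnitudes are the package's
own choice, made once. Chronic thickness is acute × (1 − atrophy). GOS-E
is an affine-*decreasing* function of each subject's mean true
(noise-free) atrophy plus latent noise, rounded and clipped to 1–8: any
GCS→GOS association in generated data arises through atrophy, mirroring
the two-step structure under test. Rounding and clipping shrink the
realized GOS-E SD somewhat below its 2.51 target; the generator's moment
guarantees (property-tested at $n = 10{,}000$) cover age, GCS-E and the
seizure rate.

Missingness emulates focal lesions: with probability 0.3 a subject
receives one contiguous block of 25 registry-adjacent regions missing at
both timepoints. These defaults were sized analytically (binomial
coverage model) so that about 10% of regions fail the availability gate
at $N = 33$; the realized fraction varies substantially across seeds
because lesion blocks are spatially shared across regions, and the test
suite checks the replicate *mean* against the analytic expectation.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: spatial autocorrelation of thickness and
of atrophy beyond lesion blocks, non-linear severity–atrophy dose
response, measurement error correlated between timepoints, informative
missingness (lesions co-located with the largest true effects), secular
scanner drift, and any departure of real GOS-E from an
atrophy-plus-noise ordinal readout.

## Numerical choices

- **H/E assignment.** E is the residual SSCP and H the regression SSCP,
  the standard multivariate-regression forms; only this assignment makes
  $\Lambda$ fall (and F grow) with effect size and yields the
  $F_{2,30}$ semantics at $N = 33$.
- **Degenerate $t$.** For $p = 1,\ \nu_H = 2$ the exponent
  $t = \sqrt{0/0}$ is indeterminate; the standard convention $t = 1$ is
  used, under which the transformation is exact.
- **Solvers, not inverses.** Coefficients come from QR decompositions
  (`qr.coef`, `qr.resid`); no explicit $(X^\top X)^{-1}$ is formed. Rank
  deficiency in the model design is an error naming the collinear
  columns; in the *nuisance* design (e.g. a single-sex cohort) the
  collinear column is dropped with a warning instead, since failing
  there would veto the primary analysis for a data quirk.
- **Permutation estimator.** Random permutations use the add-one
  estimator $(1 + \#\{F_\pi \ge F_\text{obs}\})/(1 + n_\text{perm})$,
  which cannot return 0; exhaustive enumeration (small N, testing) uses
  the exact proportion. Comparisons use a $10^{-9}$ relative tolerance so
  the identity permutation's tie with $F_\text{obs}$ is counted
  consistently in floating point. For $p = 1$ the permuted statistics
  are computed in closed form from permuted cross-products — the
  predictor Gram matrix is permutation invariant — which is why a
  148-region × 10,000-permutation scan takes seconds.
- **Per-region seeds.** Region $i$ permutes under `seed + i`, so any
  region's empirical p-value is reproducible in isolation.
- **Degenerate inputs.** A constant response (zero total variation) makes
  $\Lambda$ undefined and is an error at the operation level; scans
  catch it and mark the region `untested` rather than aborting 147
  healthy regions. Zero-variance vectors in step 2 behave the same way.
  $|r| = 1$ yields an overflow-flagged record with $p = 0$.
- **Bisection/search tolerances.** $10^{-6}$ on $f^2$, exact integer
  search on $n$ — far below the 4-decimal reporting precision of the
  power tables.

## Design choices

Several points were genuinely open and were settled as follows:

- **Nuisance handling.** Age and sex are residualized from the response
  only, and downstream d.f. remain $\nu_E = N - q - 1 = 30$ uncorrected —
  the only convention consistent with $F_{2,30}$ reporting at $N = 33$.
  The predictors are left untouched.
- **Sex coding.** Files use `"M"`/`"F"`; internally male = 1, female = 0.
  Any full-rank coding yields identical residuals, so the choice is
  cosmetic.
- **GOS-E as numeric.** The outcome is an ordinal score treated
  numerically: step 2 is a Pearson correlation, which requires numeric
  treatment, and the step-1 functional-outcome variant inherits it for
  consistency. No categorical encoding is attempted.
- **One-sided step 2.** The directional hypothesis (atrophy ↔ worse
  outcome) uses the lower t tail; a `two_sided` flag overrides.
- **Separate FDR families.** Step-1 and step-2 p-values are corrected
  within their own step, each over its tested regions; the families are
  never pooled.
- **Hemispheres.** The registry keeps left and right structures distinct
  (148 rows); any bilateral pooling is left to the caller.
- **Atrophy sign.** $(acute - chronic)/acute$, so `relative_atrophy`
  equals $1 - \text{chronic}/\text{acute}$ (property-tested identity).

## Problem sizes in the test suite

The shipped tests run the oracle-equivalence sweep at 1,000 random
instances, permutation calibration on 200 Gaussian null datasets at 2,000
permutations each, FDR-control simulation at 1,000 global-null replicates
of 148 regions, parameter recovery at $N = 200$ with 20 affected regions,
and the end-to-end determinism check at the pipeline's full 10,000
permutations per region. These sizes keep the whole suite under a minute
on one core while leaving Monte-Carlo error well inside the asserted
margins; all are the package's own choices and are trivially enlarged.

## Known limitations

- Mean substitution understates residual variance; with the 90% gate the
  effect is ≤10% of cells per region, but p-values in imputed regions are
  mildly anti-conservative. No regression or multiple imputation is
  offered by design.
- The multivariate machinery supports $p > 1$ responses, but the shipped
  scans use $p = 1$; the $p > 1$ path is tested yet not exposed in the
  pipeline.
- The pipeline is single-process; at this scale (148 regions × 10⁴
  permutations of a 33 × 3 solve) parallelism would cost more in
  reproducibility than it buys in time.
- Power solvers assume the F framings used here (regression F; the
  correlation t as $F_{1, N-2}$); no other test families are covered.
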