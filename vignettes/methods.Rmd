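---
title: "Methods: diagnostic test evaluation in dxeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnostic test evaluation in dxeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxeval)
```

## The estimation problem

A diagnostic test is judged by comparing its result with a binary
reference standard: the best available determination of true disease
status. Cross-tabulating dichotomous test results against the reference
gives the four counts TP, FP, FN, TN, from which every indicator in this
package derives. The statistical model is deliberately simple: the TP
count is binomial given the number of diseased subjects
(TP ~ Bin(n~d~, Se)) and TN is binomial given the non-diseased count
(TN ~ Bin(n~nd~, Sp)), with the two margins treated as independent. No
covariates, clustering or verification bias are modelled; the package
evaluates one test at a time against one reference.

## Indicators and their intervals

**Proportions.** Sensitivity, specificity and accuracy are binomial
proportions and carry 95% Wilson score intervals,

$$\mathrm{CI} = \frac{p + z^2/2n \pm z\sqrt{p(1-p)/n + z^2/4n^2}}{1 + z^2/n},$$

chosen over the Wald interval for its small-sample and boundary
behaviour: it stays inside [0, 1] and has positive width at p = 0 or 1.
Its true coverage is close to, but oscillates around, the nominal 95%
because the binomial is discrete; by exact enumeration the coverage at
p = 0.8, n = 40 is 92.8%, which is what the test suite asserts the
simulation must reproduce.

**Predictive values.** PPV and NPV are post-test probabilities and
depend on the pre-test probability of disease. The package computes them
from Bayes' theorem at a *user-supplied population prevalence*, never
the sample prevalence: diagnostic study samples are usually enriched for
disease, so column proportions of the 2×2 table would answer the wrong
question. (When the supplied prevalence happens to equal the sample
prevalence the Bayes formulas reduce algebraically to TP/(TP+FP) and
TN/(TN+FN); this identity is property-tested.) Their bounds are
propagated by evaluating the Bayes expression at all four combinations
of the Se and Sp interval limits and taking the extremes. Both
expressions are monotone non-decreasing in Se and Sp, so the extremes
sit at the (lower, lower) and (upper, upper) corners; the four-way
evaluation is kept because it states the intent. This propagation is
conservative and distribution-free — appropriate at the small sample
sizes where an asymptotic (delta-method) variance would be least
trustworthy, and cheaper and more stable than bootstrapping the whole
pipeline.

**Likelihood ratios.** LR+ = Se/(1−Sp) and LR− = (1−Se)/Sp get intervals
on the log scale: log LR is approximately normal with standard error
√(1/TP − 1/(TP+FN) + 1/FP − 1/(FP+TN)) for LR+ and the FN/TN analogue
for LR−. A zero cell in any reciprocal makes the interval undefined; no
continuity correction is applied, the interval is simply reported
missing while a defined point estimate (e.g. LR− = 0 for a test with
perfect sensitivity) is kept.

**Youden index.** J = Se + Sp − 1 with variance approximated by the sum
of the two binomial variances, assuming independence of the margins. The
bounds are reported *unclipped*: a bound slightly outside [0, 1] is a
faithful consequence of the normal approximation, and clipping would be
a presentation choice that hides it.

**AUC.** The ROC curve is traversed at every candidate threshold; the
trapezoidal area equals the Mann–Whitney probability that a random
diseased score exceeds a random non-diseased score, ties counted one
half (asserted to 1e−12 against a pair-counting oracle). The variance
uses DeLong's placement values — for each case, the fraction of controls
it beats, and symmetrically — computed via midranks in O(N log N);
the interval is AUC ± 1.96·√(S₁₀/m + S₀₁/n), clipped to [0, 1]. With
fewer than two cases or two controls the placement variances are
undefined and the bounds are missing while the AUC is still reported.
For a qualitative (0/1) test the same machinery yields the degenerate
AUC = (Se+Sp)/2, reported for completeness.

## ROC construction and the optimal cutoff

*Candidate thresholds* are the midpoints between consecutive distinct
sorted score values, flanked by ∓∞ sentinels, so the curve always
contains (Se = 1, Sp = 0) and (Se = 0, Sp = 1). *Positivity* is "score
strictly greater than the cutoff" (mirrored when lower scores indicate
disease); with midpoint cutoffs a ≥ rule would classify the observed
data identically, which is why midpoints were chosen — they make the
strictness question moot.

The *direction* (whether high or low scores indicate disease) is
auto-detected by comparing group medians, with ties going to
higher-is-positive; a CLI/function argument can override it.

The *optimal cutoff* minimizes the Euclidean distance
d(t) = √((1−Se(t))² + (1−Sp(t))²) to the top-left corner over the finite
candidates. Exact ties on d are broken by higher sensitivity (favouring
case detection, the usual clinical preference), then by smaller
threshold, making selection deterministic. Constant scores admit no
finite threshold and are reported as an explicit failure rather than an
arbitrary cutoff. Dichotomizing at the selected cutoff and recomputing
Se/Sp from the resulting confusion matrix reproduces the cutoff's
operating point exactly; this cross-stage consistency is tested.

## Bootstrap sensitivity band

The band around the ROC curve is pointwise: cases and controls are
resampled separately with replacement (stratification guarantees no
replicate loses a class), the empirical curve is rebuilt, sensitivity is
read off by linear interpolation of the curve's upper envelope at each
specificity on a 0.01-step grid, and the 2.5th/97.5th percentiles across
iterations form the band. Defaults: 5000 iterations, grid 0 to 1. The
band is a graphical uncertainty display, not a simultaneous confidence
region; with a seed it is bit-reproducible, without one it varies
slightly across runs, which is expected behaviour. A replicate with
constant scores degenerates to the diagonal ROC and simply contributes
its values.

## Fixed constants and numerical choices

- z is the literal constant 1.96 and the confidence level is fixed at
  95%; this is part of the method's definition, not a tunable. (The
  test suite compares DeLong variances, not intervals, against pROC,
  whose z is qnorm(0.975) = 1.959964.)
- Display rounding is **half-up to three decimals** at the reporting
  boundary only (`dx_round`); all internal computation is full
  precision. Half-up is chosen over R's banker's rounding so 0.8055
  displays as 0.806.
- **Missing-value rule:** any zero denominator produces `NA`, never an
  exception or ±Inf; an estimate whose point value is missing has
  missing bounds, and a metric depending on a missing input is fully
  missing. (Exception by design: a defined LR point estimate with an
  undefined interval keeps its value.)
- Wilson bounds are clamped by at most one ulp so the interval always
  contains the raw proportion and p = 0 gives a lower bound of exactly
  0.
- Prevalence must lie strictly inside (0, 1): the Bayes formulas
  degenerate at the endpoints.

## Input validation

Input is a `.xlsx` workbook; the first row is the header, columns are
addressed by name, and the first sheet is read unless another is
requested. Rows with a missing value in either *selected* column are
dropped first (missingness elsewhere is irrelevant) and the dropped
count is logged; the remaining values are then checked, yielding one of
four exact error messages (qualitative test not 0/1, reference not 0/1,
quantitative test not numeric, reference missing a level after
cleaning). Numbers stored as text are accepted wherever they parse; 0/1
columns require the parsed value to equal 0 or 1 exactly, so "1.0"
passes and "0.5" fails. Duplicate header names are rejected outright —
silently renaming them risks analysing the wrong column. Because no
installed package writes `.xlsx`, the exporters sit on a minimal
single-sheet Office Open XML writer (inline strings and number cells,
deterministic timestamps so equal content gives equal bytes), verified
by round-tripping through the reader.

## The synthetic-data generator

`dx_simulate()` emulates the structure of a typical single-test
evaluation dataset: `Disease ~ Bernoulli(p_disease)` with
p_disease = 0.64 by default (diagnostic study samples are commonly
case-enriched; the default sampling fraction is intentionally far above
the default analysis prevalence of 0.1 to keep the two notions
distinct); `Test1 | Disease ~ χ²(3)` versus `χ²(1.5)` — strictly
positive, right-skewed scores, as biomarker concentrations usually are —
whose population AUC, P(χ²₃ > χ²₁.₅), is 0.730 by numerical integration,
a moderately discriminative marker; and `Test2` drawn conditionally on
disease with true Se 0.9 and Sp 0.7, so parameter-recovery tests have a
known truth. Generation is bit-reproducible under a seed and leaves the
caller's RNG stream untouched.

What it does **not** emulate: measurement error in the reference
(imperfect gold standard), correlated or clustered observations,
covariate-dependent accuracy, missing-not-at-random patterns, or
spectrum effects. Passing tests on generated data therefore demonstrate
the *correctness of the computations*, not the robustness of the
indicators to those real-data complications.

## Problem sizes in the test suite

The suite checks oracle equivalence (pair-counting AUC, enumerated
DeLong placements, exhaustive cutoff search) on 500+ random instances
with up to 20 cases and 20 controls each; Wilson coverage with 2000
binomial draws against the exactly enumerated coverage; predictive-value
propagation on hundreds of random tables; and end-to-end Wilson coverage
over 500 seeded replicates of n = 200. Bootstrap bands in tests use
30–200 iterations — the band's computation is iteration-count-agnostic,
and the 5000-iteration default remains for analyses.

## Known limitations

Single-test analyses only: no comparative ROC test between two markers,
no partial or smoothed AUC, no time-dependent ROC, no multivariable
adjustment. Likelihood-ratio and predictive-value intervals grow
unstable with extreme or zero cells (reported as `NA` rather than
patched with continuity corrections). Predictive values inherit whatever
error is in the user's prevalence assumption. The bootstrap band is
pointwise and its exact shape depends on the stated grid/stratification
choices; other implementations' bands will differ in detail.
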