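---
title: "Evaluating small-panel epigenetic clocks with pyroclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating small-panel epigenetic clocks with pyroclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyroclock)
```

## The problem

DNA methylation at a small number of CpG sites drifts with age strongly
enough that an affine combination of two to four percent-methylation values
— an "epigenetic clock" — predicts chronological age with errors of a few
years in adults. Pyrosequencing makes those few sites cheap to assay, so
such clocks are attractive for routine use; but their published accuracy
depends heavily on the age range and cohort in which they were validated.
`pyroclock` implements the validation side: it applies a clock with *given*
coefficients to a cohort and quantifies its accuracy overall, per age group
and per sex. It never fits clock coefficients (that is a training problem,
out of scope by design).

## The model and its statistics

A clock maps a sample's methylation profile to
$X' = \beta_0 + \sum_j c_j\, m_j^{p_j}$, with powers $p_j \ge 1$ to
accommodate published models with polynomial terms. Accuracy over $n$
paired ages is summarized by:

* MAD $= \frac{1}{n}\sum_i |X_i - X'_i|$ — the mean absolute deviation.
  The clock literature sometimes labels this quantity "median absolute
  deviation"; the quantity actually computed (here and in the studies this
  package mirrors) is the *mean*, and `median_abs_error()` is provided
  separately under an unambiguous name.
* SEE $= \sqrt{\sum_i (X_i - X'_i)^2/(n-2)}$ — the standard error of the
  estimate, with the regression-flavored $n-2$ denominator; it therefore
  needs $n \ge 3$ and always satisfies SEE $\ge$ RMSE $\ge$ MAD.
* PCP($\tau$) $= 100\,k/n$, where $k$ counts samples with
  $|X_i - X'_i| \le \tau$. The boundary is *included*: an error of exactly
  $\tau$ years is a correct prediction. Conventional thresholds are 5, 7.5
  and 10 years.
* $R^2$: the squared Pearson correlation between $X'$ and $X$. We
  deliberately do not use the identity-line residual definition
  $1 - SS_{res}/SS_{tot}$, which goes negative for a biased clock; the
  correlation-based definition is bounded in $[0,1]$ and matches how
  validation studies report near-zero values in old-age strata. The choice
  matters: a stratum can have small MAD and still near-zero $R^2$ when the
  stratum's age range is narrow, because $R^2$ measures discrimination
  *within* the stratum, not calibration.
* delta age $= X' - X$, the per-person signed error; group differences in
  delta age are what "epigenetic age acceleration" analyses test.

Group differences in delta age are tested with the two-sample Wilcoxon
rank-sum (Mann–Whitney) test: the strata being compared (age groups, sexes)
are disjoint sets of individuals, so the paired signed-rank variant would
be wrong as a default (it remains available via `paired = TRUE`). The exact
null distribution is used when the pooled sample is small ($n_a + n_b \le
20$) and tie-free; otherwise the normal approximation with midranks,
tie-corrected variance and continuity correction. p-values are reported
raw, as validation studies tabulate them; `p.adjust()` can be applied
downstream when many strata are compared.

## Age groups and error dynamics

The default scheme is young 0–17, adult 18–80, old 81+ (nominally 81–101),
with membership by completed years (`floor(age)`), so age 17.9 is "young"
and 80.99 is "adult"; ages beyond the last bound fall into the last group.
Any contiguous zero-based scheme can be supplied instead.

`metric_dynamics()` recomputes MAD or SEE over cumulative ranges
$[\min, t]$ as $t$ sweeps a grid (1-year steps by default; the final point
is pinned to the cohort maximum so it equals the global metric exactly).
The lower bound stays fixed: the curve answers "how would my headline error
change had I stopped recruiting at age $t$", which is how validation
studies display the strong age-range dependence of MAD/SEE. Early grid
points cover few samples; points below a metric's minimum n (1 for MAD, 3
for SEE) are reported as `NA` rather than silently skipped.

## The synthetic cohort generator

Because real cohort tables and published coefficients are external inputs,
the package carries a generator that reproduces the *statistical structure*
the analysis assumes, so every pipeline stage is testable offline.

Ages and sexes are drawn from a five-band table sampler mirroring a
153-person reference cohort spanning ages 0–101: band weights 24, 24, 25,
25, 55 out of 153 for bands 0–20, 21–40, 41–60, 61–80 and 81+, each band
split by sex (96 women, 57 men overall, with women dominating the 81+ band
as in real elderly cohorts). Ages are continuous-uniform within a band,
parameterized so completed years land inside the band's inclusive bounds.
A uniform sampler is available for designed experiments.

Per-site methylation follows
$$m = b_0 + b\,\min(a, k) + \lambda b \max(0, a - k) + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma),$$
clipped to $[0, 100]$ with clip counts reported. The knot $k$ (default:
none) and factor $\lambda \in [0,1]$ implement *attenuation*: methylation
drift slows beyond $k$, which makes any clock calibrated below the knot
under-predict above it — the mechanism behind the reproducible observation
that people over 80 read epigenetically younger than their chronological
age, whether through selective mortality, training-set age skew, or
genuinely decelerated aging.

**Calibration.** Defaults are derived analytically in code, not tabulated.
For a site with slope $b$ and noise $\sigma$ evaluated over an age
distribution with standard deviation $\sigma_a$, the age–methylation
correlation is $r = b\sigma_a / \sqrt{b^2\sigma_a^2 + \sigma^2}$, so a
target $r$ fixes $\sigma = |b|\,\sigma_a\sqrt{1/r^2 - 1}$. With
$\sigma_a \approx 30.7$ y (closed form for the band-weighted uniform
mixture of the table sampler), the default panel targets r = 0.94
(ELOVL2_6), −0.79 (ASPA_1), 0.92 (PDE4C_1) and −0.90 (EDARADD_1) — the
first two being the canonical strong/weak extremes reported for these
markers, the latter two chosen once from the literature range for those
assays. Slopes (0.50, −0.25, 0.35, −0.30 %/y) and baselines (20, 50, 20,
60%) are typical pyrosequencing values and keep every mean trajectory more
than four noise SDs inside $[0, 100]$ across ages 0–101, so boundary
clipping affects well under 0.1% of draws.

`matched_clock()` returns the exact algebraic inverse of the noiseless
generator below the knot — per site $(m - b_0)/b$, averaged with equal
weights across sites. Equal weights keep the inverse interpretable and
exactly analyzable (with noise, its prediction error is Gaussian with
variance $\frac{1}{K^2}\sum_j \sigma_j^2/b_j^2$, giving closed-form
expected MAD $\sigma_{\mathrm{eff}}\sqrt{2/\pi}$ via the folded normal);
it is a reference instrument for self-tests, not an optimal estimator —
a precision-weighted inverse would be more accurate but would break the
closed forms the tests rely on.

**What the generator does not emulate:** assay chemistry (bisulfite
conversion efficiency, pyrosequencing dispensation noise), heteroscedastic
or age-dependent noise, between-site correlation beyond the shared age
signal, batch effects, and cohort selection effects. Tests passing on
synthetic cohorts therefore demonstrate the *pipeline's* correctness and
statistical calibration, not any claim about a particular real cohort.

## Numerical and design choices

* Equal-weight matched inversion and analytic noise calibration, as above.
* Validation of input tables is total: every malformed cell is reported
  with row, sample and site; nothing is silently dropped or imputed. A
  sample missing a site required by a clock is excluded from that clock's
  predictions with a logged count — imputation would bias MAD downward.
* Predictions outside a clock's declared valid age range are flagged,
  never clipped; systematic out-of-range drift is a finding.
* Per-site regressions run methylation-on-age (slopes in %/year); r and
  R² are direction-invariant, the slope convention is stated.
* Reproducibility: one integer seed per simulated cohort; per-site noise
  streams are derived deterministically from it, so adding a site leaves
  the other sites' draws unchanged. CSV writers emit full double precision
  (`%.17g`), making write/read round trips bit-identical.
* Problem sizes used by the test suite were chosen for statistical power
  at desk scale: 1000 random instances for metric-oracle equivalence,
  n = 20,000 for the folded-normal noise law (3–5% tolerance), 200
  seeded replicates for type-I calibration and for the attenuation
  scenario, 500 replicates for the age-band sampler's multinomial check.
* The type-I property (adult-vs-old rejection rate within [1%, 10%] at
  α = 0.05 under the null) and the attenuation property (old group
  epigenetically younger in ≥ 99% of replicates; MAD over the full range
  exceeding MAD up to age 80) are asserted over fixed-seed replicate
  families; the strict "every replicate" form of the dynamics clause has
  a small but nonzero per-replicate failure probability (~0.1% under the
  calibrated defaults), which is the sharpest contract the generator's
  noise level supports.

## Limitations

Stratum R² is undefined (reported `NA`) for degenerate strata — fewer than
two samples or constant ages/predictions — and SEE for strata with n < 3.
The rank-sum test's exact branch is skipped in the presence of ties even
at small n. The generator's linear-drift-plus-knot model is a deliberately
minimal mechanism for old-age under-prediction; real cohorts likely mix
several of the candidate explanations and show heteroscedastic errors that
this package evaluates but does not simulate by default.
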