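---
title: "Validating leftover-based intake estimation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating leftover-based intake estimation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intakeval)
```

## The measurement problem

Hospitals track how much of each served dish a patient actually eats.
The clinical reference method is weighing: intake is the pre-meal weight
minus the post-meal weight of each dish. Because ward staff cannot weigh
every tray, practice relies on *leftover estimation* — a nurse looking at
the tray (direct visual), a dietitian looking at a photograph (image
visual), or an image-analysis model (AI) — all reporting on the same
11-point scale, where a converted value $v \in \{0, \dots, 10\}$ encodes
intake in tenths of the served portion.

`intakeval` implements the complete validation analysis for such a study:
the scale conversions, nutrient-intake computation from menu composition,
every agreement statistic comparing an estimation channel against
weighing, and a seeded synthetic-cohort generator so the whole pipeline is
testable without patient data.

## The 11-point converted scale

Weighed intake is first expressed as a fraction
$f = (w_{\text{pre}} - w_{\text{post}}) / w_{\text{pre}}$, clamped to
$[0, 1]$ (a post-meal weight a few grams above the pre-meal weight is
expected noise on a ±2 g kitchen scale, so it is clamped with a warning,
not rejected). The fraction is then binned:

* $v = 0$ for $f \le 0.05$ (5% or less ingested),
* $v = k$ for $f \in (0.05 + 0.10(k-1),\; 0.05 + 0.10k]$, $k = 1, \dots, 9$,
* $v = 10$ for $f > 0.95$.

The verbal bin definitions ("between 5% and 15%") leave the boundary
membership open; we fix **lower-open / upper-closed** bins, which matches
the end-point phrasings "5% or less" and "95% or more" verbatim and makes
the rule a total function — a weighing of exactly 15% scores 1, not 2.
A small tolerance ($10^{-9}$) keeps fractions that are mathematically on a
boundary in their lower bin despite floating-point representation error;
this is what makes the weight-pair round trip ($v \to$ weights $\to v$)
exact for every value and portion weight.

Raters that report *leftovers* rather than intake are mapped by the
complement $v = 10 - \text{leftover class}$.

## Nutrient intake

Each dish's menu entry carries its full-portion energy (kcal), protein,
fat and carbohydrate (g). Ingested nutrients are the full-portion content
times $v / 10$ — the fraction the converted value encodes, not the raw
integer; only this reading keeps intake bounded by the portion content.
Meal totals sum over the meal's *evaluable* dishes. Packaged beverages
and seasonings are flagged non-evaluable (their leftovers cannot be
scored visually) and contribute nothing, by construction rather than by
convention. Internally everything is kcal and grams; the report layer
converts protein and fat to mg ($\times 1000$), the unit the clinical
tables use, so there is exactly one unit system in the arithmetic.

Portion weights are not part of published composition tables; the
reference menu ships plausible serving weights (200 g gruel, 150 g soup
and beverages). Every downstream statistic depends only on the ingested
*fraction*, so these placeholders cannot affect any reported value.

## Agreement statistics

All statistics orient differences as **estimated − actual**, so positive
signed quantities mean overestimation, one convention across the signed
mean error, the paired $t$ test and Bland–Altman. For an aligned paired
series $(x_i, y_i)$, $i = 1, \dots, n$:

* $\mathrm{RMSE} = \sqrt{\tfrac1n \sum (x_i - y_i)^2}$.
* $R^2 = 1 - \sum (x_i - y_i)^2 \big/ \sum (y_i - \bar y)^2$ — the
  *mean-reference* coefficient of determination (error relative to a
  model that always predicts the mean of the measured values). This is
  deliberately **not** the squared Pearson correlation; it can be
  negative, and negative values are surfaced, never clipped.
* $\mathrm{ME} = \tfrac1n \sum (x_i - y_i)$ and
  $\mathrm{MAE} = \tfrac1n \sum |x_i - y_i|$ on the converted scale.
* Spearman $\rho$ as the Pearson correlation of midranks, with a
  two-sided $p$ from the $t$ approximation on $n - 2$ df — the standard
  choice at $n \ge 100$; exact permutation $p$ values are out of scope.
* Paired $t$: $t = \bar d / (s_d / \sqrt n)$, $n - 1$ df. All-zero
  differences are reported as $t = 0$, $p = 1$; nonzero differences with
  zero variance are a degenerate input and rejected.
* Friedman test across the related estimation channels, with within-block
  midranks and the standard tie-correction denominator
  $nk(k+1) - \sum (t^3 - t)/(k-1)$. Converted values pile up at 10 (about
  three quarters of dishes are finished), so the uncorrected statistic
  would be badly biased; when every block is a complete tie the statistic
  is defined as 0 with $p = 1$.
* Bland–Altman: mean difference ± 1.96 × sample (n−1) SD of the
  differences, the convention of the agreement literature.
* An 11×11 confusion matrix (rows actual, columns estimated) carrying the
  MAE of the same pairs.

## The synthetic cohort

No per-dish ratings from a real ward are published, so validation runs on
synthetic cohorts that emulate the study conditions:

* **Composition** — each meal is thin rice gruel + vegetable soup + one
  side-2 item; per 100 meals the side-2 counts are exactly
  31/18/12/13/26 (fermented milk, peach, grape, orange, mixed juice),
  randomly assigned; for other cohort sizes the counts act as sampling
  weights.
* **True intake** — each dish's converted value is drawn from the
  empirical distribution 23/6/3/2/9/6/6/6/3/6/230 over $v = 0..10$
  (mean intake rate 84.7%). Dishes are independent by default because the
  dish-by-intake joint distribution is unpublished; the
  `appetite_coupling` knob optionally replaces a dish's draw with a
  shared per-meal draw with probability $a$, inducing within-meal
  correlation while preserving the marginal distribution exactly.
* **Weighing channel** — weight pairs are back-computed from the true
  value ($w_{\text{post}} = w_{\text{pre}}(1 - v/10)$), so reconversion
  recovers the true value exactly and the weighing channel is a faithful
  gold standard.
* **Estimation channels** — a channel estimate is
  $\mathrm{clamp}(\mathrm{round}(v + b_d + \varepsilon),\, 0,\, 10)$ with
  a per-dish signed bias $b_d$ and $\varepsilon \sim N(0, \sigma_d^2)$.
  This additive, discretized, truncated Gaussian is the simplest model
  that matches the first two error moments and reproduces the pileup of
  estimates at the scale end-points that biased raters show when most
  dishes are finished. Default biases follow the published per-dish mean
  errors (AI underestimates gruel −0.22 and soup −0.53; image-visual
  overestimates most dishes; direct-visual is near zero); dispersions
  default to 1.0 scale units for the photo-based channels and 0.4 for
  direct-visual, matching the published *ordering* of method accuracies,
  not the exact table values.
* **Seeding** — one master seed; each channel (and the truth draw)
  consumes a substream derived deterministically from the seed and the
  channel label, so two runs with the same seed are byte-identical and
  adding a channel never perturbs another channel's draws.

What passing tests on this generator do *not* show: real raters are not
additive-Gaussian (their errors depend on intake level and dish
appearance), real intake correlates with dish type, and the ±2 g scale
noise is modelled only through the clamp rule. The generator validates
the *pipeline arithmetic* under the study's marginal distributions, not
the raters.

Because estimates are clamped to 0..10, an injected bias $b$ is *not*
recovered as a raw mean error: a +1 bias on a cohort where 76.7% of
dishes sit at $v = 10$ yields an ME of about 0.23, not 1. The recovery
tests therefore compare the pipeline's ME against the clamp-adjusted
analytic expectation
$\sum_v p(v) \sum_k P(\text{round/clamp} \to k)\,(k - v)$ computed from
the intake distribution and the normal CDF.

## Evaluation levels

Nutrient-level statistics (means, SD, paired $t$, Spearman, RMSE, $R^2$,
Bland–Altman) are computed at **meal level** — one observation per meal,
summing evaluable dishes — because a measured mean energy of ~72 kcal per
observation is only consistent with meal totals, not single dishes.
Dish-level statistics (per-dish RMSE/$R^2$, signed mean errors, Friedman,
confusion matrices) use one observation per dish instance. Methods are
compared only on dish instances rated by weighing *and* every estimation
channel present (complete-case alignment — the paired statistics require
it); excluded instances are counted and reported. Raw $p$ values are
reported without multiple-testing correction, matching how such
validation tables are conventionally presented.

Dish-level series can be degenerate: a dish with zero content of a
nutrient (vegetable soup has 0 g fat) has zero variance on both sides.
Zero residual on zero variance is reported as $R^2 = 1$ (trivially
perfect agreement); nonzero residual on zero variance has no defined
$R^2$ and is reported `NA`.

## Problem sizes and numerical choices

The shipped tests exercise cohorts of 100 meals (300 evaluable dish
instances, the reference study size) for pipeline checks; 10,000+ dishes
for bias-recovery and composition-convergence checks; 100,000 meals for
the mean-intake-rate check; and 10,000 normal differences for
Bland–Altman coverage. Agreement statistics are validated against
independent brute-force re-implementations (direct formula evaluation
with explicit loops, midranks built by counting) to $10^{-10}$ on 100
random series, and against `stats::cor.test`, `stats::t.test` and
`stats::friedman.test` where base R offers the same quantity.

Rounding in the channel model uses R's `round()`; with continuous
Gaussian noise, ties at the half-integers have probability zero, so the
round-half-to-even convention is immaterial. Estimates are clamped
*after* rounding. The report JSON is written at full double precision;
only the rendered markdown tables round to 2 decimals.

## Known limitations

* The generator's channel defaults are qualitative: they reproduce the
  direction and ordering of the published per-method errors, not the
  published RMSE/$R^2$ tables, which depend on unpublished raw ratings.
* Continuous-percentage intake output is out of scope; the analysis is
  defined on the 11-point scale throughout.
* No regression-based Bland–Altman bias correction and no
  repeated-measures variance components: each dish instance is treated
  independently, as in the source analysis design.
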