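---
title: "Comparative wound-healing kinetics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative wound-healing kinetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundrate)
```

## The scientific problem

Skin wounds in mammals close at a roughly constant speed once re-epithelialization
or contraction is under way, so the biologically meaningful quantity is a
*healing rate* in mm/day: the slope of wound-closure distance against time.
Comparative questions — do captive and wild animals heal at the same speed, do
primates heal like rodents, are humans unusually slow — then reduce to
comparing slopes across groups of individuals that were each measured
repeatedly over days to weeks.

`woundrate` implements that comparison as a pipeline with four stages:

1. **Geometry** — recover the minor-axis *width* of an elliptic natural wound
   from its photographed *area*, via a day-one width–length relation.
2. **Kinetics** — turn longitudinal size measurements into *healing
   distances*, the model's response.
3. **Mixed model** — fit a Gaussian linear mixed model with group-specific
   slopes and per-individual random intercepts and slopes, estimate rates in
   mm/day, and test slope contrasts.
4. **Synthetic data** — generate datasets with the statistical structure the
   analysis assumes, so every stage is testable offline and parameter
   recovery is measurable.

## Elliptic wound geometry

Experimental wounds are circular (a 40 mm full-thickness defect), so their
width *is* the measured size. Natural wounds are elongated and approximately
elliptic, and often only the surface area \(S\) is available. Assuming the
wound keeps its shape while healing, and that widths and lengths of fresh
wounds follow a linear relation \(W = aL + b\) (fitted by ordinary least
squares on day-one wounds), substituting \(L = (W-b)/a\) into the ellipse
area \(S = \pi L W / 4\) gives

\[ W^2 - bW - \frac{4aS}{\pi} = 0 . \]

For \(S > 0\) the product of the two roots is \(-4aS/\pi < 0\): exactly one
root is positive, and `width_from_area()` returns it,
\(W = \tfrac12\,(b + \sqrt{b^2 + 16 a S / \pi})\).

Two numerical conventions are worth stating explicitly:

* **Coefficient arrangement.** This quadratic is sometimes typeset with the
  roles of \(a\) and \(b\) interchanged (\(W^2 - aW - 4bS/\pi = 0\)), which
  does not follow from the substitution above. The package implements the
  algebraically consistent form by default and exposes the alternative
  arrangement as `quadratic = "printed"` (also a `--quadratic` flag on the
  command line) purely for sensitivity analysis. With the reference
  coefficients (\(a = 0.121\), \(b = 3.963\)) the two forms differ
  substantially, so any analysis of area-recorded wounds should state which
  was used.
* **The healed limit.** At \(S = 0\) the roots are \(\{0, b\}\); the limit of
  the model as \(L \to 0\) is \(W = b\), which is returned with a warning.
  A fully healed wound is better encoded as a healing distance equal to the
  reference size than pushed through the inversion.

All lengths are mm and areas mm² internally; readers convert cm inputs
through an explicit `unit` column, never silently.

## Healing distances

For one wound and one measurement replicate, the *reference size* is the size
at \(t = 0\) when that is the largest size observed; when an early
inflammatory response enlarges the wound, the maximum observed size is used
instead (both branches equal the trajectory maximum). The healing distance at
time \(t\) is

\[ d(t) = \text{reference} - \text{size}(t), \]

which is 0 at baseline and reaches the reference at complete closure. With
the maximum-size reference the subtraction can never go negative, so the
clipping step is a verified no-op; note that when the inflammation rule fires,
\(d(0) > 0\) — the "zero at baseline" property holds only for monotone
trajectories. Area-recorded (natural) wounds are converted to widths first,
and their first photographed day is re-indexed to \(t = 0\); the calendar day
of injury is not needed. Missing visits are simply absent rows — the linear
model needs no imputation.

Each photograph is measured twice, independently. The default keeps both
readings as repeated measures absorbed by the residual term
(`replicates = "keep"`); averaging per time point is available for
sensitivity checks and shrinks measurement noise by \(\sqrt 2\), which the
test suite verifies by Monte Carlo.

## The mixed model

With groups \(g\) (species, setting, sex, age class, or wound site),
individuals \(i\), and scaled time \(s(t)\),

\[ d_{it} = \beta_{0,g(i)} + \beta_{1,g(i)}\, s(t) + u_{0i} + u_{1i}\, s(t) +
\varepsilon_{it}, \qquad (u_{0i}, u_{1i}) \sim N(0, G), \quad
\varepsilon_{it} \sim N(0, \sigma^2). \]

This is the maximal random-effects structure the design supports: every
individual gets its own intercept and slope deviation. Duplicate
measurements enter as independent residual draws given the individual's
random effects; there is no replicate-level random effect.

**Time scaling.** \(s(t) = (t - \bar t)/\mathrm{sd}(t)\) over all records in
the fitted dataset, using the sample (n−1) standard deviation — the same
convention as R's `scale()` — so that, e.g., times \((0, 2, 4)\) map to
\((-1, 0, 1)\). The constants are stored in the fit and every reported rate
is back-transformed to mm/day (`rate = slope / sd(t)`), making rates
invariant to the scaling choice (verified to \(10^{-6}\) on noiseless data).

**Estimation.** The engine profiles out \(\beta\) and \(\sigma^2\) in closed
form and optimizes the three parameters of a log-Cholesky factorization of
\(\Gamma = G/\sigma^2\) by Nelder–Mead with three starting points (one
data-driven, two fixed) before declaring non-convergence. Because the
random-effect design has two columns, the Woodbury identity reduces every
per-individual computation to 2×2 algebra on precomputed cross-products, so
one REML evaluation costs \(O(\text{individuals})\) regardless of the number
of records. The unpenalized criterion agrees with `lme4::lmer` REML fits to
six significant figures on shared test data (the test suite checks this).

**Boundary avoidance.** Small designs often drive variance-component
estimates onto the boundary (a singular \(G\)). The package adds a
weakly-informative, log-Wishart-style penalty

\[ \lambda\,\bigl(-\log\lvert G\rvert + \operatorname{tr} G\bigr), \]

evaluated at the profiled \(\sigma^2\), whose barrier term diverges as
\(G\) approaches rank deficiency while the trace term stops it inflating
\(G\). The default \(\lambda = 0.01\) is small enough that estimates on
well-behaved data are essentially unchanged (the penalized optimum matches
the unpenalized one to \(10^{-4}\) in the objective as \(\lambda \to 0\)),
and large enough that even noiseless degenerate data return a tiny but
positive-definite \(G\) (numerically floored near \(10^{-8}\)) with the
`singular` flag false. A fit is flagged singular when the smallest eigenvalue
of \(\widehat G\) is below \(10^{-6}\) times its trace.

**Inference.** Rates come with standard errors from the fixed-effect
covariance. Equality of slopes among \(k\) groups is tested by the Wald
chi-square statistic with \(k - 1\) degrees of freedom — the statistic is
invariant to group relabeling and to the time scaling. An F-test with
denominator-degrees-of-freedom corrections (Kenward–Roger style) is a
deliberate non-goal; with few individuals per group the normal-based Wald
machinery is known to be slightly anticonservative, which is a documented
limitation (below) rather than something the package hides.

**Preconditions.** Groups with a single individual abort with an error naming
the group (a random slope cannot be separated from the fixed slope there),
as do individuals observed at a single time point.

**Age classes.** For within-human analyses, `assign_age_classes()` splits
ages at the sample median, tertiles, or quartiles (type-7 quantiles), with
boundary ties going to the lower class.

## The synthetic-data generator

`simulate_healing_data()` draws, for each individual, \((u_0, u_1) \sim
N(0, G)\) and generates a true width trajectory
\(\max(\text{floor},\, W_0 - (r + u_1)t - u_0)\) over a visit schedule with
uniform integer revisit intervals starting at \(t = 0\). Per visit it adds
biological noise (shared by the duplicate readings of that photograph), then
emits `n_replicates` readings with independent measurement noise. Elliptic
profiles convert each noisy width through the forward ellipse model and emit
areas; their closure floor is \(W = b\) (implied area 0) rather than 0 mm.
An optional multiplicative triangular bump emulates early inflammatory
enlargement — a minimal mechanism chosen to exercise the maximum-reference
rule, not a claim about inflammation biology.

The `"study"` preset emulates a seven-group comparative design: 40 mm
circular experimental wounds on baboons (n = 6), Sykes' monkeys (n = 5) and
vervets (n = 6) revisited every 2–3 days over 21 days; natural chimpanzee
wounds (n = 5, 25 mm, every 2–7 days); human post-surgical defects (n = 24,
20 mm, every 3–7 days over 28 days); mice (n = 8, 10 mm) and rats (n = 4,
20 mm) every 1–2 days. Non-human groups heal at 0.6 mm/day and humans at
0.25 mm/day — the headline rates the pipeline should recover. The
`"baboon_wild"` preset generates natural elliptic wounds recorded as areas
(day-one area 1000 mm², ≈15 mm wide) through the reference relation
\((a, b) = (0.121, 3.963)\); `"null_two_groups"` gives two identical groups
of 6 on a fixed 8-visit grid for null calibration.

Values the design itself does not pin down are package choices, made once
and exposed in the profile arguments rather than hidden:

* noise magnitudes — biological `resid_sd = 1` mm and measurement
  `replicate_sd = 0.3` mm, i.e. duplicate readings of one photograph agree
  to a few tenths of a millimetre while day-to-day sizes scatter by about a
  millimetre;
* between-individual spread — `re_cov = diag(1, 0.08²)`: individuals differ
  by ±1 mm in baseline and ±0.08 mm/day in rate (≈13% of 0.6 mm/day);
* wound sizes and horizons for groups without a stated size (25 mm chimp,
  20 mm human, 10/20 mm rodents; horizons 12–28 days), chosen so wounds
  rarely reach the closure floor inside the observation window, keeping the
  generating trajectory linear where it is observed.

What the generator emulates: linear per-individual closure, heterogeneous
rates, two-layer measurement noise, irregular visit schedules,
area-vs-width recording, early enlargement. What it does not: curvature in
late-stage closure, wound-shape change during healing, autocorrelated
measurement error, dropout related to healing speed, or the distinct biology
of contraction versus re-epithelialization. Passing recovery tests therefore
demonstrates that the pipeline is statistically sound under its own
assumptions, not that those assumptions hold for any particular real
dataset.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle: the
quadratic inversion against a numeric root-finder over a 10,000-point
\((S, a, b)\) grid (agreement to \(10^{-8}\), round trips to \(10^{-9}\));
the OLS fits against hand-assembled normal equations; the REML engine
against `lme4` and, on balanced designs (where GLS reduces to OLS exactly),
against closed-form OLS to \(10^{-6}\); and the full pipeline by parameter
recovery. The heavier Monte-Carlo checks use: 100 seeds of the full study
emulation (group rates within 3 SEs of generating values in ≥95% of seeds,
human slowdown ratio in [2, 4.5] in ≥90%); 1000 two-group null replicates
for the type-I error of the Wald contrast; 400 replicates for interval
coverage; and 1000 individuals for distributional checks on simulated
slopes. These sizes keep each property estimable with useful Monte-Carlo
precision while the whole suite completes in minutes.

## Known limitations

* **Small-cluster Wald inference.** With 6 individuals per group the
  slope-variance information carries roughly 10 effective degrees of
  freedom, so normal-quantile Wald intervals under-cover (measured ≈91%
  for a nominal 95% at the null-preset design) and the chi-square contrast
  rejects above nominal (measured 8.7% at α = 5% over 1000 null
  replicates — the test suite records this). Two effects combine: the
  classic z-versus-t smearing of small-cluster Wald statistics, and the
  maximum-reference rule, which under measurement noise induces a small
  shared component among one replicate's distances that the residual term
  treats as independent. Both are shared by any analysis that reads
  \(X^2\) against a chi-square reference on this design; df-corrected
  F-tests are out of scope, and the contrast should be read as
  approximate when groups have few individuals.
* **Penalty at the profiled scale.** The covariance penalty is evaluated at
  the REML-profiled \(\sigma^2\) rather than jointly optimized with it; for
  the small default strength the difference is negligible, and the
  \(\lambda \to 0\) limit is verified against unpenalized REML.
* **The inversion needs \(W \ge b\).** Area-recorded wounds narrower than
  the day-one intercept have no implied length; the generator floors
  elliptic widths at \(b\), and `length_from_width()` refuses smaller
  widths rather than extrapolating.
* Rates are reported per group; the package does not model phylogenetic
  covariance between species, and nothing here identifies the mechanism
  (contraction vs re-epithelialization) behind a rate difference.
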