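---
title: "Methods: nickel toxicity endpoints, LC50 and LT50 estimation in nematode sediment bioassays"
author: "nematox"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nematox)
```

## The assay and its endpoints

The package analyses whole-sediment and water-only toxicity tests in which
10 synchronized, freshly hatched nematode larvae (*Caenorhabditis elegans*
or *Pristionchus pacificus*; the P0 generation) are placed in each well of
a 12-well plate containing 1 mL of test sediment (or water) plus food, and
recovered after one life cycle (96 h for *C. elegans*, 120 h for
*P. pacificus*). Each treatment is run as six replicate wells per trial
with at least two trials, so a treatment typically contributes 12 wells and
at least 120 loaded animals. At harvest, three counts are taken per well:
live P0 adults, dead P0, and F1 progeny. Corpse recovery from sediment is
incomplete, so the validation rule is `live <= added` and
`live + dead <= added`, never equality.

Three endpoints are derived per well:

* **P0 recovery** — live adults recovered (also expressed as a fraction of
  animals added);
* **F1 progeny** — larvae recovered;
* **fecundity index** — progeny per recovered live adult. The well, not the
  animal, is the unit of replication: each well contributes one index, and
  group tests run with n = number of wells.

A well with no recovered adults and no progeny scores a fecundity index of
0; a well with progeny but no recovered adults has no denominator and is
*undefined* — it is logged and excluded from group tests rather than
treated as infinite. Whether a zero/zero well should instead be excluded is
not settled by the assay literature, so both behaviours exist behind the
`zero_recovery` switch; the default is 0, which keeps heavily poisoned
treatments in the comparison rather than silently dropping them.

## Concentration-response model and LC50

P0 recovery (animals/well, per-well points) is regressed on sediment
total-recoverable nickel (TR-Ni, µg/g dry weight) in four least-squares
families:

| family | model | fitting scale |
|---|---|---|
| quadratic ("binomial") | $y = a x^2 + b x + c$ | raw $y$ |
| cubic ("trinomial") | $y = a x^3 + b x^2 + c x + d$ | raw $y$ |
| logarithmic | $y = a \ln x + b$ | raw $y$ |
| shifted exponential | $y + 1 = A e^{k x}$ | $\ln(y+1)$ |

"Binomial"/"trinomial" are the reporting convention for 2nd-/3rd-degree
polynomials in this assay literature (nothing to do with the binomial
distribution); `fit_dose_response()` accepts them as aliases. The shifted
exponential is fitted by log-linear least squares of $\ln(y+1)$ on $x$ —
the spreadsheet-trendline convention — because an exponential decay fitted
to raw counts would have to cross zero, and the +1 shift sidesteps that.
$R^2$ is reported on the fitting scale, so the exponential $R^2$ refers to
the log scale; this matches how trendline software reports it, and is the
reading we adopt where the convention is ambiguous.

The **LC50** is defined operationally: the smallest positive concentration
at which the fitted curve crosses the *half-of-control* line,

$$y_{\mathrm{target}} = \tfrac12 \,\overline{y}_{\mathrm{control}},$$

computed by `control_target()` from the control wells. In replication mode
(`round_target = TRUE`) the target is rounded half-away-from-zero to a
whole animal, reproducing the integer target lines (y = 5 for
*C. elegans*, y = 4 and y = 3 for *P. pacificus* in the two spiked
series) used in the published analysis. For the shifted exponential the
intersection is taken on the fitting scale, i.e. against
$y_{\mathrm{target}} + 1$. Controls enter the fits at their *measured
background* TR-Ni (59.7 µg/g and 8.9 µg/g for the two sediments), never at
zero — this is what keeps $\ln x$ defined at every dose.

Root finding: quadratic, logarithmic and exponential intersections are
closed-form; the cubic is bracketed numerically (sign-change scan over an
8192-point grid, then `uniroot`) to an absolute tolerance well below
10⁻⁶ µg/g. The *smallest* positive root inside `(0, search_max]` is taken,
with `search_max` defaulting to 1.5× the largest tested concentration;
cubics re-cross the target line outside the tested range, and those
extrapolated crossings are not biologically meaningful. Complex-only
quadratic roots, or no crossing in range, report "not attained" (`NA`).
The reported LC50 *range* for a series uses the polynomial families only
(`lc50_range()`), the families that consistently fit these data best.

Two conventions were genuinely open and are fixed as follows: wells from
all trials of a treatment are pooled for fitting (per-trial fitting is
available by subsetting); and fits use per-well points rather than
treatment means (a means-based mode exists via
`dose_response_points(..., means = TRUE)` for sensitivity checks).

## Survivorship over time and LT50

Adult lifespan in sediment is measured by destructive daily sampling: 22
wells are loaded per treatment (~55 or ~75 animals per well depending on
trial date) and one whole well per treatment is harvested each day for 22
days. Each day's fraction alive — live recovered over initially added for
*that* well — is therefore an independent cohort, which is why the package
offers no Kaplan–Meier machinery: there is no censoring structure to
exploit. Trial dates differed between treatments, so initial counts differ
(~55 versus ~75 animals per well); per-well `n_initial` is carried through
every computation, so nothing depends on which treatment received which
count.

`fit_survivorship()` fits a cubic in day to the 22 fractions by ordinary
least squares; `lt50()` returns the smallest positive day at which the
cubic crosses 0.5, bracketed numerically to well below the 10⁻⁴-day
tolerance, restricted to the observation window. A curve that never
reaches 0.5 inside the window reports "beyond window" (`NA`), with any
extrapolated crossing (searched out to 10× the window) logged as an
attribute rather than reported — a cubic's behaviour outside its data is
an artefact. Fitted cubics may leave [0, 1] slightly; values are reported
unclamped as a diagnostic of the polynomial approximation.

## Group comparisons

Per-well endpoint values are compared across treatments by classical
one-way fixed-effects ANOVA followed by Tukey HSD (`TukeyHSD()`'s
studentized-range comparisons, with the standard adjustment for unbalanced
groups). Homogeneity of variance is *assumed*, matching the analysis
convention for these assays; a Brown–Forsythe diagnostic is printed but
never gates. All wells enter, including values a box-plot convention would
flag as outliers.

`compact_letter_display()` implements the insert-and-absorb algorithm: one
letter column initially contains all groups; each significant pair splits
every column containing both members; columns absorbed by a superset are
dropped. The result guarantees the display invariant exactly — two groups
share a letter if and only if their adjusted p-value exceeds α — and
represents non-transitive patterns (A≈B, B≈C, A≠C) with overlapping
letters. Letters are ordered by descending group mean so the
best-performing group reads "a". No installed package exposes this
algorithm over a bare p-value matrix (the usual implementations want a
fitted model object), so it is implemented directly and property-tested
against the invariant on randomized significance patterns.

## The synthetic-data generator

`simulation_config()` fixes the study conditions the generator emulates:

* dose grid = the measured TR-Ni values of the high-organic spiked series
  (59.7, 156, 369, 1040, 2680, 7660 µg/g);
* 12 wells per dose (two trials of six), 10 larvae per well;
* developmental survival: live adults ~ Binomial(10, p(dose)), with the
  default p(dose) a logistic in dose (p₀ = 1.0, midpoint 1273 µg/g, Hill
  slope 1.5 — midpoint set to the quadratic-based LC50 estimate for that
  series, slope a moderate value chosen once as realistic for this span);
* progeny ~ negative binomial with mean = live adults × 2.5 and
  variance = 2 × mean. No progeny-count distribution is published for this
  assay, so the per-adult rate matches the ~25 larvae/well recovered in
  the best control sediment, and the dispersion is a conventional moderate
  choice; both are config fields, and the per-dose multiplier defaults to
  1 because fecundity indices are statistically flat across sediment
  doses;
* incomplete corpse recovery: recovered dead ~ Binomial(dead, 0.75);
* longevity: one independent cohort per day, live ~ Binomial(n_initial,
  e^(−h·day)), with default hazards ln 2/{16, 16, 7, 3} days⁻¹ and initial
  counts {55, 75, 75, 55} matching the four tested treatments.

One global seed governs everything, with per-well substreams derived
deterministically from (seed, well index), so tables are identical across
runs and do not depend on how many doses are generated.

`true_lc50()` returns the generator's ground truth in closed form: the
dose at which p(dose) falls to half its dose-0 value. For the logistic
family this is exactly the `lc50` parameter; for a polynomial truth the
half-intercept target is handed to the same root-finder the analysis uses.
The dose-0 intercept (rather than the lowest tested dose) is the reference
because it is the generator's un-dosed control level; the lowest tested
dose carries measured background nickel and sits marginally below it.

**What the generator does not emulate.** Real wells share trial-level
batch effects; simulated wells are exchangeable within a dose. Survival
follows the configured curve exactly, so passing parameter-recovery tests
shows the *estimators* work, not that real dose-response curves are
logistic or polynomial. There is no AVS/TOC-dependent bioavailability
mechanism, no between-sediment heterogeneity, and no multigenerational
carry-over. A visible consequence shows up in the analysis drivers:
polynomial fits to a logistic truth over a 59.7–7660 µg/g span overshoot
the generator's LC50 by roughly 20%, which is a limitation of the
curve-family-plus-intersection procedure itself, not of the estimation
code — on a polynomial truth the same pipeline recovers the true LC50 to
within a few percent.

## Numerical choices and problem sizes

* Least squares everywhere is QR-based (`lm.fit`); tests cross-check
  coefficients against explicit, column-equilibrated normal equations to
  10⁻⁹.
* Root tolerances: 10⁻⁶ µg/g (concentration), 10⁻⁴ day (time); tests
  cross-check against exhaustive fine-grid sign-change scans to 10⁻³.
* A flat response (zero variance) fits with $R^2 = 1$ when residuals are
  exactly zero, and is rejected otherwise.
* Degenerate designs (too few distinct doses/days, collinear covariate
  subsets) are rejected or flagged, never silently dropped.
* Simulation sizes used in the test suite were chosen to make the checks
  sharp at interactive cost: law-of-large-numbers checks use 10⁴ wells per
  dose (1% tolerance), parameter recovery uses 200 wells per dose for the
  LC50 (5% tolerance) and 500 animals per day for the LT50 (10%
  tolerance), convergence of the estimation error uses 100 seeds over
  {12, 48, 200} wells per dose, and the letter-display invariant runs over
  1000 random significance patterns.

## Reproducing the published estimates

The raw well-level data behind the published fits are not deposited, so
the package ships the printed best-fit coefficients as fixtures
(`reported_dose_response_curves()`, `reported_survivorship_curves()`) and
re-derives every published LC50 (12 values, including the raised-target
exponential rows) and every published 50%-survival day (4 values) by
applying its own intersection rules to them. `replicate_reported()` flags
any row deviating more than 0.5% relative; all sixteen reproduce to within
a few parts in 10⁵, the residual being the 4–5 significant figures of the
printed coefficients.

## Known limitations

* Polynomial and log/exponential families are empirical descriptions;
  no probit/logit or four-parameter logistic model is offered, and no
  confidence intervals on LC50/LT50 are produced (none are published for
  this design, and the intersection construction does not yield them
  without a resampling layer).
* The covariate screen is an all-subsets OLS ranking, not an inferential
  model; with eight sediments and up to three factors it is descriptive
  only.
* Pore-water-normalized toxicity modelling and bioavailability mechanisms
  are out of scope; the treatment tables carry the chemistry needed to
  attempt them downstream.
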