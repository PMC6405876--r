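---
title: "Methods: open-population demography, dispersal and resource selection from mark-release-recapture data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: open-population demography, dispersal and resource selection from mark-release-recapture data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mrrkit)
```

mrrkit analyses butterfly (or other short-lived insect) mark-release-recapture
(MRR) surveys end to end: open-population demography, movement and dispersal
kernels, wing-wear ageing, behaviour and nectar-source selection, plus a
seeded simulator that generates full synthetic studies with known ground
truth. This vignette documents the models, the conventions, and the design
decisions, so that every number the package prints has a stated definition.

## Encounter data

A survey is a set of capture records (individual id, date, sex, planar
location, wing-wear score 1–4, behaviour, optional nectar taxon) and a
session calendar (sampling dates with effort hours). Sessions are calendar
*dates*: days without sampling (weather gaps) are not sessions, but they
contribute to the gap in days between sessions so survival can be scaled per
elapsed day. Within-session duplicate captures of one individual collapse to
a single detection keeping the first payload (recapture events are counted
across days, not within them); the collapse count is logged. Sex is
immutable per individual — conflicting codes are a hard error rather than a
majority vote, because marking errors must surface.

Longitude/latitude input is converted once at ingestion to a local
tangent-plane metric projection centred on the data centroid; at the
sub-kilometre scale of these surveys the projection error is far below GPS
error. Unprojected geodetic coordinates are refused by the distance
computations rather than silently treated as metres.

## POPAN demography

The demographic core is the POPAN (Schwarz–Arnason) parameterization of the
Jolly–Seber open-population model. A superpopulation of `N` individuals
enters the sampled population according to entry probabilities `pent_t`
(summing to 1 over sessions), survives between sessions with apparent daily
survival `phi`, and is detected at each session it is alive with capture
probability `p_t`. With `psi_1 = pent_1`,
`psi_{t+1} = psi_t (1 - p_t) phi_t + pent_{t+1}` and
`chi_t = (1 - phi_t) + phi_t (1 - p_{t+1}) chi_{t+1}`, the log-likelihood is

```
log C(N, n) + (N - n) log pi0
  + sum over histories of
      log psi_f + log p_f
      + sum_{t = f+1..l} [ log phi_{t-1} + y_t log p_t + (1-y_t) log(1-p_t) ]
      + log chi_l
```

where `pi0 = 1 - sum_t psi_t p_t` is the probability of never being
detected and `f`, `l` are the first and last detection. The implementation
is verified against an independent oracle that enumerates every
(entry session, last-alive session) pair per individual, including the
unseen ones.

Model structures use the field's dependency grammar
`{Phi(...) p(...) pent(...) N(...)}` with vocabulary `.` (constant), `g`
(sex), `t` (factorial time), `T` (linear time) and `hours` (session effort,
capture probability only), combined with `+` (additive) or `x`
(interactive). Links are logit for `phi` and `p`, multinomial logit with the
last session as reference cell for `pent`, and a shifted log for `N`:
`N = n_observed - 1 + exp(eta)`, which enforces the bound that the
superpopulation cannot be smaller than the number of distinct individuals
seen. Conventions worth stating explicitly:

* **Unequal spacing.** Daily survival is raised to the calendar gap in days
  between sessions, and linear time `T` enters as centred elapsed calendar
  days (not session index), evaluated at the session opening each interval.
* **Effective sample size for AICc** is the total number of capture events
  (captures plus recaptures), configurable; published MARK analyses do not
  state their choice, so ours is documented rather than assumed identical.
* **Parameter counting.** Both the structural count `K` (used in AICc) and
  the numerically estimable count `K_est` (rank of the observed information
  at relative tolerance 1e-6) are reported. Published tables often print
  estimability-adjusted counts that cannot be reconstructed from structure
  alone; boundary entry probabilities routinely reduce the rank.
* **Optimization.** BFGS on the negative log-likelihood with
  finite-difference gradients, from a default start (logit 0 rates, uniform
  entry, `N` at twice the observed count) plus 5 seeded jittered restarts;
  convergence requires a gradient norm below `1e-6` relative to the
  objective magnitude. Non-convergence is an error carrying the best point
  and gradient norm, not a silent result. Real parameters that reach 0 or 1
  within `1e-12` yield `-Inf`, never `NaN`.
* **Model selection** sorts by AICc and, within a `delta < 2` equal-support
  band, selects the fewest-parameters model (ties broken by AICc, then by
  the canonical model string).

Derived abundance follows `B_t = N pent_t`, `N_1 = B_1`,
`N_{t+1} = N_t phi_t^gap + B_{t+1}`; recruitment conserves the
superpopulation exactly. Standard errors use the delta method through the
beta covariance (inverse observed information, with a pseudo-inverse when
the information is singular).

Goodness of fit is a parametric bootstrap: simulate from the fitted model,
refit, and report the percentile of the observed deviance in the bootstrap
distribution. This replaces contingency-table GOF machinery that is
specific to legacy software; it is labelled as such, requires at least 20
bootstrap replicates, and its percentile is checked for calibration in the
test suite (data simulated from a fitted model should give non-extreme
percentiles).

## Dispersal

Movement distances are Euclidean distances between consecutive captures of
the same individual. The inverse cumulative proportion (ICP) at distance
class `i` (width `w`, conventionally 20/30/50 m) is the fraction of moves
with distance at or beyond `(i - 1) w`; the first class is always 1. Two
ambiguities had to be resolved: the at-or-beyond rule uses `>=` (rather than
`>`), and proportions are per *move* by default with a `per_individual`
flag restricting to each individual's first recapture (the convention of
percentage-of-recaptured-individuals figures).

Kernels are fitted by least squares on the linearised forms over the class
*index* `x` (not metres — extrapolation tables in this literature address
"interval numbers", which fixes the convention): `ln I = ln a - k x` for the
negative exponential function (NEF) and `ln I = ln a - k ln x` for the
inverse power function (IPF). Classes at or beyond the first zero
proportion are excluded (zero is never log-transformed), at least three
positive classes are required, and `R2_adj = 1 - (1 - R2)(n-1)/(n-2)` with
the slope F test reported. A nonlinear least-squares refinement exists
behind a flag for sensitivity checks; the linearised fit is the reference
method because the published F statistics come from linear regression in a
general statistics package. Extrapolation maps `d` kilometres to
`x = 1000 d / w` (1 km is interval 20 at 50 m width) and returns the kernel
prediction as a percentage.

Sexes are compared with a two-sided Mann–Whitney U test: exact for combined
sample sizes up to 20 without ties, normal approximation with tie
correction otherwise.

## Wing wear

Wing condition is scored 1 (pristine) to 4 (seriously damaged) and is used
as an age proxy. Two regressions are provided. The population-level trend
regresses the unweighted daily mean score per sex on the calendar-day
serial number, using only days with at least 5 scored individuals of that
sex (the threshold is configurable); using serial days explains the large
negative intercepts conventional in this literature, and only the slope is
interpreted. Weighting days by sample size is *not* applied — the published
convention is unstated, so the simpler choice is documented. The
individual-level decay sets the first capture to zero and takes one pair
(days since first capture, score difference) per later detection — pairs
are always relative to the *first* capture, not chained — then fits a
regression through the origin, `slope = sum(xy) / sum(x^2)`, alongside the
mean per-pair daily rate with its SE. Score decreases (wing wear cannot
heal) trigger a data-quality warning but are retained.

## Behaviour and nectar-source selection

Behavioural dimorphism uses only first captures (one observation per
individual, so individual preferences cannot inflate the sample) in a
Pearson chi-squared homogeneity test without continuity correction;
zero-total categories are dropped with a warning, zero cells within used
categories are kept.

Selection compares used against available proportions. Jacobs' index
`D = (r - p) / (r + p - 2rp)` enters the used proportion at full precision
(`x/n`, not printed 3-dp values — rounding first visibly changes
second-decimal results at `n = 59`), with ratings `D > 0.33` preference,
`D < -0.33` avoidance, and the closed interval in between neutral.
Simultaneous multinomial intervals split the familywise alpha across the
`k` candidate categories (all candidates, including never-used ones, by
default). Because the transformation behind the classic tabulated intervals
is not uniquely identifiable from published tables — published lower bounds
are not even monotone in the count in at least one instance — the variant
is configurable: a variance-stabilising arcsine transformation with 3/8 and
3/4 continuity adjustments (default) or Goodman-style quadratic score
intervals. Both are validated structurally against Bonferroni-adjusted
exact binomial intervals computed by tail summation; printed interval
endpoints from the literature are deliberately not targets. The selection
pipeline tests sex homogeneity first and pools when non-significant; at the
genus level the denominator `n` remains the total number of feeding visits
even when the candidate set is restricted to the genera of one family, so
used proportions remain comparable across levels.

## The synthetic study generator

The simulator draws a full study from an explicit configuration: entry
session per individual from a multinomial entry schedule; daily Bernoulli
survival with a logit-linear structure (intercept, sex offset, day slope);
daily movement by a kernel-distance, uniform-heading step reflected at the
arena borders (positions evolve every day, so consecutive-capture distances
aggregate several steps, as in reality); per-session capture with
effort-dependent logit probability; observed wing scores
`clamp(1 + rate * age + Normal(0, sigma), 1, 4)` rounded to integers with
noise applied *before* discretisation and monotonicity enforced by running
maximum (wear cannot reverse); behaviour i.i.d. per capture from a sex
multinomial (no behavioural syndromes — the simplest structure consistent
with a first-capture chi-squared analysis); and a flower-choice multinomial
for feeding captures. Everything is reproducible from a single mandatory
seed.

The study template (`study_template()`) encodes a short arctic flight
period: 10 irregular sessions across a 26-day window, 434 males + 291
females, female modal entry delayed two days, daily survival 0.80 (males)
with a +0.35 logit female offset and a mild seasonal decline, wing decay
0.10/0.09 score units per day, male-biased flight behaviour and flower
choice concentrated on one genus. Where the emulated design does not pin a
value the choice is documented here once: effort hours are fixed
study-plausible values between 3 and 6 h; capture intercepts were set with
the analytic calibration helper (`calibrate_capture()`) so the expected
number of marked individuals is 261; daily step means (90/60 m) reproduce
mean consecutive-capture displacements near 143/92 m in a 700 x 250 m
reflecting arena; wing noise `sigma = 0.15` makes simulated decay-rate
standard errors close to 0.01.

What the generator does *not* emulate — and hence what passing tests do not
certify about real data: weather-driven detectability beyond effort hours,
temporary emigration and soft study-area borders, individual heterogeneity
in catchability, movement or behaviour, density-dependent dispersal, and
observer differences in wing scoring. Parameter-recovery results therefore
demonstrate correctness of the estimation machinery under the model, not
robustness to these violations.

## Problem sizes and statistical checks

The test suite runs entirely on synthetic data built at test time. Sizes
were chosen to keep the checks sharp but quick: likelihood-vs-enumeration
on 200 random instances (2–4 sessions, up to 5 histories, superpopulation
up to 8); parameter recovery on 50 replicates of a 700-individual,
10-session single-sex design (within 2 SE for `phi`, `p`, `N` in >= 90% of
replicates; 95% Wald coverage >= 85%); kernel discrimination on 100
replicates of 65 exponential distances (NEF out-fits IPF by adjusted R^2);
GOF calibration on 20 meta-replicates of 20 bootstraps each; wing-decay
direction on 50 template replicates.

One statistical limitation deserves explicit statement. At study scale the
sex difference in wing decay (0.10 vs 0.09 units/day) is smaller than its
sampling uncertainty: with integer scores and 16–62 recapture pairs per sex
the standard error of each rate is about 0.01, so the *direction*
male > female reproduces in only roughly three quarters of simulated
studies. A single study observing this direction is therefore weak evidence
by itself; the package reports rates with standard errors so users can see
this directly.

## Known limitations

* No CJS-only, multi-state, robust-design or Bayesian variants of the
  demographic model.
* Contingency-table (RELEASE-style) goodness of fit is intentionally not
  re-implemented; the parametric bootstrap is the supported GOF.
* Wing scores are treated as numeric 1–4; no ordinal model.
* Kernel fits are linearised least squares on class indices; standard
  errors for extrapolated percentages are not propagated (extrapolations
  orders of magnitude beyond the data should be read as model output, not
  inference).
* The availability table is taken as known; uncertainty in plant-community
  inventories is not propagated into selection ratings.
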