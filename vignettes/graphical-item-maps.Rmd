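---
title: "Graphical item maps: models, layout rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graphical item maps: models, layout rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gimkit)
```

## What a graphical item map is

A graphical item map (GIM) gives one exam candidate a picture of their
performance that is organised for *learning*, not ranking. Four
variables build the map: the items themselves, each item's subject
cluster, its relative difficulty, and whether the candidate answered it
correctly. Items answered correctly appear left of a central vertical
axis, incorrect items to the right; the vertical position is the item's
difficulty in logits (higher = harder); columns group items by subject
cluster. The candidate's ability estimate is drawn as a horizontal
line, optionally joined by the pass standard, which together cut the
map into four quadrants. The lower-right quadrant — items easier than
the pass standard that the candidate nevertheless missed — is where
revision effort pays off first.

## Measurement model

### Rasch calibration by conditional maximum likelihood

Dichotomous responses are modelled by the Rasch item characteristic
curve $P(x_{ni}=1) = \mathrm{logit}^{-1}(\theta_n - \delta_i)$. We
estimate the $\delta_i$ by conditional maximum likelihood: given a raw
score $r$, the person parameter drops out of the pattern likelihood,
whose normalising constants are the elementary symmetric functions
$\gamma_r$ of the easiness terms $\varepsilon_i = e^{-\delta_i}$.
`elementary_symmetric()` evaluates $\gamma_0\ldots\gamma_n$ with the
summation recursion (one pass per item, numerically stable), never by
subset enumeration; the enumeration form survives only as a test
oracle. CML was chosen over marginal maximum likelihood deliberately:
it assumes nothing about the ability distribution, its sufficiency
structure (ability depends on data only through the raw score) is
exactly testable, and the ESF machinery admits an independent
brute-force oracle. The estimator solves the score equations by Newton
iterations with the analytic gradient and full Fisher information
(pairwise item covariances via pair-deleted ESFs), step-halved on the
conditional log-likelihood, to a gradient max-norm of 1e-8 or 100
iterations (both overridable). Identification uses the mean-zero
constraint, applied after optimising in a reference-item gauge; the
reported standard errors are the free-parameter covariance projected
onto the mean-centred scale.

Items answered correctly by everyone or no one carry no information
about their own difficulty; they are excluded and *reported* in
`excluded_items`, never silently dropped or pinned to pseudo-values.
Likewise persons with raw score 0 or $n$ contribute nothing to the
conditional likelihood and are listed in `excluded_persons`. The two
exclusion rules are alternated until stable.

### Person measurement

Abilities use Warm's weighted likelihood estimator: the solution of
$r - \sum_i p_i + J/(2I) = 0$ with $I = \sum p_i(1-p_i)$ and
$J = \sum p_i(1-p_i)(1-2p_i)$, found by safeguarded Newton/bisection to
a residual of 1e-10. WLE matters operationally because it is finite at
zero and perfect scores — a feedback map must exist for *every*
candidate, including the ones at the extremes, where plain maximum
likelihood diverges. Standard errors are $1/\sqrt{I}$ at the estimate.
Because the raw score is sufficient, `estimate_persons()` solves each
distinct score once and shares the result; equal raw scores give
bitwise-equal abilities by construction.

Calibration and person measurement are decoupled: `estimate_persons()`
accepts anchored bank difficulties directly, supporting the operational
mode where item difficulties are treated as invariant across assessment
sittings.

### Pass standards and fit

A percentage pass mark is converted to logits by inverting the test
characteristic curve $T(\theta)=\sum_i p_i(\theta)$ with bisection to
an interval of 1e-12, so the returned ability (not merely its expected
score) is pinned within tolerance. Item quality is monitored with
infit (information-weighted) and outfit (unweighted) mean squares of
standardised residuals; cells with numerically degenerate probabilities
are excluded from the sums with a reported count. On model-conforming
data both statistics concentrate near 1; a miskeyed item shows up as
outfit well above 1.5, which is what the annual item review looks for.

## Layout rules

Several layout behaviours are deliberate choices where the map grammar
itself leaves room:

- **Co-location.** Within each (cluster, side) cell, items are merged
  by single linkage with a 0.15-logit tolerance: a chain of items each
  within tolerance of its neighbour forms one group even when its
  extremes are farther apart. 0.15 logits is roughly a typical item
  difficulty standard error at cohort sizes of a few hundred, so items
  closer than that are statistically indistinguishable anyway. The
  group sits at the mean difficulty of its members and its label
  carries the member count in parentheses (`DECEL (3)`). Tolerance 0
  degenerates to singletons up to exact ties.
- **Quadrant boundary.** An item exactly on the pass line falls in the
  *lower* quadrants, and a difficulty exactly at the ability line
  counts as "at or below" it for flagging. Closed-below conventions
  keep revision guidance conservative: borderline items are treated as
  revisable, not as secure.
- **Flagging.** Published maps annotate strengths and weaknesses by
  hand; this package operationalises them deterministically. A cluster
  is a *weakness* when at least 2 of its items are incorrect at
  difficulties at or below the candidate's ability (easy misses); a
  *strength* when it has at least 3 items, no easy misses, and at
  least one correct item above the ability line; weakness wins if both
  fire. Both thresholds are configurable in `layout_config()`.
- **Column order** follows the canonical eight-cluster listing (PHYS,
  UPFH, NORM, BFHR, DECEL, MHR, UNCOM, RANZ); clusters outside that
  set are appended alphabetically so custom banks stay reproducible.
- **Pass line optionality.** Operational maps may omit the pass line;
  `build_gim()` therefore makes it optional, and quadrants are only
  assigned when it is present.
- **Blank responses** default to score 0: an unanswered item in a
  supervised exam earns no credit. A `blank_policy = "missing"` switch
  keeps blanks out of facility denominators for other administrations.

## Variants

**Partial credit.** For polytomous items scored with the partial
credit model, each score category $k$ is placed at its own
adjacent-category threshold $\delta_{ik}$ — the model's native
parameters, rather than cumulative/Thurstonian locations — attained
categories ($k \le x$) on the left, unattained on the right. A
candidate scoring two of three points sees categories 1 and 2 left and
category 3 right. Thresholds are *inputs* (anchored): estimating PCM
parameters is out of scope, which keeps every placement testable
against closed forms, and a single-threshold item reduces exactly to
the dichotomous rule. Polytomous categories do not join co-location
groups.

**Classical facility axis.** A map can be built without Rasch scaling
at all: items are placed by $100 - \mathrm{facility}$ ("percentage
difficulty") on a 0–100 axis, so the harder-is-higher orientation
matches the logit map. The candidate's line is their percentage
incorrect on the same axis. On Rasch-conforming data facility is a
monotone-decreasing proxy for difficulty (rank correlation below
−0.9 in the acceptance checks), so the two variants induce the same
within-column ordering up to ties.

**Practitioner levels.** Percentage bands classify candidates into
levels 0–3. The published anchors are level 1 = 55–65 % and level 3
strictly above 75 %; the unstated gaps are closed as level 0 = [0, 55),
level 1 = [55, 65], level 2 = (65, 75], level 3 = (75, 100]. The
closure at 65 and 75 is a documented convention consistent with the
strict ">" of the level-3 anchor, not a published fact.

## Rendering

SVG was chosen over raster output so snapshot tests can compare bytes.
Coordinates are printed with two decimals via `sprintf` (locale-free in
R), labels are anchored rather than measured (no font-metric
dependency), and overlapping labels in a column are separated by a
fixed 0.1-logit nudge in document order. Given the two-decimal
coordinate grid, the affine logit-to-pixel map is verified to output
precision (residual spread under 0.06 px) rather than to floating
tolerance. Ellipse outlines bound the flagged cluster's groups on its
dominant side; exact ellipse geometry on the published figures is not
replicated. A monospaced text renderer (one row per 0.25 axis units,
`T` marking the ability row, `P` the pass row) serves terminals and
diff-friendly tests. The golden files under `tests/testthat/golden/`
were frozen from the first manually verified render of the fixture
candidate.

## Synthetic data

The operational item bank and candidate data are confidential, so all
testing runs on a generator that emulates their shape:
`make_fsep_fixture()` builds 60 dichotomous items with true
difficulties evenly spaced on [−3, 3] logits (the span visible on
published maps), clusters assigned round-robin over the eight canonical
labels, and 200 candidates with abilities drawn from Normal(0.5, 1) —
a cohort mostly above the item centre, as expected for practising
clinicians. Responses are Bernoulli draws from the item characteristic
curve under a fixed seed; equal seeds reproduce outputs exactly on one
platform (cross-platform bit identity is not promised). What passing
tests on this fixture *do* show: the estimators recover their
generating parameters, every layout invariant holds cohort-wide, and
the pipeline runs end to end. What they *cannot* show: behaviour under
real-data pathologies — guessing, speededness, multidimensionality,
item drift — none of which the generator emulates (only a deliberate
miskeying helper exists, used to validate the fit statistics).

Problem sizes in the checked properties — 2 000 persons for recovery
studies, 200-candidate cohorts for layout invariants, 5-item banks for
oracle comparisons — were chosen so each study is comfortably
informative at desk scale while the full suite stays fast.

## Known limitations

- Dichotomous Rasch only: no 2PL/3PL discrimination or guessing
  parameters, no marginal-ML or Bayesian estimation, no DIF analysis.
- PCM support is mapping-only; mixed dichotomous/polytomous
  *calibration* is not implemented.
- CML requires complete response matrices; structurally missing
  designs (linking, adaptive administration) are not supported.
- The flagging rule is a deterministic stand-in for what practitioners
  annotate by judgement; its thresholds are defaults to tune, not
  validated cut-offs.
- Exact numeric agreement with any production scale is not expected:
  operational estimation settings differ (and are not public), and the
  logit scale is only identified up to its constraint.
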