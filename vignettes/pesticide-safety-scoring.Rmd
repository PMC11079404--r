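---
title: "Scoring pesticide environmental safety with a Mamdani fuzzy model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pesticide environmental safety with a Mamdani fuzzy model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beesafe)
library(dplyr)
```

## The problem

Choosing among registered pesticides is a trade-off between efficacy against
the pest and collateral damage to the receiving environment — above all to
pollinators. beesafe implements a fuzzy-logic decision-support model that
condenses five ecotoxicological properties of a compound into a single
safety level point on a 0–10 scale (higher is safer), so that candidate
products can be ranked before application:

* **persistency** — soil half-life in days (0–30 non-persistent, 31–99
  moderately persistent, 100–200 persistent);
* **AEQ** — the agroecology environment quality quotient, the reciprocal
  honey-bee toxic unit (below 1 high contamination, 1–2 moderate, 2 and
  above low);
* **LD50** — acute contact toxicity toward honey bees in µg/bee (below 1
  highly toxic, 1–100 moderate, above 100 low);
* **likely exposure** — a 0–4 score for how likely bees are to contact the
  compound on plant surfaces (0–2 unlikely, 3–4 likely);
* **MRL** — the legally tolerated maximum residue limit in mg/kg (below 250
  low limit, 250–400 high limit). A *low* limit marks the more hazardous
  compound: regulators tolerate less of it in food.

The engine is a classical Mamdani controller: crisp inputs are clamped to
each parameter's universe, fuzzified through per-category membership
functions, pushed through an exhaustively enumerated rule base, and the
aggregated consequent is defuzzified by the centroid method.

## The weighted rule base

Rather than eliciting 108 individual expert judgements, the rule base is
*generated*. Each category carries a code $p_i$ (0 for the environmentally
best category, 0.5 for the middle one, 1 for the worst), each parameter a
weight $w_i$ from a two-expert panel, and every combination of categories
becomes a rule whose consequent is

$$\text{Not Safe} \iff \sum_{i=1}^{5} p_i\,w_i > 0.5 ,$$

with an exact tie at 0.5 classified Safe. Expert ratings (0–5 importance
scales) are normalized per expert and averaged:

```{r weights}
w <- expert_weights(load_fixture("expert_ratings"))
tidy(w)
```

The averaged weights are kept internally as exact fractions
(7/30, 6/30, 7/30, 5/30, 5/30), so the threshold comparison is integer
arithmetic and tie detection cannot be disturbed by floating-point round-off.
Six of the 108 rules sit exactly on the 0.5 boundary; all are Safe. The
generated base is monotone by construction: worsening any one antecedent
category can only move a rule toward Not Safe, which the test suite asserts
by exhaustive enumeration.

```{r rules}
m <- default_model()
glance(m)
```

## Membership functions and their calibration

The persistency family uses the trapezoid/triangle shapes
(non-persistent `trapmf [0, 0, 30, 65]`, moderate `trimf [15, 65, 150]`,
persistent `trapmf [65, 100, 200, 200]`), and the exposure score uses the
smooth saturation pair `zmf [1, 3]` / `smf [1, 3]`; both families are fixed
by the model definition. The z/s shapes are the standard quadratic splines
with degree ½ at the breakpoint midpoint — every bundled record sits at the
saturated exposure score 3, so results are insensitive to the exact spline.

The AEQ, LD50 and MRL families are *reconstructions*: their category
boundaries (1 and 2 for AEQ; 1 and 100 for LD50; 250 for MRL) are fixed by
the standard categorizations, but the interior shoulder points are not
printed anywhere. They were calibrated once against the bundled
ten-pesticide study and then frozen:

* AEQ on [0, 20]: high contamination `trapmf [0, 0, 1, 1.25]`, moderate
  `trimf [0.5, 1.5, 2.5]`, low `trapmf [1.5, 2, 20, 20]`. The 1.25 shoulder
  is pinned by fenthion (AEQ 1.11), the only record that falls between the
  high and moderate categories.
* LD50 on [0, 200] µg/bee: high toxicity `trapmf [0, 0, 1, 50.5]`, moderate
  `trimf [0.5, 50.5, 125]`, low `trapmf [50.5, 100, 200, 200]`. The moderate
  apex at the 50.5 midpoint and the 125 upper vertex are pinned by DDT
  (LD50 8.8, partial moderate membership 0.166) and dodine (LD50 145, which
  must fire no Not-Safe rule).
* MRL on [0, 400] mg/kg: low limit `zmf [100, 400]`, high limit
  `smf [100, 400]`, crossing at the 250 boundary. All bundled records are
  ≤ 10 mg/kg and saturate, so only the crossover location matters.

The output consequents on [0, 10] are the unique symmetric shoulder pair
Not Safe `trapmf [0, 0, 3, 7]` / Safe `trapmf [3, 7, 10, 10]`: their
full-activation centroids, $79/30 \approx 2.63$ and $7.37$, bound every
attainable score and match the reference end points.

```{r mfs, fig.width = 7, fig.height = 5}
autoplot(m)
```

## Inference and defuzzification

Rule activation is the minimum of the five antecedent degrees
($A \wedge B = \min(A,B)$); per consequent, activations combine by
maximum. Implication is Mamdani *clipping*: each output trapezoid is capped
at its consequent's aggregate degree, and the two clipped curves combine by
pointwise maximum. The crisp score is the centroid (first moment over area)
of that curve.

Two independent defuzzification paths are provided:

* `defuzzify_centroid()` samples the curve on a regular grid (default step
  0.01 over [0, 10]) and integrates by the trapezoidal rule. The quadrature
  error at step 0.01 is below $10^{-4}$ on this geometry, comfortably inside
  the 2-decimal reporting precision.
* `centroid_oracle()` computes the exact polygon moment of the clipped
  trapezoid union in closed form (segment-wise
  $\int x\,\mu(x)\,dx$ on a piecewise-linear curve), with crossing points of
  the two clipped curves resolved analytically.

`assess()` always runs both and records a per-record `verification_value`
(1 when the rounded results agree), reproducing the manual verification
workflow. A configuration in which no rule fires raises an explicit error —
it cannot occur under the calibrated model, so it flags a broken custom
model rather than silently scoring 0.

## The AEQ sub-model

When a record arrives without an AEQ value, it is derived from the field
dose:

$$\text{concentration} = \frac{\text{dose} \times 0.99 \times 1000}{50{,}000},
  \qquad TU_{bee} = \frac{\text{concentration}}{LD50},
  \qquad AEQ = \frac{1}{TU_{bee}} .$$

0.99 is the fraction of an application that misses the target pests, and
50,000 a typical colony size. The factor 1000 is a unit calibration — with
doses in mL/ha and LD50 in µg/bee, the reference quotients are reproduced
only with this extra scale, so it is exposed as an overridable argument
(`unit_factor`) rather than hidden. Product volumes are taken as stated; no
active-ingredient fraction is modelled.

## A worked assessment

```{r assess}
records <- read_pesticide_table(
  system.file("extdata", "pesticides.csv", package = "beesafe"))
res <- assess(records, m, quiet = TRUE)
res
glance(res)
```

Dodine and iprodione top the ranking at 7.37 — both fire only Safe rules —
while the four compounds that are simultaneously highly bee-toxic, highly
contaminating and tightly residue-limited saturate the Not-Safe consequent
and floor at 2.63. DDT's half-life of 2000 days exceeds the 200-day
universe and is clamped (with a warning, visible in the trace); iprodione's
LD50 of 400 µg/bee is clamped likewise. The fired-rule trace explains every
score:

```{r trace}
tidy(res) |> filter(name == "Clofentezine")
```

## Numerical choices and degenerate inputs

* Scores are computed at step 0.01 and rounded half-up to 2 decimals for
  reports; the oracle path is exact. Acephate sits on a rounding boundary
  (analytic centroid 2.6443), so a ±0.02 band is the honest reproduction
  tolerance for 2-dp reference scores.
* Zero-width trapezoid edges (the left and right shoulders that coincide
  with the universe bounds) evaluate to degree 1 *at* the shared breakpoint,
  so shoulder categories stay saturated at the universe edges.
* Inputs outside a universe are clamped to the nearest bound and logged;
  missing values are a hard validation error ("there must be no empty data
  value" is a model precondition, not a warnable state).
* The crisp score is **not** pointwise monotone along a single-parameter
  degradation path: wherever two categories hand over, the aggregate degree
  dips below 1 and the clipped-consequent centroid shifts toward the
  universe middle before recovering. This is intrinsic to Mamdani centroid
  defuzzification, not a calibration artifact. The guarantee the model does
  make — and the suite asserts — is that no degraded configuration ever
  scores above the undegraded baseline, and that at the *rule* level
  worsening any antecedent never flips Not Safe to Safe.

## What the bundled study does and does not show

The ten-record panel exercises every code path: plateau and transition
memberships, both consequents, mixed activations, clamping, tie rules and
both defuzzification paths. It does not probe measurement noise, correlated
parameters, formulations with multiple active ingredients, or the
multi-residue extension of the AEQ (brood and population terms), all of
which are out of scope. The expert panel is two raters; the weight vector
is an input to the model, not an estimate with uncertainty. Problem sizes in
the test suite (1,000 random aggregate pairs for oracle agreement, 200-point
degradation sweeps, dense universe sweeps for coverage) were chosen so the
whole suite characterizes the model thoroughly while remaining quick to run.

## Known limitations

* The AEQ/LD50/MRL membership interiors are calibrated reconstructions;
  alternative shoulder choices that respect the same category boundaries
  would reproduce the saturated records equally well and differ only for
  compounds in the transition zones.
* The 0.5 rule threshold makes the consequent a step function of the
  weighted score; compounds near the threshold can flip under small weight
  revisions. Re-run `rule_base()` with updated `expert_weights()` to audit
  such sensitivity.
* Scores compress onto [2.63, 7.37] by construction; the scale's end points
  are properties of the output trapezoids, not attainable grades.
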