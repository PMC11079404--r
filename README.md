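# beesafe

Fuzzy decision support for scoring the environmental safety of pesticides,
with honey bees as the sentinel organism.

Farmers and regulators choosing among registered pesticides need a single,
comparable measure of how hazardous a compound is to the receiving
environment once residues accumulate. beesafe condenses five
ecotoxicological properties — soil half-life (days), the agroecology
environment quality quotient (AEQ, the reciprocal honey-bee toxic unit),
acute contact LD50 toward honey bees (µg/bee), a bee exposure-likelihood
score (0–4), and the maximum residue limit (mg/kg) — into a **safety level
point on a 0–10 scale** (higher is safer) with a Mamdani fuzzy inference
system.

## The model in brief

Each parameter is a linguistic variable with 2–3 categories described by
trapezoid/triangle or z/s membership functions. The rule base is not
hand-written: every category carries a code $p_i \in \{0, 0.5, 1\}$ (0 =
environmentally best) and every parameter a weight $w_i$ from a two-expert
panel (normalized per expert, then averaged; kept as exact fractions
7/30, 6/30, 7/30, 5/30, 5/30). All $3^3 \times 2^2 = 108$ category
combinations become rules via the weighted threshold

$$\text{Not Safe} \iff \textstyle\sum_i p_i w_i > 0.5,$$

ties Safe. Inference is min/max Mamdani with clipping implication;
defuzzification is the centroid of the aggregated output curve on [0, 10],
computed both by grid quadrature and by an exact closed-form polygon moment
(`centroid_oracle()`) that serves as a built-in verification path. The
attainable scores span [2.63, 7.37], the centroids of the two output
trapezoids.

When a record lacks an AEQ, it is derived from the field dose:
`concentration = dose × 0.99 × 1000 / 50000`, `TU_bee = concentration /
LD50`, `AEQ = 1 / TU_bee`.

## Worked example

```r
library(beesafe)

records <- read_pesticide_table(
  system.file("extdata", "pesticides.csv", package = "beesafe"))
res <- assess(records, quiet = TRUE)
res
#> # A tibble: 10 × 7
#>    name         safety_level_point score  safe not_safe oracle_score verification_value
#>  1 Dodine                     7.37  7.37 1        0             7.37                  1
#>  2 Iprodione                  7.37  7.37 1        0             7.37                  1
#>  3 Clofentezine               5.44  5.44 0.714    0.5           5.44                  1
#>  4 Fenthion                   2.93  2.93 0        0.61          2.93                  1
#>  5 DDT                        2.75  2.75 0        0.842         2.75                  1
#>  6 Acephate                   2.64  2.64 0        0.984         2.64                  1
#>  7 Abamectin                  2.63  2.63 0        1             2.63                  1
#>  8 Dimethoate                 2.63  2.63 0        1             2.63                  1
#>  9 Chlorpyrifos               2.63  2.63 0        1             2.63                  1
#> 10 Methidathion               2.63  2.63 0        1             2.63                  1
```

`safety_level_point` is the crisp centroid score rounded to 2 decimals;
`safe`/`not_safe` are the aggregate consequent degrees; `oracle_score` is
the closed-form centroid and `verification_value` is 1 when both
defuzzification paths agree at 2 decimals. Dodine and iprodione fire only
Safe rules and top the ranking; the four bottom compounds (highly bee-toxic,
highly contaminating, tightly residue-limited) saturate the Not-Safe
consequent. DDT's 2000-day half-life and iprodione's LD50 of 400 µg/bee
exceed their universes and are clamped with a warning (suppressed above).

`tidy(res)` returns the fired-rule trace behind each score, `glance(res)` a
one-line summary, and `autoplot(res)` / `autoplot(default_model())` the
standard plots. Custom models round-trip through YAML via `write_model()` /
`read_model()`.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/beesafe.R assess inst/extdata/pesticides.csv
Rscript inst/cli/beesafe.R rules --format csv     # the 108-rule base
Rscript inst/cli/beesafe.R verify inst/extdata/pesticides.csv --format csv
```

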