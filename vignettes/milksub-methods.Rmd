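---
title: "Methods: substitution modeling of milk products in young children's diets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: substitution modeling of milk products in young children's diets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milksub)
```

This vignette is the package's account of its own methods: the models
and conventions it implements, the parameters that matter, the design
decisions that were genuinely open, and what the synthetic-data
machinery does and does not emulate.

## 1. Intake computation and consumer classification

Daily intake is the standard linear food-composition sum: each recall
line contributes `amount/100` times the food's nutrient density per 100
units as consumed. The component set is fixed and closed — energy
(kcal), protein (g), vitamin A (µg RE), vitamin C (mg), vitamin D (µg),
folate (µg), calcium (mg), iron (mg), zinc (mg) — and all inputs must
already be expressed in these units; the package performs no silent unit
conversion, because EAR cut-points are only meaningful under fixed
units. Composition entries may be per 100 g or per 100 mL; conversion
between bases multiplies by the food's density (g/mL) and round-trips to
machine precision.

Milk-consumer groups must be mutually exclusive for group counts to sum
to the population, yet a recall can contain several milk types. The
package assigns the group by a **dominant-energy rule**: the milk type
contributing the most energy among the child's milk lines, with exact
ties broken in the fixed order ycm > cow > condensed. Any deterministic
rule would serve; this one is reproducible, favours the type that
dominates the child's milk consumption, and reduces to the obvious
answer for single-milk children. Only explicit milk-typed lines count:
condensed milk hidden inside mixed dishes is not attributed, since
recipe decomposition is out of scope.

## 2. The EAR cut-point method

Inadequacy prevalence is the percentage of children whose intake falls
**strictly below** the estimated average requirement of their own age
band (12–35, 36–47, 48–60 months). Strictness follows from "below the
reference value"; for continuous intakes the boundary has probability
zero, so the choice is a convention, not a modeling decision. When an
analysis group pools two reference bands (the 36–60 month modeling
group spans the 36–47 and 48–60 month cut-points), each child is judged
against their own band and a single pooled prevalence is reported —
the only reading consistent with one prevalence column alongside two
reference columns. Vitamin C is tracked in intakes but has no bundled
cut-point; evaluating it requires a user-supplied reference row, with no
default.

Because the design uses one recall day per child, the intake
distribution mixes within- and between-person variance; the cut-point
prevalence therefore describes single-day intakes and is biased (usually
upward in the tails) relative to usual-intake inadequacy. The package
reproduces this single-day design deliberately and implements no
deattenuation.

## 3. Substitution scenarios

A scenario is (target milk, replacement profiles, mode). Substitution is
applied **per line**: every target-milk line becomes a replacement line;
by linearity of the intake sum this is equivalent to substituting daily
totals, and it preserves line-level structure. Replacement profiles are
per-100-mL as-consumed entries, chosen by modeling age group (a "1+"
product below 36 months, "3+" from 36 months). Young-child milks are
sold as powder, so `reconstitute_powder()` maps a per-100-g powder
profile plus the label reconstitution rate to an as-consumed profile;
condensed milk is likewise interpreted on an as-consumed (post-dilution)
basis, because recalls record consumed portions.

Equal-volume mode keeps the consumed millilitres; isocaloric mode
multiplies the volume by the ratio of energy densities so each line's
energy is conserved exactly (to floating-point rounding; the test suite
asserts 1e-9 relative per child). Three structural properties follow
and are property-tested: equal-volume conserves each child's total milk
volume; children without target milk are returned bit-identical;
self-substitution is the identity. A replacement that dominates the
target componentwise per mL can only raise intakes under equal volume,
hence can only lower prevalences — the monotonicity the test suite
checks.

## 4. Statistical layer

* **Fisher's exact test** (2×2, two-sided) sums hypergeometric
  probabilities of all tables, with fixed margins, whose probability
  does not exceed the observed table's (probability-mass rule, with a
  1e-7 relative guard against floating-point ties). The doubling rule
  would give different values; the convention is documented because the
  choice matters. The suite cross-checks every table of grand total ≤ 30
  against direct enumeration from binomial coefficients.
* **Wilcoxon signed-rank** compares paired baseline/scenario intakes.
  Zero differences are dropped (Wilcoxon's convention), absolute
  differences are ranked with midranks for ties. Up to `exact_limit`
  (default 25) non-zero pairs, the exact two-sided p-value is computed
  from the null distribution of the rank sum built by generating-function
  convolution (ranks doubled so midrank halves stay integral); the
  distribution is symmetric under sign flips even with ties, so the
  two-sided p is the mass at least as far from the mean as observed.
  Beyond the limit, a normal approximation with the general
  tie-corrected variance `sum(r_i^2)/4` is used, without continuity
  correction. The suite cross-checks small cases against full 2^m
  sign-assignment enumeration and tie-free cases against the classical
  exact distribution.
* **Chi-square** for r×c characteristic tables is Pearson's statistic
  without continuity correction — a uniform rule, since most tables are
  larger than 2×2.
* **Bonferroni** adjustment multiplies by an explicit family size m and
  caps at 1. For the group-comparison table the default family is m = 2
  (the two comparator groups per nutrient per age band); the family size
  is surfaced in the report rather than hidden, because the appropriate
  family is a judgment call.
* The per-scenario Wilcoxon tests treat each scenario against baseline
  separately, matching the paired table layout.

Relative reductions are reported unrounded, together with a
**round-half-up** integer percent (base R's `round()` is
round-half-even, which would turn 30.95 into 31 but 23.5 into 24 vs 23
inconsistently with how such summaries are usually printed).

## 5. The synthetic survey generator

No microdata ship with the package; the generator emulates the
*structure* of a large one-day national dietary survey of children aged
12–60 months so that the pipeline can be exercised and calibrated at
realistic scale.

What it models:

* **Covariates** — age bands (~23/24/26/27% across 12–23, 24–35, 36–47,
  48–60 months, uniform months within band), sex (51.7% boys), region
  (42.9% urban), SES (59/34/7% low/middle/high) and 7-level maternal
  education, drawn independently per child from configurable categorical
  tables.
* **Milk groups** — P(group | age band) over non-milk/YCM/condensed/cow,
  defaulting to the published age-specific shares (e.g. 57.7% YCM at
  36–47 months, with roughly half of children consuming no milk in most
  bands).
* **Background diet** — per nutrient and modeling group, an independent
  log-normal intake with an optional zero point mass. Right-skewed
  single-day intakes are standard; zero inflation is the minimal
  mechanism reproducing a zero 25th percentile with a small positive
  median, as the vitamin D targets require (default `p_zero = 0.3`).
  Log-scale SDs are fixed from the spread of the published baseline
  quartiles; locations are set analytically and then calibrated (below).
  The background diet enters the recall as one line per single-nutrient
  pseudo-food (`BG_*`, 100 units per 100 g, so the line amount equals
  the drawn intake) — a deliberately transparent device, not an attempt
  at a food list.
* **Milk portions** — log-normal daily volume per milk type (defaults:
  median 250 mL, sdlog 0.6 for condensed; 300/0.5 for YCM; 250/0.5 for
  cow). Consumed volumes are not published; these are single fixed
  choices at the level of one to two cups per day, stated here and not
  revisited.
* **Seeding** — child i draws from streams seeded by
  `(root*69069 + 8i + offset) mod (2^31 - 1)`, so identical
  (config, seed) reproduce the survey exactly and growing n leaves
  earlier children untouched.

What it does **not** model, hence what passing tests do not show about
real data: correlations between nutrients (a copula hook is left
unimplemented — no correlation information is available to fit it),
covariate–milk-group association (covariates are independent of group,
so the generator does not reproduce chi-square significance patterns in
characteristics tables), the extreme upper tail of fortified-food
nutrient intakes (published baseline means for iron vastly exceed the
median, implying rare extreme values; a single log-normal matched to
quartiles and prevalence deliberately ignores that tail, which does not
affect cut-point prevalences), household clustering, and day-to-day
within-person variance.

### Calibration

`calibrate_to_baseline()` tunes the log-scale location µ of each
targeted nutrient so that simulated baseline inadequacy among
condensed-milk consumers matches a target prevalence. For each modeling
group one set of common random numbers (ages, milk volumes, background
normals and uniforms) is drawn from the seed at the calibration size;
prevalence is then a deterministic, monotone non-increasing function of
µ, and 60 bisection steps pin it to machine precision. Targets a
bisection cannot reach (e.g. prevalence 0 for a zero-inflated nutrient
whose milk contribution sits below the cut-point) raise a calibration
failure naming the unmet targets. The tolerance for declaring success is
±3 prevalence points at the default calibration size n = 5,000 — Monte
Carlo error at that size is ~0.6 points at p = 0.8, so the tolerance is
dominated by transfer error to fresh samples, which the test suite
measures by regenerating independent populations through the full
per-child recall generator (parameter recovery).

### Bundled profiles

The composition table bundled for simulation and tests is **synthetic**
(`composition_synthetic.csv`): commercial product compositions are not
public inputs, so the condensed-milk and young-child-milk profiles were
fixed once at label-plausible values consistent with the intake shifts
the bundled calibration targets describe — e.g. condensed milk as a
~70 kcal/100 mL beverage poor in iron (0.07 mg/100 mL) and vitamin D,
YCM profiles fortified at ~1–2 mg iron and ~2–3 µg vitamin D per 100 mL,
with energy densities close to condensed milk's so the two scenario
modes give similar results, as they should for near-isocaloric products.
Analyses of real data must supply a real composition table.

## 6. Numerical conventions and problem sizes

Quantiles use linear interpolation between order statistics (R type 7);
the sample SD uses the n−1 denominator and is defined as 0 for a single
observation; empty populations and empty intake distributions are
errors, not NA. Probability tables must sum to 1 within 1e-9.
Degenerate paired samples (all differences zero) return p = 1 with an
explicit flag. The default test suite exercises populations of a few
hundred to ~11,000 children and calibration/verification samples of
5,000, sizes at which group-level Monte Carlo error is small relative to
every stated tolerance while the whole suite runs in well under a
minute per file.

## 7. Known limitations

Single-day EAR cut-point bias (section 2); no survey weights (the
emulated analysis reported unweighted tests); no confounder adjustment —
group differences in SES, region and maternal education mean baseline
group comparisons are descriptive, not causal; the energy/protein
adequacy classification of the emulated survey is not public, so
`energy_protein_status()` is an explicitly approximate
fraction-of-requirement rule; and modeled substitution describes a
theoretical nutrient-supply impact, not behaviour, cost or
acceptability.
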