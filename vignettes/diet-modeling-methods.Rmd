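---
title: "Methods: free-sugar diet modeling by linear programming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-sugar diet modeling by linear programming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and of the design
choices that were genuinely open: what is computed, under which assumptions,
with which defaults, and what the synthetic-data results do and do not say
about real survey data.

## Free sugars and the study design

Free sugars are the mono- and disaccharides added to foods by the
manufacturer, cook or consumer, plus the sugars naturally present in honey,
syrups, fruit juices and concentrates (the WHO definition). Intrinsic
(non-free) sugars — those inside whole fruit, or lactose in plain milk —
are total sugars minus free sugars. The analysis pipeline classifies adults
from a 7-day food diary into **FS-ACCEPTABLE** (free-sugar energy share
≤ 10%) and **FS-EXCESS** (> 10%), compares their diets, and then asks the
individual diet model what minimal changes would bring each diet into
compliance with a full nutrient panel at unchanged energy.

The energy share uses the Atwater factor 4 kcal/g for sugars throughout;
the classification boundary is inclusive on the acceptable side (a share of
exactly 10% is acceptable). Alcoholic beverages are excluded from diet
vectors and from the optimizable energy: nutrient recommendations apply to
non-alcoholic intakes, and alcohol cannot sensibly be "optimized".

## Free-sugar annotation of the composition table

Foods are annotated by rule class, mirroring how a national table is
completed in practice:

* `sugars_equal_free` — beverages (including water, trivially), honey,
  syrups: free sugars equal total sugars.
* `recipe` — composite foods: free sugars are the summed recipe weights of
  assimilated sugar ingredients times their converting factors. The two
  anchoring factors are 1.0 for white sugar and 0.8 for honey; syrup (0.8)
  and fruit-juice-concentrate (1.0) factors are shipped defaults flagged as
  configurable, since only the two anchors are documented.
* `expert_zero` / `expert_value` — mono-ingredient foods and expert
  estimates. Expert estimates are always explicit per-food inputs, never
  inferred.

The invariant `0 ≤ free ≤ total sugars` is enforced by clipping with a
warning; `starch + sugars ≤ carbohydrate × 1.02` and the taxonomy mapping
(every food in exactly one of the 33 leaf sub-categories over 9 categories)
are hard validation errors. The energy-free-drink flag (beverage with
< 4 kcal/100 mL) treats 100 mL as 100 g; for the watery drinks concerned,
density 1 is accurate to well under the nutritional noise.

## Diet quality indicators

* **SED** — energy of solid foods over their weight (kcal/100 g); soups are
  solid, anything typically drunk (water, milk, juices, soft drinks) is not.
* **Variety** — distinct foods over the 7 days; water counts by default
  (configurable), alcoholic drinks do not.
* **MAR** — mean over 23 nutrients of percent of recommended intake, capped
  at 100; weekly mean intakes (mean of the 7 diary days) enter the ratio.
* **MER** — mean percent exceedance above the maxima for sodium, saturated
  fatty acids and sugars; values below a maximum contribute 0, so MER ≥ 0
  and 0 means "no excess". The phrase "(minus 100%)" in the index's verbal
  definition is ambiguous; the truncated reading was chosen because an
  excess indicator should not reward margins below the ceiling. The sugars
  term uses **free** sugars against the 10%-energy reference by default
  (configurable to another basis), which is what separates the FS groups.
* **PANDiet** — 100 × (adequacy + moderation)/2, where each sub-score
  averages Gaussian probabilities of adequate usual intake over 22 adequacy
  and 3 moderation nutrients. The probability for an adequacy nutrient is
  Φ((x̄ − EAR)/√((cv·EAR)² + s²w/7)), with s²w the within-person variance
  of the 7 daily intakes; moderation mirrors it below the reference.
  Requirement CVs default to 15% (25% for vitamin D, 20% for iron and
  iodine). Degenerate case: zero total variance with the mean exactly at
  threshold gives probability 0.5 by symmetry.

The 23-MAR / 25-PANDiet nutrient lists and all reference values live in
`inst/extdata/nutrient_references.yaml`. They are a **reconstruction** from
French adult reference values, sex-averaged into a single table; the YAML
is the contract and the lists are data, so a user with the original
appendix can substitute it without touching code.

## The individual diet model

For an individual with observed diet $o_f$ (g/day, non-alcoholic foods),
the LP minimizes

$$\sum_{f \in \text{repertoire}} \frac{w^+ d^+_f + w^- d^-_f}{o_f}
  \;+\; \pi \sum_{f \notin \text{repertoire}} \frac{q_f}{m_f},
\qquad q_f = o_f + d^+_f - d^-_f,\; d^\pm_f \ge 0,$$

which encodes the model's three aims: prefer repertoire foods, penalize
reductions more than additions ($w^- \ge w^+$), and control non-repertoire
entries (scaled by $m_f$, the population mean among consumers, which is
also their cap; foods never consumed in the population are not variables).
Defaults $w^+ = 1$, $w^- = 2$, $\pi = 5$ are config-exposed; the package's
acceptance properties hold across a grid of these weights because they
follow from the constraint structure, not the weights.

Constraints:

* **Iso-energy** equality at the observed non-alcoholic energy.
* **33 nutrient rows**: protein 10–20%E, fat 30–40%E, carbohydrate
  45–60%E, fiber ≥ 25 g, SFA ≤ 12%E, cholesterol ≤ 300 mg, sodium
  ≤ 3150 mg, the conditional free-sugar row, and 22 micronutrient minima at
  the reference intakes. Percent-energy bounds are rewritten as linear rows
  using the individual's fixed energy target (9 kcal/g for fats, 4 kcal/g
  otherwise).
* **Conditional free-sugar rule**: if the observed share exceeds 10%E the
  bound is 10%E (in grams, 0.10·E/4); otherwise the observed gram amount
  (no increase).
* **Acceptability**: per-food and per-sub-category maxima at the 95th
  percentile of consumption among consumers. Two adjustments keep the
  individual's own diet admissible and the model meaningful across the
  energy range: bounds are relaxed to the observed value where the
  individual already exceeds them, and caps scale with
  $\max(1, E_i/\bar E)$ — population portion ceilings refer to the mean
  energy level, and an iso-energy model for a 3000-kcal individual must be
  allowed proportionally larger amounts (without this, high-energy
  individuals are spuriously infeasible).
* **Total diet weight** (energy-free drinks excluded, to avoid competition
  between water and nutrient-dense food) ≤ 1.3 × observed, and **total
  cost** ≤ 1.1 × observed. The bounds are not documented in the source
  study; ×1.0 was considered and rejected because the published optimized
  diets themselves weigh ~10% more than the observed ones (fruit and
  starchy foods are less energy-dense than what they replace), so an
  equality-tight weight bound contradicts the solutions the method is known
  to produce.

### Solver and duals

No installed R package provides an LP solver with dual values, so the
package carries a bounded-variable two-phase primal simplex written for
this purpose: nonbasic variables rest at either bound, entering steps may
end in bound flips, Dantzig pricing with a Bland anti-cycling fallback,
row scaling for balance. Duals are read off the final basis
($y = c_B B^{-1}$) and reported as ∂(objective)/∂(bound). The solver is
validated against an independent brute-force vertex-enumeration oracle on
hundreds of random instances, against finite-difference sensitivities for
the duals, and (where the form allows) against `pracma::linprog`; every
accepted solution is re-verified against all rows at tolerance 1e-8 before
being returned, and a verification failure is a distinct `solver_error`
status, never a silent partial diet. A constraint counts as *binding* when
|dual| > 1e-6; at degenerate optima the reported dual is one valid
subgradient of the (convex, piecewise-linear) value function, which is why
the test suite brackets duals between one-sided finite-difference slopes
rather than equating them.

Infeasible individuals are reported as such and excluded from downstream
summaries, mirroring how survey respondents without a mathematically
feasible diet are dropped from an analysis sample.

## The synthetic survey generator

The generator's defaults are the documented study conditions, not tuning
knobs: mixture weight 0.41 for FS-EXCESS; free-sugar shares 6.3 ± 2.5 %E
(ACCEPTABLE) and 14.2 ± 4.2 %E (EXCESS); energies 2123 ± 539 and
2192 ± 529 kcal/day; snacking energies 131 ± 154 and 258 ± 220 kcal/day.
Distributional choices that the published moments force:

* The group statistics are conditional on the 10% threshold, so the
  ACCEPTABLE share is drawn from a normal truncated to (1, 10] whose
  *underlying* parameters are solved (deterministic moment matching) so the
  truncated distribution has exactly the stated mean and SD. Naively
  truncating N(6.3, 2.5) would bias the realized mean upward.
* A lower-truncated normal above 10 cannot have SD equal to its mean excess
  (its CV is strictly below 1), so the EXCESS share is 10 + Gamma with
  mean 4.2 and SD 4.2 — an exponential-like tail, which also matches the
  right-skew of high sugar consumers.
* Snacking energy has SD > mean, also unreachable by a truncated normal;
  it is Gamma with the stated moments (mass near zero matches the ~quarter
  of respondents who report never snacking).

Each individual's diary is realized in four steps: (1) leaf sub-category
amounts from independent Gamma draws centred on survey-magnitude group
means (a scaled-Dirichlet-style allocation; the induced between-category
correlation is the Dirichlet one, since the true correlations are
unpublished); (2) a joint rescaling of the sweet and non-sweet pools — a
2×2 linear solve — so the computed diary hits the drawn energy and FS share
*exactly*, which makes ground-truth labels recoverable by construction;
(3) greedy assignment of snack-eligible foods to snacking moments until the
drawn snacking energy is met (the boundary food split fractionally);
(4) Dirichlet day-weights spreading each food over the 7 days, preserving
weekly means exactly while creating the day-to-day variance PANDiet needs.

The synthetic food table covers all 33 leaves with macro profiles of
composition-table magnitude and energy consistent with the macros (4/9/4).
Micronutrient densities follow per-group richness patterns (fruit/vegetable
vitamin C and folate; fish vitamin D, B12, iodine, selenium; dairy calcium
and riboflavin; meat iron, zinc, B-vitamins; wholegrain magnesium and
thiamin; oils vitamin E), including the ultra-dense offal and shellfish
items every real table contains — without them, low-energy individuals
cannot reach absolute micronutrient minima and the feasibility rate
collapses, which is a table artifact rather than a property of the method.

**What passing tests show, and what they do not.** The generator reproduces
the two-group free-sugar structure, the energy and snacking moments, and
the broad category amounts; diaries are day-balanced and moment-assigned by
simple affinity rules. It does **not** emulate food-to-food correlations
beyond the category allocation, seasonal or weekday effects, portion-size
quantization, under-reporting (diaries are generated at their true energy),
or the sociodemographic joint distribution. Results on synthetic data
therefore validate the *machinery* (scores, LP, duals, reporting
identities) and the generator's own parameter recovery — they are not
re-estimates of the published population values.

## Problem sizes and numerical choices

The shipped analysis scripts simulate 1693 individuals over a 100-food
table (the surveyed cohort size); the test suite exercises the
end-to-end pipeline at n = 500 with the same table size and solver
settings, a size chosen so the whole suite stays comfortably inside a
development test cycle while leaving every constraint of the full model
active. Solver feasibility tolerance is 1e-8 (scaled rows), binding
threshold 1e-6, deterministic behavior under fixed input ordering (no
randomized pivoting). Survey weights are lognormal, normalized to mean 1
(the true weight distribution is unpublished); weighted SDs use the
frequency-style normalization that reduces to the n−1 sample SD under
equal weights.

## Known limitations

* The 33-constraint panel, nutrient lists and Goldberg constants are
  reconstructions from French reference values; users with the original
  appendix should replace the YAML files.
* Single sex-averaged reference table (no age/sex-specific interpolation).
* The objective's functional form (relative absolute deviations with
  asymmetric weights plus a scaled non-repertoire penalty) reconstructs the
  three stated aims of the original individual diet models; the original
  SAS implementation is not public, so coefficient-level agreement cannot
  be claimed.
* Moment-of-consumption-aware optimization and portion-based (integer)
  modeling are out of scope.
* Variety in synthetic diaries (~40 foods/week) runs below survey
  magnitude (~58) because the table holds 100 foods rather than 1314;
  variety-dependent conclusions should be read accordingly.
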