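---
title: "Water footprint accounting for recommended dietary patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water footprint accounting for recommended dietary patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietwf)
```

## The accounting model

The water footprint (WF) of a food is the freshwater volume used to produce
it over its full supply chain, split into three components: green (rainwater
evapotranspired), blue (surface and groundwater consumed), and grey (the
volume needed to assimilate pollutant loads). Food-level WFs are expressed
in L per kg of *production* weight — the raw product as it leaves
agriculture.

A national food-based dietary guideline (FBDG) pattern is a list of food
categories, each with a serving size in g of *edible* weight and a
suggested consumption frequency. The weekly WF of a pattern is

$$ WF_{week} = \sum_{c} \frac{m_c}{1000} \cdot wf_c, $$

where $m_c$ is the weekly consumption of category $c$ in g of production
weight and $wf_c$ its WF in L/kg, computed componentwise for green, blue,
and grey. The per-capita daily WF is the weekly total divided by 7; the
component shares are each component over the total; and group contributions
are the summed entry totals of a partition (animal/plant/other, or coarser
food groups) over the pattern total.

Between the guideline text and this sum sit the conversion rules this
package implements explicitly:

* **Edible to production weight** (`edible_to_production()`): serving sizes
  are edible weights, WF databases price production weight; the edible
  fraction in (0, 1] divides the mass.
* **Group averaging** (`group_wf()`): when a guideline names member foods
  without individual frequencies, the group WF/kg is a mean over members —
  unweighted, consumption-share weighted, or *serving weighted*. The
  serving-weighted rule is defined as the mean per-serving WF divided by
  the mean serving mass. The guideline text only says servings were
  "averaged considering the serving sizes"; this definition is the unique
  reading that keeps the result in L/kg and collapses to the simple mean
  when serving masses are equal (cup-equivalent dairy: 244 g milk, 43 g
  natural cheese, 57 g processed cheese). It is isolated in one function so
  it can be swapped.
* **Cooked to dry legume mass** (`cooked_to_dry_mass()`): WFs price dried
  pulses; cooked serving masses are divided by a swelling factor of 2.5.
* **Aquaculture share of seafood** (`effective_seafood_mass()`): wild-caught
  fish carries 0 L/kg, and half of consumption is assumed farmed. The
  discount halves the *mass charged*, not the WF/kg, because resolved
  pattern tables keep the full aquaculture WF/kg (987 L/kg) next to a
  halved g/week.
* **Composite foods** (`jam_wf()`): jam is 35 % fruit and 40 % sugar by
  mass; its WF is the corresponding linear combination.
* **Min/max averaging and energy rescaling** (`average_min_max()`,
  `rescale_to_energy()`): guidelines stating serving ranges are resolved as
  the categorywise mean of a minimum and a maximum pattern, then all
  servings are multiplied by one common factor so the pattern supplies a
  target energy (2000 kcal/day by default). Rescaling is uniform across
  *all* entries, indulgence foods included — the guidelines give no reason
  to exempt them — and therefore preserves serving ratios exactly.

All four constants (2.5, 0.5, 0.35, 0.40) live in `wf_constants()` and are
arguments everywhere they are used.

### Classification

Contribution analyses split entries into **animal** (meat, poultry, eggs,
seafood, dairy), **other** (discretionary/indulgence items: sugar, jam,
alcohol, the US "limit on calories" allowance), and **plant** (everything
else). Two assignments deserve emphasis because they are forced by the
published group percentages rather than by intuition: butter is carried on
the *plant* side, riding with the oils/fats group, and nuts ride with the
fruit-and-vegetables food group in all three patterns (the Italian table
groups them so, and the US and Spanish fruit-and-vegetable contribution
percentages are reproducible only under the same assignment).
`classify_entry()` refuses unmapped categories rather than defaulting.

## The packaged guideline patterns

The Italian, US, and Spanish 2000 kcal/day patterns ship as CSV fixtures
(`inst/extdata/fixture_*.csv`) mirroring the published table layout cell by
cell, so they can be diffed against the source. The loader
(`load_fixture()`) resolves entries from the printed *weekly* WF cells,
which are the authoritative published results, for two reasons found by
checking every row:

1. For several grouped rows the weekly cells are **not** `g/week x printed
   WF/kg`, because the underlying computation was serving-weighted per
   member food while the printed WF/kg column is a simple mean (US dairy,
   meat, fruit, nuts and "limit on calories"; Spanish cereals, dairy and
   wine/beer).
2. For a few rows the printed green/blue/grey cells do not sum to the
   printed row total (Italian butter, croissants, biscuits; Spanish
   vegetables), and the grand totals of the source tables sum the row
   *totals*, not the component columns.

The loader therefore reconciles components proportionally to each printed
row total and derives an *effective* WF/kg as weekly WF over weekly
production mass. Every row needing reconciliation carries a `note` in the
CSV. Three cells are carried with explicit flags: the Spanish egg row's
weekly cells (printed identical to its WF/kg cells), the Spanish sugar
g/week (the printed 1668 g contradicts its own weekly WF; the serving
arithmetic 52.5 g is used), and the Spanish wine/beer weekly cells. The
printed jam WF/kg (1277/416/321) is likewise carried verbatim: it is not
reproducible from the 35 %/40 % composition rule with any fruit or sugar
WF printed alongside it, so `jam_wf()` remains a generic rule and the
fixture keeps the published value.

Published serving counts are rounded after the energy rescale, so the
edible mass they imply can exceed the printed production mass by a few
percent (Spanish nuts: 25 g x 4 = 100 g against 95 g/week). Pattern
validation takes a `mass_tol` argument (strict 0 by default); the fixture
loader passes 0.06.

With this resolution the package reproduces, from the fixtures alone, the
published weekly totals within ±3 L (19,645 / 21,440 / 21,958 L/week for
Italy, the USA, and Spain), the per-capita totals within ±1 L/day
(2806 / 3062 / 3137), all component shares and group contributions within
±1 percentage point, and the dairy (3943 vs 5724 L/week) and olive-oil
(+2421 L/week) contrasts — exactly what `tests/testthat/test-acceptance.R`
asserts and `scripts/acceptance.R` recomputes.

## Substitution scenarios

`delta_equal_mass()` computes `(mass/1000) * (wf_remove - wf_add)`;
`delta_equal_protein()` chooses the removed mass to match the protein of
the added mass; `apply_swap()` edits a pattern and returns the delta, which
always equals a full recomputation (a property the suite checks on 1000
random synthetic swaps). Positive totals mean water saved.

One caution for users reproducing published what-if numbers: deltas quoted
in prose are often not derivable from the printed per-kg values because the
meat mix or protein densities behind them are unstated. For example,
replacing 400 g of the US meat group (7248 L/kg) with dairy (3713 L/kg)
gives `0.4 x (7248 - 3713) = 1414` L/week by equal-mass arithmetic — not
the 3121 L/week quoted alongside the same tables. This package asserts only
the olive-oil contrast (+2421 L/week), which is exactly derivable from the
two oil entries; the others are left as documented reconstructions with a
residual gap.

```{r evo}
spain <- load_fixture("spain")
italy <- load_fixture("italy")
evo <- spain$entries[spain$entries$category == "Extra virgin olive oil", ]
oil <- italy$entries[italy$entries$category == "Vegetable oil", ]
wf_total(entry_weekly_wf(evo)) - wf_total(entry_weekly_wf(oil))
```

## The synthetic-data generator

`gen_food_db()` draws per-kg total WFs from a log-normal
(`meanlog = log(1500)`, `sdlog = 1`, spanning roughly the 270–15,400 L/kg
range of real food categories) and splits them green/blue/grey with a
Dirichlet(7.7, 1.2, 1.1), whose mean green share of 0.77 matches the
75–80 % observed across the three patterns. Edible fractions are uniform
on (0.7, 1], energy densities on 20–600 kcal/100 g, protein on
0–30 g/100 g — realistic whole-food ranges. `gen_pattern()` draws serving
sizes of 5–250 g and servings/week in 0.4–24, the ranges the published
patterns span, and emits a resolved pattern plus a min/max pair for
exercising the averaging and rescaling path. All draws are reproducible
from the `seed` in `synth_config()` and leave the caller's RNG stream
untouched.

What the generator does *not* emulate: correlations between footprint and
energy density, country-specific food composition, seasonal or regional WF
variation, and food waste (deliberately excluded from the accounting).
Passing tests on synthetic data therefore demonstrate the arithmetic and
its invariants, not the realism of any particular national pattern — that
is what the fixtures are for.

## Numerical choices

* Full precision everywhere; rounding (half away from zero, the convention
  of the published tables) happens only in `render_table()`.
* Component shares and contribution fractions must sum to 1 within 1e-9;
  a zero-footprint pattern has no shares and `component_shares()` says so.
* Test problem sizes: patterns of 5–25 categories, food databases of up to
  1000 foods for the Dirichlet calibration check, and 1000 random swaps for
  the incremental-vs-recompute property — small enough to run in seconds,
  large enough to exercise every branch.
* Weekly-cell tolerances in the fixture tests are ±1 L on row totals
  (exact by construction after reconciliation), ±2 L on unflagged component
  cells (printed-cell rounding), ±3 L on pattern totals, and ±1 percentage
  point on published percentages.

## Limitations

* The fixture WF/kg values are taken as given from the published tables;
  the package does not re-derive them from the upstream global WF
  databases, and inherits any inconsistencies the reconciliation rule
  cannot see (only rows whose own cells disagree are detectable).
* Food waste is not modelled; published per-capita WFs that include waste
  will be higher.
* Single swaps and scripted sequences only; no diet optimisation.
* Energy is the only nutritional dimension used for rescaling, and protein
  the only one for substitution equivalence.
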