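---
title: "Farm-to-fork nutrient accounting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Farm-to-fork nutrient accounting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbsr)
```

This vignette documents the accounting model `nbsr` implements, the
parameters that matter, the synthetic-data generator used for verification,
and the design decisions taken where the methodology leaves genuine freedom.

## The accounting model

A food balance sheet records annual quantities (1000 metric tonnes) for each
food category and *element* — production, imports, exports, feed, seed,
losses, food, and so on. The `food` element is availability for human
consumption, which after loss adjustments we call *apparent intake*: it is a
supply-side construct, not measured individual intake.

Per-capita conversion uses a fixed 365-day year (the leap-day error of
~0.07% is far below the uncertainty of any input):

$$g/\text{person/day} = \frac{Q \times 10^9}{365\,N}.$$

Each flow then passes through the multiplicative identity

$$\text{nutrient/day} = g/\text{day}\times(1-\text{refuse})\times
  r_\text{proc}\times\frac{\text{composition}}{100\,g}\times
  r_\text{FLW}\times r_\text{cook},$$

with four variants controlling which factors are active:

| variant | processing | FLW + cooking |
|---|---|---|
| `raw` | — | — |
| `processing_only` | yes | — |
| `flw_cooking_only` | — | yes |
| `final_best` | yes | yes |

`final_best` is the recommended apparent-intake estimate; `processing_only`
is the closest match to agency availability statistics that include milling
but not waste. Because every factor is multiplicative and at most 1 (aside
from dilution factors, which act on mass, not nutrients), `final_best` never
exceeds `processing_only` — a property the test suite checks on random
inputs, along with degree-1 homogeneity in the quantity.

**Cereal milling.** Wheat, maize, sorghum and millet are consumed mainly as
flour. A regional specification gives the share of grain milled refined
versus whole, and extraction rates convert grain mass to flour mass: 0.72
for straight-grade wheat flour, 0.70 refined maize, 0.74 refined millet,
0.79 refined sorghum, and 1.00 for whole-grain flours. The two flour streams
carry their own composition records (`<fc>_refined`, `<fc>_whole`); total
cereal consumption is the sum of the streams. Dividing each stream by its
extraction rate recovers the grain mass exactly (tested).

**Commodity processing factors.** Some primary commodities are consumed in
transformed mass: tea leaves brew into ~119.05 g of beverage per gram of
leaf, sugar cane yields 0.11 g sugar per gram of cane, cocoa 0.82. Factors
above 1 represent dilution, below 1 extraction.

**Food loss and waste.** Regional FLW fractions apply per subgroup at up to
three stages — post-harvest (fish and seafood only), retail, and
consumption — combined as $(1-l_1)(1-l_2)(1-l_3)$. Subgroups without
credible FLW estimates (sugar crops and sweeteners, pulses, tree nuts,
vegetable oils, stimulants, spices, alcohol, animal fats, infant foods) are
exempt and use retention 1. FLW and cooking retention are applied to the
`food` element only: the `losses` element already reports farm-to-retail
losses in the source accounts, and applying survey-based FLW to non-food
elements would risk double counting. This is a deliberate, documented
interpretation of an ambiguity in the source methodology.

**Composition overrides.** Overrides are configuration
(`inst/extdata/composition_rules.yaml`), not code. Two rules ship by
default: palm oil retained for domestic consumption in tropical rain-belt
Sub-Saharan African countries is blended 70% unrefined red palm oil
(carotenoid-rich, hence high vitamin A) and 30% refined, while exports and
imports are always refined; and rice in Bangladesh uses the parboiled,
polished white record. The tropical-belt membership list is editable config
because no canonical enumeration exists.

**Missing composition values** are imputed at their lower bound of zero and
the affected cells are flagged (`imputed_cells()`), so uncertainty analyses
can exclude them. Categories absent from the phytate table default to
phytate 0; tea is the only polyphenol carrier, valued as a single
tannic-acid-equivalent figure.

**Aggregation.** The production side excludes categories that are processed
forms of other flows (vegetable oils, alcohol, butter, cream, fish oils) to
avoid double counting; the intake side sums the `food` element over all
categories.

## Mineral bioavailability

Iron in heme-source foods (meat, fish, poultry) is split 40% heme / 60%
non-heme; heme iron is absorbed at a fixed 25%. Non-heme absorption is
predicted from the whole-diet profile by one of three algorithms, selected
by name and parameterized entirely from
`inst/extdata/absorption_params.yaml`:

* `conway` — a linear food-group regression on vitamin C, meat+fish+poultry
  (MFP), phytate and calcium;
* `rickard` (default) — a log-linear test-meal model with `log1p` terms for
  enhancers (vitamin C, MFP) and inhibitors (phytate, polyphenols,
  calcium);
* `armah` — a complete-diet log-linear model that additionally conditions
  on iron status through serum ferritin, fixed at the reference value 21.7
  µg/L corresponding to 40% reference-dose absorption (national accounting
  has no individual iron status).

Predicted fractions are clamped to (0.001, 1). All three satisfy a shared
contract — bounded, never increasing in phytate, never decreasing in
vitamin C — enforced by a property suite that runs regardless of the
coefficients in the file. The file carries citation strings and its md5
checksum is recorded in every run manifest. `rickard` is the default for
downstream adequacy and fortification because the test-meal model is the
conventional choice for bioavailable-iron mapping; the other two are
reported side by side in `bioavailable_minerals()`.

MFP grams enter the algorithms as edible, post-loss mass
(`g × (1−refuse) × FLW retention`): absorption enhancers act on food as
eaten, not as purchased. The heme split is computed on the `final_best`
variant; because all adjustments are multiplicative, the ordering of split
and adjustment is immaterial.

Absorbed zinc (TAZ) uses the saturable, phytate-inhibited trivariate model
in mmol/day,

$$TAZ = \tfrac12\left(A - \sqrt{A^2 - 4\,A_{max}\,TDZ}\right),\qquad
  A = A_{max} + TDZ + K_r\!\left(1+\frac{TDP}{K_p}\right),$$

with the updated constants $A_{max}=0.091$, $K_r=0.033$, $K_p=0.680$
mmol/day and molar masses 65.38 (Zn) and 660.04 (phytate) g/mol. TAZ is
bounded by both $A_{max}$ and intake, increases in zinc, decreases in
phytate, and saturates at $A_{max}$ — each verified against an independent
numeric root of the underlying binding equation.

## Weighted requirements

The requirement database crosses one-year age-sex population counts with
reference values. Standards follow a preference order: average requirement
(AR), else adequate intake (AI); iron and zinc additionally carry
absorbed-basis ("physiological") standards used whenever supplies are
bioavailability-adjusted — comparing absorbed supply with an ingested
requirement would be incoherent. Protein-type values specified per kg body
weight are expanded with reference body weights before weighting. Energy
requirements are taken at the minimum physical activity level.

Pregnant women are estimated by duration-weighting annual outcomes:
$P = B\cdot\frac{40}{52} + A\cdot\frac{10}{52} + M\cdot\frac{10}{52}$
(births, induced abortions, miscarriages; all durations configurable, since
the surveillance method we adapt does not print its constants). Lactating
women are births × 6/12, and infants aged 0–5 months are set equal to the
exclusively breastfeeding count (fraction configurable, default 1).
Pregnant and lactating women are drawn proportionally from female cells
aged 15–49 — the maternal age allocation is not specified by any source, so
proportional draw is the neutral choice — and added back as dedicated
groups, conserving total persons (tested). Maternal per-kg values use the
15–49 female reference weight.

## Adequacy surfaces

Percent of requirement is $v/r \times 100$; the percent gap is the same
minus 100. Gaps are binned into ten ordered classes of width 15 percentage
points. Only the count and width are fixed by convention, so the anchors
were chosen symmetric about zero: interior edges at −60, −45, …, +45, +60
with open tails, half-open `[lower, upper)` intervals so that a gap of
exactly 0 (supply exactly meets requirement) starts the first non-negative
class. Nutrient density is expressed per 2000 kcal. Min-max normalization
pools the years being compared and maps onto 0–100 separately for
production and intake; a constant series returns zeros with a warning
rather than an error, since degenerate panels occur in practice.

Outlier screening flags country-years whose dietary energy lies outside
`[Q1 − 1.5·IQR, Q3 + 1.5·IQR]`. The source phrasing does not say whether
fences were computed per country or pooled; `iqr_exclude()` takes a plain
vector so callers can group either way, and `k` is configurable.

## Interventions

Deficit countries are those with per-capita apparent intake below
per-capita requirement; the annual aggregate deficit is
$\sum (r_i - v_i) N_i \times 365$ over the deficit set only — surpluses
elsewhere never offset shortfalls. Capsule needs are computed two ways:
dividing annual child requirements by capsule content (30,000 µg per 100K
IU capsule for infants 6–11 months; 60,000 µg per 200K IU capsule for
children 1–4 years), or by delivery protocol (one 100K capsule per infant,
two 200K capsules per child, annually). Fortified flour required is
`deficit / (level × bioavailability)` with shipped fortificant specs:
retinol 3 mg/kg (fully available), NaFeEDTA 35 mg/kg at 10% iron
bioavailability, zinc oxide 30 mg/kg at 30%. Percentages of flour
consumption are reported rounded half-up to integers, as conventionally
printed, with unrounded values retained; values above 100% are meaningful
(full fortification insufficient) and never clamped.

## Monte Carlo uncertainty for catch-all categories

Catch-all ("other, not elsewhere specified") categories pool items of
unknown proportions. Each draw assigns every catch-all a Dirichlet(1,…,1)
weight vector over its candidate items — uniform on the simplex, the
maximum-entropy choice given that no sampling law is specified — and
recomputes totals; 1000 draws by default, seeded for exact
reproducibility. Because totals are linear in the weights, every draw lies
in the convex hull of the single-candidate (vertex) assignments; the test
suite verifies hull containment against exhaustive vertex enumeration on
small candidate sets, and that the baseline (mean composition) equals the
expectation of the scheme.

## The synthetic world generator

`generate_world()` emits a complete, internally consistent input bundle: 15
food categories across 8 subgroups (including three catch-alls, two split
cereals, two processing-factor commodities, three heme-iron sources, and
exempt oil/stimulant/sugar subgroups), compositions with domain structure
(phytate confined to cereals and pulses, polyphenols to tea, a
carotenoid-rich red palm oil record), refuse and cooking-retention entries,
regional FLW, demographic pyramids over ages 0–80, reproductive statistics,
a synthetic reference-value table exercising every standard type (AR, AI,
physiological, per-kg), and both shipped override rules bound to generated
countries.

Alongside the inputs it computes **ground truth** by direct formula
evaluation — plain base-R loops that share no code with the engine's joins.
The central oracle test requires full-pipeline agreement with ground truth
to 1e-9 relative across all four variants, all three iron algorithms,
absorbed zinc, requirements, adequacy and deficits. Default problem size (3
countries × 2 years × 15 categories × 5 elements, ages 0–80) keeps the
whole verification run in seconds while exercising every code path;
generation is byte-deterministic given the seed.

Adequacy targeting: a request such as "country CA should sit at percent gap
−10 for vitamin A" is satisfied by uniformly rescaling that country's
`food`-element quantities so the target nutrient's intake hits the implied
value (possible because the engine is homogeneous of degree 1 in
quantities). Other nutrients shift along; only one nutrient per country can
be targeted exactly.

What the generator does **not** emulate: realistic magnitudes or
co-variation of food supplies, supply-utilization balance identities across
elements, reporting gaps and revisions, or historical-country boundary
changes. Passing the oracle therefore demonstrates computational
correctness of the accounting, not calibration against real food systems.

## Numerical choices and degenerate inputs

* Year length 365 days everywhere; annualization of daily deficits uses the
  same constant, so the two conversions cancel exactly.
* Zero requirement, zero dietary energy and zero-variance comparison series
  are errors or `NA`-with-warning, never silent zeros.
* Absorption fractions clamp to (0.001, 1); the zinc quadratic's
  discriminant is checked and cannot be negative for valid parameters.
* A country-year with no contributing flows aggregates to an explicit zero
  with a warning rather than dropping out of the panel.
* Empty catch-all candidate sets, malformed schemas, negative quantities
  outside stock changes, and demographic cells with no or ambiguous
  reference-value match all fail fast with named rows or groups.

## Known limitations

* The iron-algorithm coefficient file is transcribed from the cited
  publications and shipped as versioned data; users applying the package to
  real data should verify the transcription against the originals before
  drawing substantive conclusions. The engine's behaviour is tested
  independently of any particular coefficient values.
* Apparent intake is national availability after losses, not individual
  intake; distributional statements within countries are out of scope.
* Only iron and zinc are bioavailability-adjusted; cooking losses use a
  retention table that defaults to 1 where no match exists.
* Supplementation coverage, cost-effectiveness and biofortification
  breeding targets are out of scope; density-delta scenarios can be
  expressed as modified composition inputs.
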