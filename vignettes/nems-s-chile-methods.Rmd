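---
title: "NEMS-S-CHILE: scoring model, reliability statistics, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NEMS-S-CHILE: scoring model, reliability statistics, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemschile)
```

## The instrument

NEMS-S-CHILE is a store-audit checklist: an evaluator walks a supermarket or
a street market (*feria libre*) and records, food by food, whether each item
is on offer, its unit price for price-comparison foods, the organoleptic
condition of fresh produce, and the varieties on offer beyond the checklist.
Unlike the original US NEMS-S (which rewards low-calorie/low-fat "healthy
options" and spans −8 to 50 points), the Chilean adaptation organises its 62
foods into 27 measures by **NOVA processing group**:

* **Group 1** — natural or minimally processed foods (fresh fruits and
  vegetables, meats, fish, legumes, eggs, nuts, potato, rice, fluid milk);
* **Group 2** — processed culinary ingredients (oil, butter, wheat flour);
* **Group 3** — processed foods (canned seafood, yogurt, dried noodles,
  wholemeal bread, cheeses, processed nuts);
* **Group 4** — ultra-processed products (sausages, jams, soda, juices,
  processed fat, breakfast cereals, biscuits, white bread).

Availability earns positive points for groups 1–3 — with group 1
concentrating the highest share — and **negative** points for each of the
eight group-4 foods, so a store stocked only with ultra-processed products
scores −30 while a store with everything healthy and every bonus reaches
100. `score_bounds()` computes both extremes by greedy enumeration, which is
exact because all components are additive and independent.

### Reconstructed point allocations

The published checklist fixes the attainable range (−30 to 100), the group
structure, and the component maxima implied by the reported score
distributions (fruits & vegetables ≈ 30, other group-1 foods ≈ 40, group 2
= 10, group 3 = 20, group 4 = −30), but not every per-food point value: the
full allocation table lives in unpublished supplementary material. The
packaged JSON therefore ships a **constrained reconstruction**: per-food
values chosen once so that each component maximum and the global range are
met exactly. They are a synthetic stand-in, marked as such here and in
`?default_chile_instrument`, and every value can be overridden by editing
the JSON definition and loading it with `load_instrument()`.

Two placement decisions were genuinely open:

* **Egg** appears in the reliability tables among group-1 foods but not in
  the measure list; following the Chilean dietary-guideline grouping
  "legumes and eggs" we file it under the legume measure with
  `counts_as_variety = FALSE`, so it never counts as a legume variety.
* **Price pairs**: seven (healthier, regular) comparisons — integral vs
  white rice, olive vs vegetable oil, integral vs white flour, skim vs whole
  yogurt, integral vs white noodles, wholemeal mold bread vs batch bread,
  quesillo vs mature cheese. Milk records prices (its reliability is
  reported) but has no published healthy-vs-regular comparison, so it
  carries the price dimension without a pair.

## Scoring rules

All component points are integers and all totals are integers.

**Quality (0–3 points per store).** An available produce item is *adequate*
iff strictly more than 75% of its units are in maximum organoleptic
condition (`adequate_fraction > 0.75`). Store points come from the fraction
of **available** produce items that are adequate: >75% → 3, 50–74% → 2,
25–49% → 1, otherwise 0. The denominator is available items only — an item
a store does not stock cannot be quality-rated, which is also why the
reliability table's quality column has a varying `n`. A store with no
produce at all scores 0 and is flagged `assessable = FALSE` rather than
being conflated with poor quality. Band edges are read as printed: the 75%
edge is strict, the 50% and 25% edges are inclusive lower bounds.

**Variety.** Strictly more than 3 *additional* varieties beyond the
checklist earns +3, separately for the fruit and the vegetable measure.
Legumes earn +4 when the store offers strictly more than 5 varieties *in
total*; we count available checklist legumes plus recorded extras, since the
published rule is phrased in total varieties for legumes but in additional
varieties for produce. Exactly 3 extras or exactly 5 legume varieties earn
nothing.

**Price comparison (+1 per pair).** For each pair the bonus is earned when
both foods are available, both have a recorded unit price on a comparable
brand/size, and the healthier option costs **no more** than the regular one
— a tie earns the bonus, because the reward is for the healthy option not
being more expensive. Missing prices contribute 0. Fruits and vegetables
carry no price comparison (street-market sales formats make a unit price
ill-defined).

Prices are stored as integer Chilean pesos: CLP has no minor units and
integer arithmetic keeps the tie rule exact.

## Reliability statistics

Each store is audited twice on the same day by two trained evaluators.

**Percent agreement** is the raw share of identical paired ratings × 100,
reported to two decimals (25 matches of 26 stores prints 96.15).

**Cohen's kappa** for dichotomous records uses
κ = (p₀ − pₑ)/(1 − pₑ) with pₑ from the marginal products. When either
evaluator is constant across stores the statistic is undefined; the report
keeps the reason (`"<2 levels"`) and renders a dash, matching how such cells
are footnoted in practice — common for quality, where most produce is
adequate everywhere, and for foods every store stocks. Bands: 0–0.20 mild,
0.21–0.40 fair, 0.41–0.60 moderate, 0.61–0.80 substantial, 0.81–1.00
perfect. Banding is applied to the **unrounded** statistic; two-decimal
rounding is display-only. A negative kappa lies below the scale's floor and
is banded "mild" with a warning.

**ICC for prices.** Price pairs enter only when both evaluators priced the
same type, size and brand in the same store (`price_match()`), so `n`
varies by food. The reference scale (bad < 0.4, regular 0.41–0.59, good
0.60–0.74, excellent > 0.75) does not fix the ICC model, so a choice was
needed: we use **ICC(2,1)** — two-way random effects, absolute agreement,
single measure — because the two evaluators are interchangeable trained
raters and a systematic price-reading shift between them should count as
disagreement. The consistency form ICC(3,1) is available via
`icc(..., model = "consistency")`. Zero between-store variance leaves the
coefficient undefined with a reason rather than an arbitrary value.

**Composite rows.** The availability table includes any-item-available
composite rows for the fruit and the vegetable measures (flagged
`composite = TRUE`), alongside the per-item rows, mirroring how aggregate
fruit/vegetable rows are reported. The extra-variety indicator is "any
additional varieties present" (count > 0) per measure.

## Store-type comparison

Score components are summarised per store type by mean, SD, median and
quartiles, and compared with the **two-sided Mann–Whitney U test** — exact
when the combined sample is ≤ 20 without ties, tie-corrected normal
approximation with continuity correction otherwise. The test identity is a
package assumption: published comparisons of this design report medians and
quartiles at small n without naming the test, and a rank test is the
standard choice there. Quartiles use linear interpolation
(`stats::quantile` type 7); conventions differ across software, so the
method is fixed and stated.

## The synthetic audit generator

`simulate_audits()` exists so every stage — scoring, reliability,
comparison — can be exercised end to end without field data. Its model is
the simplest generative structure consistent with a kappa analysis:

* Evaluator 1 records the store's **true state**; evaluator 2 records the
  truth with independent symmetric errors — availability flips with
  probability `rater_flip_prob` (default 0.02), prices re-read with
  lognormal noise (`price_reading_sd = 0.01`), a different brand/size
  priced with probability `1 − brand_match_prob` (default 0.1), variety
  counts off by one with the flip probability.
* Default design matches the study: 17 supermarkets + 9 street markets,
  two evaluators each, one audit date.
* Availability prevalences are **direction-calibrated only** (true field
  prevalences are unpublished): processed and ultra-processed foods are
  common in supermarkets (0.90/0.85/0.95 for groups 2/3/4) and scarce in
  street markets (0.30/0.40/0.20), while fresh produce is richer in street
  markets (0.95 vs 0.80). Other group-1 staples sit at 0.85/0.75.
* Store-level prices are lognormal around per-food base prices
  (median `price_location` = 1500 CLP, log-SD `price_cv` = 0.25); the
  adequate-unit fraction of available produce is Beta(8, 2) (mean 0.8, so
  most items clear the 75% threshold, reproducing the high-adequacy regime
  that makes quality kappas frequently undefined); extra varieties are
  Poisson(1.5) per measure.
* All randomness derives from the single integer `seed`; the same
  configuration always reproduces a byte-identical audit CSV.

Under this model the large-sample availability kappa has the closed form
implemented in `expected_kappa(p, f)`: observed agreement 1 − f and chance
agreement from the marginals p and p + f(1 − 2p). It equals 1 at f = 0 and
0 at f = 0.5 (the second evaluator is then independent of the truth), and
the test suite checks that the empirical kappa pooled over ~5,000 simulated
item pairs matches it within 0.02.

**What the generator does not emulate:** price co-movement across stores,
seasonal produce availability, evaluator-specific bias (the error model is
symmetric; asymmetric rates would need a two-parameter flip model), and
correlated availability within a measure. Passing tests therefore
demonstrate the pipeline's correctness under the stated model, not the
field behaviour of real audits.

## Numerical and degenerate-input conventions

* Thresholds are strict exactly where the rules say "more than"; band edges
  at 0.50/0.25 (quality) are inclusive.
* Price ties earn the bonus; missing data never does.
* Undefined statistics (constant raters, < 2 both-available stores, < 3
  matched price pairs, zero between-store variance) propagate a reason and
  render as dashes; they are never coerced to 0.
* Stores with a number of evaluators other than two are excluded from
  reliability with a warning, never silently.
* Empty audit files parse to empty audit sets with a warning; validation
  rejects prices/fractions/varieties recorded on unavailable items, so a
  missing value can never be confused with an observed zero.

## Problem sizes used by the test suite

The suite cross-checks the scoring engine against an independent
first-principles oracle on instruments of up to 12 foods (where exhaustive
enumeration of availability patterns is feasible), recovers a true ICC of
0.8 from 200 simulated store pairs, checks Mann–Whitney p-values against
full enumeration for all splits of up to 8 observations, estimates the
test's type-I error from 2,000 null simulations, and verifies the kappa
closed form on ~5,000 simulated item pairs. These sizes give Monte-Carlo
error comfortably below the asserted tolerances while keeping the default
run fast.

## Known limitations

* The per-food point allocation is a constrained reconstruction (above);
  component subtotals and totals are faithful to the published range and
  component maxima, but per-food contributions are conventions.
* Reliability is defined for exactly two evaluators; multi-rater
  generalisations (Fleiss kappa, weighted kappa) are out of scope.
* The comparison module tests distributional location only; no regression
  modelling of score determinants.
* Published field statistics depend on the unpublished audit data and are
  not reproducible from this package; what is reproducible — and tested —
  is every printed rule constant, the score bounds, and the analytic worked
  examples forced by the printed agreement counts.
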