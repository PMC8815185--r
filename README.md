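# nemschile

Scoring engine and reliability analysis for **NEMS-S-CHILE**, the Chilean
adaptation of the Nutrition Environment Measures Survey for Stores.

Food-environment researchers audit retail stores with a checklist to
quantify how easy it is to buy healthy food in a neighbourhood. NEMS-S-CHILE
reorganises the classic NEMS-S checklist by **NOVA food-processing group**:
62 foods in 27 measures, where natural/minimally processed foods (group 1),
culinary ingredients (group 2) and processed foods (group 3) earn positive
availability points, and the eight ultra-processed group-4 products earn
negative points. With the produce quality bonus (0–3), the extra-variety
bonuses (+3 per fruit/vegetable measure beyond 3 extra varieties, +4 for
more than 5 legume varieties) and seven healthier-vs-regular price
comparisons (+1 each when the healthier option costs no more), a store's
total spans

```
-30  <=  S = G1 + G2 + G3 - |G4|  <=  100
```

The package provides, for this instrument:

* the packaged checklist as an editable JSON definition
  (`default_chile_instrument()`, `load_instrument()`), with validation of
  all structural invariants and `score_bounds()` by exact enumeration;
* a validated audit data model with CSV round-tripping (`read_audits()`,
  `write_audits()`);
* the scoring engine (`total_score()`, `score_audits()`) with per-component
  reports;
* inter-evaluator reliability (`percent_agreement()`, `cohens_kappa()`,
  `icc()` as ICC(2,1), `price_match()`, `reliability_report()`) with the
  banded interpretation scales (kappa: mild → perfect; ICC: bad →
  excellent) and dash-rendered undefined cells;
* store-type comparison (`summarize_scores()`, `mann_whitney()`,
  `compare_store_types()`);
* a seeded synthetic generator of paired-evaluator audits
  (`simulate_audits()`, `expected_kappa()`) emulating 17 supermarkets and
  9 street markets audited twice the same day;
* a command-line pipeline (`nems_cli()`; launcher in `inst/cli/nemschile`)
  with `simulate`, `score`, `reliability` and `compare` subcommands.

See `vignettes/nems-s-chile-methods.Rmd` for the model, the reconstruction
of the point-allocation table, and every numerical convention.

## Worked example

```r
library(nemschile)

instr <- default_chile_instrument()
instr
#> NEMS instrument 'NEMS-S-CHILE-1.0': 62 foods, 27 measures, score range [-30, 100]
#>   foods per NOVA group: G1=37 G2=6 G3=11 G4=8

aud <- simulate_audits(sim_config(seed = 42), instr)
aud
#> NEMS audit set: 3224 observations, 26 stores, 52 audits (instrument NEMS-S-CHILE-1.0)

scores <- score_audits(aud, instr)
head(as.data.frame(scores)[, c("store_id", "store_type", "evaluator_id",
                               "group1_total", "group2", "group3",
                               "group4_magnitude", "total")], 4)
#>   store_id    store_type evaluator_id group1_total group2 group3 group4_magnitude total
#> 1    MKT01 street_market           E1           52      4      6                0    62
#> 2    MKT01 street_market           E2           52      4      6                0    62
#> 3    MKT02 street_market           E1           46      1      5                3    49
#> 4    MKT02 street_market           E2           46      1      5                7    45
```

The two rows per store are the two evaluators; their disagreement is what
the reliability report quantifies:

```r
rel <- reliability_report(aud, instr)
rel
#> NEMS reliability report over 26 paired stores (instrument NEMS-S-CHILE-1.0)
#>   availability kappa: 62 foods, 0 undefined, median defined 1.00
#>   price ICC: 17 foods with >=3 matched pairs

cohens_kappa(c(rep(TRUE, 25), FALSE), c(rep(TRUE, 24), FALSE, FALSE))
#> kappa = 0.65 (substantial), n = 26
```

That last call is the analytic 2×2 worked example: 24 both-yes, 1 yes/no,
1 both-no over 26 stores gives observed agreement 25/26 (96.15%) and
κ = 48/74 ≈ 0.65, a substantial agreement.

Comparing store types (medians and Mann–Whitney p-values per component)
shows the simulated cohort separating the published way — ultra-processed
availability drives supermarket scores down:

```r
cmp <- compare_store_types(scores)
round(cmp[, c("street_median", "super_median", "p_value")], 3)
#>   street_median super_median p_value
#> 1          52.0         50.5   0.148   # group 1
#> 6           0.0         30.0   0.000   # group 4 magnitude
#> 7          61.5         45.0   0.000   # total
```

The same pipeline runs from a shell:

```sh
Rscript inst/cli/nemschile simulate --out audits.csv --seed 42
Rscript inst/cli/nemschile score --audits audits.csv --out scores.csv
Rscript inst/cli/nemschile reliability --audits audits.csv --out-dir reports/
Rscript inst/cli/nemschile compare --audits audits.csv --out compare.csv
```

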