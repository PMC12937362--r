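# asrwi

Welfare assessment for intensively kept sheep and goats in hot-arid
climates: multi-assessor scoring sheets, inter-observer reliability, and
the Arid-Hot Small Ruminant Welfare Index (ASR-WI).

## Who this is for

Farm advisors, welfare scientists and students who score sheep and goats
with a panel of independent assessors and need to know (a) whether the
assessors agree well enough for the scores to mean anything, and (b) how
the herd scores on a single 0–100 welfare scale. The protocol covers 24
indicators across four welfare domains — Behaviour and Mental State,
Environment, Nutrition, Health — chosen for feasibility under intensive
husbandry and high thermal load (panting, hydration by skin pinch, shade
access, stocking density, lameness, body condition, ...).

## The statistics at the core

**Inter-observer reliability.** With m assessors assigning categorical
scores to the same animals, agreement beyond chance is quantified by
Fleiss' κ on the subjects × categories count table
(n<sub>ij</sub> = number of raters giving subject *i* category *j*):

- p<sub>j</sub> = Σ<sub>i</sub> n<sub>ij</sub> / Σ<sub>i</sub> n<sub>i</sub> (category proportions)
- P<sub>i</sub> = Σ<sub>j</sub> n<sub>ij</sub>(n<sub>ij</sub>−1) / (n<sub>i</sub>(n<sub>i</sub>−1)) (per-subject pairwise agreement)
- P̄ = mean<sub>i</sub> P<sub>i</sub>, P̄<sub>e</sub> = Σ<sub>j</sub> p<sub>j</sub>²
- **κ = (P̄ − P̄<sub>e</sub>) / (1 − P̄<sub>e</sub>)**

Subjects may have different numbers of raters (n<sub>i</sub> ≥ 2); with
constant n<sub>i</sub> this is classic Fleiss' κ. Percentage agreement is
100 · P̄ (mean pairwise within-subject agreement — the exact quantity in
the κ numerator). κ is interpreted on the Landis–Koch scale
(poor < 0 ≤ slight ≤ 0.20 < fair ≤ 0.40 < moderate ≤ 0.60 <
substantial ≤ 0.80 < almost perfect ≤ 1).

**The index.** Indicators enter the index only if κ ≥ 0.35 (at least
moderate agreement) and they are on the curated index-member list. Encoded
scores are 0–2 (0 = worst, 2 = best). Each domain is a weighted mean of
its members rescaled to 0–100, e.g. behaviour
B = (0.30 S_D + 0.25 S_HAR + 0.25 S_SW + 0.20 S_St)/2 × 100, and

**ASR-WI = 0.20 B + 0.30 E + 0.20 N + 0.30 H**  ∈ [0, 100].

## Worked example

Simulate the pilot design (46 sheep + 54 goats, 8 assessors, all 24
indicators, per-indicator rater-error rates calibrated to the published
reliability bands), then analyse it:

```r
library(asrwi)
sheet <- generate_sheet(synthetic_config(seed = 2026))  # 19,200 records

rel <- reliability_table(sheet)
head(rel[rel$species == "goat", c("indicator_id", "kappa", "percent_agreement", "band")], 5)
#>   indicator_id      kappa percent_agreement band
#> 1 demeanour         1                 100   almost_perfect
#> 2 har               1                 100   almost_perfect
#> 3 social_withdrawal 0.362              61.7 fair
#> 4 stereotypic       0.672              82.9 substantial
#> 5 shade_shelter     0.608              76.9 substantial

domain_summary(rel)
#>   domain           species n_indicators n_undefined mean_kappa mean_percent_agreement
#> 1 behaviour_mental goat               4           0      0.759                   86.1
#> 3 environment      goat               5           0      0.645                   80.3
#> 5 nutrition        goat               5           0      0.682                   82.1
#> 7 health           goat              10           0      0.770                   87.1
#> ... (sheep rows omitted here)

welfare_index(sheet, species = "goat")
#> <welfare_index_result> herd (goat), 54 animal(s)
#>   behaviour_mental   73.6  (weight 0.20)
#>   environment        78.8  (weight 0.30)
#>   nutrition          75.2  (weight 0.20)
#>   health             75.6  (weight 0.30)
#>   ASR-WI             76.1 / 100
#>   measured-only indicators (not in the index): 8 - see $appendix
```

Reading the numbers: every Demeanour rating was unanimous (κ = 1, 100%
agreement), Social Withdrawal assessors agreed only fairly (κ = 0.36), and
the goat herd scores 76.1/100 overall, pulled up by health (75.6, weight
0.30) and environment (78.8, weight 0.30). The eight indicators that are
measured but carry no index weight (e.g. Condition of Equipment) are
reported in the result's `$appendix`.

`select_indicators(pilot_reliability())` applies the κ ≥ 0.35 gate to the
packaged pilot-study reliability values; `asrwi_report()` bundles
validation, reliability, selection and index into one printable/JSON
report. A command-line wrapper with `validate`, `reliability`, `index`,
`simulate` and `report` subcommands ships at
`system.file("cli", "asrwi.R", package = "asrwi")`.

## Limitations

The generator's rater-error model (latent truth + symmetric uniform
error) is intentionally simple so agreement has a closed form; it does not
model rater drift, fatigue or correlated errors. Index weights are fixed
expert constants; no sensitivity analysis or external construct validation
is provided. See the methods vignette (`vignettes/asrwi-methods.Rmd`) for
the full account of model choices, tie-breaks and degenerate cases.
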