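---
title: "Methods: inter-observer reliability and the ASR-WI composite index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inter-observer reliability and the ASR-WI composite index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asrwi)
```

## The assessment problem

On-farm welfare assessment of small ruminants under intensive, hot-arid
husbandry rests on a panel of independent assessors scoring the same
animals on categorical indicators. Two questions follow. First, are the
scores reproducible across assessors — without that, an indicator is noise
regardless of its biological appeal. Second, how do the many indicator
scores combine into a single interpretable welfare figure. This package
implements both steps: generalized Fleiss' κ for multi-rater agreement,
and the ASR-WI, a reliability-gated, fixed-weight composite on a 0–100
scale.

The protocol's catalogue is 24 indicators in four domains — 4 behaviour
and mental state, 5 environment, 5 nutrition, 10 health — applicable to
both sheep and goats. Sixteen of them are index members; the other eight
(e.g. Condition of Equipment, Respiratory Quality) are measured and
reported but carry no index weight.

## Score encoding

Every indicator is encoded on a 0–2 ordinal scale with 0 = worst and
2 = best welfare; binary presence/absence indicators map "problem
present" to 0 and "absent" to 2. Raw field definitions with the inverse
sense are re-coded at data entry, so `polarity` is always "higher is
better" inside the package. The common `scale_max = 2` is what makes the
domain formulas' division by 2 a pure scale normalization (below). The
registry (`load_registry()`) is an editable CSV, so a user who prefers a
different symbol-to-indicator mapping or weight set can supply their own
file; all invariants (unique ids/symbols, per-domain weights summing
to 1) are re-validated at load.

## Reliability: generalized Fleiss' κ

For each indicator and species we form the rating matrix: rows are
animals, columns the categories `0..k-1`, entries the number of assessors
assigning that category. With row sums \(n_i\),

\[
p_j = \frac{\sum_i n_{ij}}{\sum_i n_i},\qquad
P_i = \frac{\sum_j n_{ij}(n_{ij}-1)}{n_i(n_i-1)},\qquad
\bar P = \frac{1}{N}\sum_i P_i,\qquad
\bar P_e = \sum_j p_j^2,
\]

\[
\kappa = \frac{\bar P - \bar P_e}{1-\bar P_e}.
\]

Design choices, each of which can move numbers if decided differently:

* **Varying raters per subject.** Subjects are retained whenever
  \(n_i \ge 2\) (a subject with one rating carries no agreement
  information and is dropped, but recorded). With constant \(n_i\) the
  formula reduces exactly to classic Fleiss' κ, which the test suite
  verifies against an independently coded textbook implementation.
* **"% agreement" means pairwise agreement.** \(P_i\) is the proportion
  of concordant assessor pairs within animal \(i\), so the reported
  percentage agreement \(100\,\bar P\) is the mean pairwise
  within-subject agreement — the exact quantity entering the κ numerator.
  Modal definitions ("share of raters matching the majority") give
  different, typically higher, numbers; users comparing against other
  tools should check which definition those use.
* **Undefined κ.** If every rating falls in one category,
  \(\bar P_e = 1\) and κ is 0/0. This is surfaced as an explicit
  condition (`asrwi_kappa_undefined`, with the percentage agreement of
  100 still attached), never coerced to 0 or 1: absence of category
  variation is absence of evidence about agreement, not perfect or null
  agreement. Downstream, such indicators are excluded from domain means
  (and counted) and fail the selection gate with reason "kappa
  undefined".
* **Interpretation bands.** κ is labelled on the Landis–Koch scale. The
  scale is conventionally printed with discrete-looking bounds
  ("0.21–0.40"), which are ill-defined for continuous κ; the package uses
  half-open bands closed at the top — fair is \((0.20, 0.40]\) — so 0.40
  is fair and 0.41 moderate, with 0 itself counted as slight. The tiling
  is gapless on \((-1, 1]\) and band assignment is monotone in κ.
* **No standard errors.** κ standard errors and significance tests are
  out of scope; the package reports point estimates and bands only.

Domain-level reliability is the unweighted arithmetic mean of
indicator-level κ (and of % agreement) within each domain and species.
On the packaged pilot reliability fixture this reproduces the goat
behaviour-domain mean of 0.75. For some other domains the pilot study's
narrative quotes domain values that are *not* the arithmetic means of its
own indicator table (e.g. a goat health figure of about 0.83 against a
table mean of 0.785); the aggregation behind those narrative figures is
not stated, so this package implements the transparent mean-of-indicators
and documents the discrepancy rather than reverse-engineering an
undisclosed pooling.

## The composite index

**Selection.** An indicator enters the index only if (1) its κ is at
least 0.35 — boundary inclusive, i.e. at least moderate agreement under
the band decision above — and (2) it is on the registry's curated
index-member list, which encodes the protocol's biological-relevance
judgement as data rather than computation. `select_indicators()` returns
both flags per indicator for audit. Every κ in the packaged pilot fixture
passes the gate (the tightest case sits exactly at 0.35), so all 16
members are included there.

**Consensus across assessors.** The index consumes one encoded score per
animal and indicator, but eight assessors produce eight. The consensus is
the rounded median, with half-scores rounded toward the worse-welfare
category (median 1.5 becomes 1): conservative in an audit context, where
the cost of overstating welfare exceeds that of understating it. The
protocol itself does not prescribe a combination rule; this one is the
package's choice and is isolated in one small function.

**Domain scores and the index.** With member weights \(w_s\) summing
to 1 per domain and encoded scores \(S_s \in [0,2]\),

\[
D = \frac{\sum_s w_s S_s}{2}\times 100,
\qquad
\mathrm{ASR\text{-}WI} = 0.20\,B + 0.30\,E + 0.20\,N + 0.30\,H .
\]

The printed forms of these domain formulas end in a trailing "2" whose
typographic role is ambiguous; it is read here as the division by
`scale_max = 2`, because only that reading makes every domain attain
exactly the stated 0–100 range: the weighted mean of 0–2 scores lies in
\([0,2]\), and dividing by 2 maps it onto \([0,1]\) before the percentage
scaling. Any other reading either overshoots 100 or cannot reach it.

Herd-level scoring averages consensus scores across animals per indicator
and then applies the formulas; since the formulas are linear this equals
averaging per-animal indices, so the choice is presentational.
Animal-level mode (`scope = "animal"`) returns one row per fully assessed
animal. Resource-level indicators such as stocking density are scored
once per pen in practice; entering the same value for every animal leaves
both modes unchanged. If a reliability table is passed to
`welfare_index()`, index members failing the gate trigger a warning; the
index is still computed with the fixed published weights (re-normalizing
weights after an exclusion would silently change the instrument), and the
exclusion audit lives in `select_indicators()`.

The symbol-to-indicator mapping for the formulas (S_P = Panting,
S_Sh = Shade/Shelter, S_Sd = Stocking Density, S_Dir = Dirtiness,
S_Le = Body and Head Lesions, S_D = Demeanour, ...) is an interpretation:
the formulas' symbols are nowhere expanded in the source protocol. The
mapping lives in the registry CSV, not in code, precisely so it can be
edited if another reading (e.g. swapping S_Sd/S_Dir) is preferred.

## The synthetic panel generator

`synthetic_config()` / `generate_sheet()` emulate the pilot design: 46
sheep and 54 goats (100 animals), 8 assessors, all 24 indicators — 19,200
records per sheet. Per animal and indicator a latent true category is
drawn from a truth distribution (default \((0.10, 0.25, 0.65)\) over
categories 0/1/2: a mostly adequate-welfare herd with a thin tail of
problem animals, which is what a functioning intensive farm looks like);
each assessor independently reports the truth with probability
\(1-\varepsilon\) and otherwise a uniform draw among the other
categories. Identical seed and configuration give byte-identical sheets.

This model was chosen because agreement is closed-form:
\(\bar P = (1-\varepsilon)^2 + \varepsilon^2/(k-1)\) (both correct, or
both wrong on the same category), reported-category marginals
\(q_j = p_j(1-\varepsilon) + (1-p_j)\varepsilon/(k-1)\), asymptotic
\(\bar P_e = \sum_j q_j^2\), and the implied κ. `expected_agreement()`
exposes these, and `calibrate_error_rate()` inverts the monotone
\(\varepsilon \mapsto \kappa\) map numerically. Default per-indicator
\(\varepsilon\) values are obtained by inverting the packaged pilot goat
κ values, so a default sheet lands near the published agreement bands
(Demeanour nearly error-free, Panting noisy). That calibration is
illustrative — it makes a realistic demonstration panel, not a
reproduction of the on-farm data.

What the generator does **not** emulate: rater drift over the session,
fatigue, correlated errors between assessors (e.g. shared
misinterpretation of a scoring threshold), ordinal-distance-aware errors
(a confused rater is equally likely to be off by two categories as by
one), or missing scores. Passing estimator-recovery tests on this model
therefore shows the κ machinery is correct, not that real assessor error
is this benign; on real panels, correlated errors in particular would
inflate agreement relative to this model.

## Numerical choices and degenerate inputs

* \(\bar P_e = 1\) detection uses a `1e-12` tolerance; category
  proportions are exact ratios of integers, so only the genuinely
  single-category case can trigger it.
* `interpret_kappa()` rejects values outside \([-1, 1]\) and NaN;
  NA propagates (used for undefined κ rows).
* Duplicate (animal, assessor, indicator) rows are all rejected — with
  conflicting double entries there is no principled keeper — but a row
  already rejected for another reason does not drag a valid twin down.
* Probability vectors must sum to 1 within `1e-9`; weight sums within
  `1e-9` at registry load.
* Tie-break in consensus: exactly half-integer medians go to the lower
  (worse-welfare) category, as above.

## Problem sizes in the test suite

The suite validates the agreement oracle on 1,000 randomly generated
mixed-rater matrices (up to 50 subjects, 4 categories, 8 raters), checks
estimator recovery at the study design scale (100 animals × 8 raters)
over 200 paired replicates across \(\varepsilon \in \{0.05, 0.2, 0.5\}\),
and convergence of κ to its analytic value at panels of 50, 500 and 5,000
subjects using sampling envelopes of 0.23, 0.08 and 0.02 (about four
standard deviations of the estimator's spread at each size). These sizes
give stable pass/fail behaviour at fixed seeds while keeping a full run
around a minute.

## Known limitations

Reliability here is inter-observer only (one session; no test–retest),
categories are treated nominally (no ordinal-weighted κ), κ uncertainty
is not quantified, and the index weights are fixed expert constants with
no sensitivity analysis. Construct validity of the composite — whether
ASR-WI differences track welfare outcomes — is outside what any
computation on these data can establish.
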