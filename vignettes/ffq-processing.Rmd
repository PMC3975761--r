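---
title: "Processing food frequency questionnaires: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing food frequency questionnaires: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffquant)
```

## The processing model

A semi-quantitative FFQ asks, for each line of a fixed food list, how
often the participant consumed it during the reference period, choosing
one of nine frequency categories. Each line carries a portion weight (one
medium serving, standard unit or household measure, in grams). The daily
intake model is deliberately simple and fully data-driven:

* **Line grams/day** = frequency multiplier × portion grams. The
  multiplier translates a category into occurrences per day; category 1
  ("never or less than once a month") is fixed at 0.
* **Apportioning**: each line maps to up to six food codes with
  proportions summing to 1; line grams split accordingly.
* **Composition join**: nutrients are amounts per 100 g of edible food, so
  each food entry contributes grams × composition/100 per day.
* **Food groups as pseudonutrients**: a group's daily "amount" is simply
  the grams of its member foods, accumulated exactly like a nutrient.
  Group totals therefore roll up consistently from the most detailed
  output (per line × food code) to the participant totals, and the test
  suite asserts those aggregation identities exactly.

Everything that parametrises this chain — lines, multipliers, mappings,
composition, groups, reference lists, Schofield coefficients — lives in
delimited-text tables, so the engine can be re-pointed at a different
questionnaire, food list or population without touching code.

### Frequency multipliers

The nine category labels constrain, but do not fix, the numeric
multipliers; they are shipped as an editable table
(`default_frequency_scheme()`), with month-based categories using the mean
month length:

| code | label | multiplier (per day) |
|---|---|---|
| 1 | never or < once/month | 0 |
| 2 | 1–3 per month | 2/30.44 |
| 3 | once a week | 1/7 |
| 4 | 2–4 per week | 3/7 |
| 5 | 5–6 per week | 5.5/7 |
| 6 | once a day | 1 |
| 7 | 2–3 per day | 2.5 |
| 8 | 4–5 per day | 4.5 |
| 9 | 6+ per day | 6 |

Multipliers must be non-decreasing in the code; the loader enforces this.

### Part-1 cell conventions

Hand-keyed grids accumulate conventions, and the parser implements them
exactly: `1`–`9` are answers; `-9` or an empty cell is an unrecorded
frequency; `-4` is the legacy code for "two frequencies ticked", kept as a
distinct status (so logs can report it separately) but treated as missing
downstream; a dual answer may also be keyed `2;3` in one cell, in which
case the first value is processed and a note logged. Both ASCII
hyphen-minus and the Unicode minus sign are accepted, because both occur
in hand-entered files. Missing means **zero intake**, never imputation;
excessive missingness is handled by the exclusion stage instead, which
keeps the engine's mass-conservation property exact (sum of food grams =
sum of answered multiplier × portion).

### Part-2 resolution

The detail questions (milk variety and amount, up to four breakfast
cereals, frying and baking fat) resolve to food codes with a fixed
precedence per kind:

1. a pre-assigned food code (files coded against the look-up lists),
2. a ticked "None/No" box, where the reference list allows one,
3. an exact match of the normalized free text against the reference list,
4. the default code — always logged, so default counts are auditable.

Normalization case-folds, strips punctuation and collapses whitespace, and
is idempotent. Matching is *exact-after-normalization only*: assigning a
"close" name automatically would make runs depend on a similarity
threshold, and the judgement of whether an unlisted brand resembles a
listed one (by comparing nutrient profiles) is a human step. Reproducible
defaults were preferred over cleverness; the `text_matching` engine option
disables step 3 entirely, which is the mechanism for studying how text
matching affects intakes and rankings.

Three substitution rules follow from the resolved codes:

* **Milk**: the substitutable slot of milk-tagged lines takes the resolved
  milk code. The milk-amount category additionally scales milk-tagged line
  grams through a configurable factor table (`milk_amounts.csv`, default
  0.5×–2×). Only milk-tagged lines are scaled; milk hidden inside other
  lines is untouched. Both hooks (code switch, amount scaling) are
  implemented; either can be neutralised in the data model by editing the
  factor table to 1.
* **Cereal**: up to four distinct resolved cereal codes (order preserved,
  extras truncated with a note); the line's grams split **equally** across
  them. No published weighting exists for multi-cereal answers; the equal
  split is the least-informative choice and is logged so alternative
  weightings can be audited.
* **Cooking fat**: modified "without fat" foods carry an uptake (g of fat
  per 100 g food); the resolved frying/baking fat is emitted as a separate
  entry of grams × uptake/100. A "None/No" box yields the `NO_FAT`
  sentinel and no fat entry.

## Outlier identification

Two stages, in fixed order. First, questionnaires with ≥ 10 missing part-1
lines (`missing_threshold`, configurable) are excluded. Second, for the
remainder, energy intake (the designated kJ nutrient, converted to MJ by
the exact factor 1000) is divided by basal metabolic rate predicted from
sex- and age-band-specific Schofield coefficients (MJ/day =
slope × weight + intercept), and the `floor(0.005 · n)` lowest and highest
ratios are excluded. Choices worth making explicit:

* **Coefficients are data.** The adult Schofield bands (18–30, 30–60,
  60+ years per sex) ship in the fixture generator's `schofield.csv` from
  the published 1985 standard, editable like any other table; nothing is
  hard-coded. Ages outside the table's coverage raise an error rather than
  extrapolate.
* **Pooled tails, floor counts.** Tails are ranked cohort-wide (sexes
  pooled) with `floor(tail × n)` per tail and ties broken by participant
  id, making the stage rank-based (invariant to monotone transforms of the
  ratio) and deterministic. At an eligible n of 25 102 this yields
  125 + 125 = 250 exclusions, consistent with the two-stage accounting
  25 351 − 249 − 250 = 24 852 that the acceptance script recomputes. A
  per-sex ranking convention would also be defensible; pooled was chosen
  because the exclusion criterion is a property of reporting plausibility,
  not of the sex-stratified analysis that follows it.
* **Missing age or weight** makes a participant BMR-ineligible: flagged in
  the report, kept in the sample, never imputed.

## Comparison machinery

Two runs are compared per variable (optionally per stratum) with mean, SD
(sample, n−1), median, minimum, maximum, and quintile shifts. Cut-points
are the 20/40/60/80th percentiles of the **reference** run only — the
comparison is intentionally asymmetric — under R's default percentile
definition (`type = 7`, inclusive linear interpolation between closest
ranks). The definition is a named argument because statistical packages
disagree on percentile conventions and users may need to match one.
Boundary ties go to the lower quintile, which makes assignment monotone
and total; a degenerate all-equal reference puts every value in
quintile 1.

## The synthetic generator

`generate_data_model()` / `generate_cohort()` emulate the *structure* the
engine assumes: a bundle with every part-2 tag represented, a without-fat
food with nonzero uptake, full Schofield coverage, 14 food groups; cohorts
aged 40–79 with per-line frequencies weighted toward the lower categories,
missing/legacy sentinels and dual `a;b` cells injected at configurable
rates, and part-2 free text drawn from the reference lists with
single-character typos (which guarantee exact-match failure and hence
default assignment). One integer seed drives all randomness; identical
seeds give byte-identical files.

What it does **not** emulate: realistic diet composition, nutrient
correlations, sex differences in intake, seasonal or secular trends, or
the real instrument's food list. Passing tests therefore demonstrate the
correctness of the *processing* — conservation, aggregation identities,
exclusion semantics, ranking machinery — not the nutritional realism of
any output. One structural consequence worth knowing: because part-2
substitution swaps codes *within* the milk, cereal and fat groups, food-
group gram totals are invariant to the text-matching toggle in these
fixtures, while nutrient totals shift; the acceptance suite asserts
exactly that contrast. (With real data the group totals can also move
when reference lists cross group boundaries, e.g. excluding porridge from
a cereal list.)

## Numerical conventions

* All arithmetic in double precision; values are rounded only at
  serialisation (default 6 significant digits, `round_digits`, `NA` to
  disable).
* Mapping proportions must sum to 1 within 1e−9 (text files carry short
  decimals; anything farther off is a data error, not rounding).
* Unknown food codes are processed as zero nutrients with an ERROR log
  entry — the log, not the exit code, is the audit trail — unless the
  engine runs in `strict` mode.
* Logs follow the fixed grammar `<ISO8601>\t<LEVEL>\t<id>\t<message>`;
  determinism checks mask the timestamp field.

## Problem sizes

The test and acceptance suites run at desk scale by design: the micro
bundle has 5 lines, 12 foods and 3 nutrients with hand-computable
expectations; generated toy bundles use 10 lines × 12 foods ×
8 nutrients; the engine-vs-oracle equivalence sweeps 100 seeded cohorts of
2 participants; ranking checks use 20 000 synthetic values and the tail
oracle runs up to n = 25 102. The full-scale *shape* (130 lines,
46 nutrients, 14 groups) is exercised once through the `fullscale` preset.

## Limitations

* No nutrient retention or cooking-loss modelling, and no supplements.
* No fuzzy text matching; unmatched free text means the default code.
* Quintile conventions other than `type = 7` must be selected explicitly
  to reproduce other software.
* The engine trusts the data model: a questionnaire whose lines'
  proportions intentionally sum below 1 (waste fractions) is not
  representable — proportions must sum to exactly 1.
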