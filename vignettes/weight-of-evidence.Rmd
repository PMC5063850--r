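---
title: "Categorizing rat carcinogenicity by weight of evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Categorizing rat carcinogenicity by weight of evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carcwoe)
library(dplyr)
```

## The model

`carcwoe` treats the prediction of a 2-year rat carcinogenicity outcome as a
two-stage screening rule over evidence available after the subchronic
(3- and/or 6-month) study.

**Stage 1** scores a compound subchronic-positive if and only if its
subchronic study reported putative preneoplastic lesions. The operative
assumption, supported by the reference data, is that only proliferative
lesions — cellular hyperplasia, atypical foci of cellular alteration,
cellular proliferation, dysplasia — are risk factors for later neoplasia,
while greater organ weights and cellular hypertrophy are adaptive. The
transcription of the reference dataset folds all proliferative lesion types
into the hyperplasia column, so in code the rule is simply: hyperplasia
column non-empty. Crossing that with tumor presence in the 2-year study
yields TP/FP/FN/TN.

**Stage 2** assigns a category from pharmacological class knowledge. The
package computes each class's tumor fraction and calls it positive
(fraction ≥ 0.75), negative (≤ 0.25) or mixed, with closed boundaries: the
source class tables place a 75 % class among the positives, which fixes
`>=`/`<=` rather than strict inequalities. The thresholds are configuration
(`class_outcome(fraction, positive_threshold, negative_threshold)`), not
constants, so their influence can be explored. However, the per-compound
category does **not** come from the fraction: the transcribed decision table
is authoritative, because the source decisions incorporate literature
judgment that no counting rule reproduces. Two instructive cases: the
immunosuppressives show zero rat tumors in the dataset yet are decided TP
(immunosuppression is an accepted human cancer risk factor), and the
alpha-1 adrenergic antagonists are decided TP on a recurring mammary-gland
signal despite a mixed tumor fraction. `run_pipeline()` reports the
automatic outcome *next to* the expert decision in `class_summary` so every
disagreement stays visible.

Compounds that are their class's single representative carry a per-compound
recorded decision (`singles.csv`); all 52 such rows are flagged
`single_in_class` in the fixture. Every compound therefore resolves through
exactly one decision path, a property the test suite asserts.

**Combination.** `cat_ph` ∈ {TP, TN} overrides; {NT, NC} falls back to
`cat_his`. The override file ships with exactly two rows (compounds 161 and
184), the only records whose published final category deviates from the
closed-form rule; each cites its rationale. Users may extend the file.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `positive_threshold` | 0.75 | class tumor fraction called positive (closed) |
| `negative_threshold` | 0.25 | class tumor fraction called negative (closed) |
| `rounding` | `"half_away"` | reporting convention for percentages |
| relevance rules | packaged CSV | rat tumor types not predictive for humans |
| overrides | packaged CSV | per-compound final-category exceptions |

Rounding deserves a note: the source reports percentages rounded
inconsistently. Nearest-integer, half away from zero reproduces 14 of the 16
printed stage percentages; the final-stage positive predictivity (raw
98.53) and specificity (raw 99.51) are printed floored (98/99). The package
therefore always reports raw values alongside rounded ones and accepts
`rounding = "floor"` or `"none"`, so either convention is checkable.

## The human-relevance rule set

False negatives are refined by asking whether *every* tumor a compound
induced is of a type common in aged rats and not considered predictive for
humans. Rules are organ/morphology pairs with wildcards; the most specific
match wins (exact pair, then organ wildcard, then morphology wildcard) and
unmatched types default to human-relevant — the conservative choice for a
screening context. The packaged rule set encodes the spontaneous-tumor
reading of that criterion: all benign morphologies, plus organ-level rules
for pancreatic (acinar and islet), adrenal-medullary, Leydig-cell, thyroid
follicular, adenohypophysis, forestomach, urinary-bladder, hepatocellular
and mammary tumors, mononuclear-cell leukemia, and endometrial stromal
polyps. A narrower reading that accepts hepatocellular and mammary
carcinomas as human-relevant is defensible toxicologically; with the
packaged set the 96 histopathological false negatives of the reference
dataset split 77 non-relevant / 19 relevant, and each of the 19 bears a
malignant tumor of kidney, uterus, colon, skin/soft-tissue, lymphoid or
Zymbal's-gland origin. The peroxisome-proliferator flag (set for the
fibrate class) additionally voids liver-tumor relevance per compound, a
mechanism-conditional exception that stays active even under user-supplied
rule sets without liver rules.

`refine_false_negatives()` reports the matched bucket and the count of
relevant findings per compound, so any disputed call can be traced to a
rule. The post-filter metrics (`res$post_filter`) re-score non-relevant
false negatives as true negatives under three readings of "moved set"
(histopathological FNs, final FNs, union), since the prose definition is
ambiguous; they are reported, never asserted.

## Transcription decisions

The fixture is a hand-checked transcription of the source summary table.
Four cells required editorial decisions, all forced by cross-checks against
the table's own aggregates: one compound's damaged hyperplasia cell is
encoded with the organ token `unsp` ("organ not specified") rather than a
guessed organ; one compound's organ list was restored to the hypertrophy
column (its published category proves it is not hyperplasia, and the
organ-weight histogram proves it is not a weight finding); one `te`/`tes`
spelling and one free-text tumor cell were normalized. Two vocabulary
entries (`ce` = cecum, `most` = osteosarcoma) are context inferences and
carry low-confidence notes. One descriptive share cannot be reconciled: the
fully-silent true-negative screen yields 98 compounds from the transcribed
table, not the 99 stated in the source prose; every independently checkable
aggregate of the same columns matches the transcription exactly, so the
package reports what the table implies.

## The synthetic generator

`simulate_compounds()` emulates only the categorical structure the analysis
consumes: compounds grouped in classes, a per-class carcinogenicity rate,
hyperplasia arising with probability `hyperplasia_sensitivity` in
carcinogens and `hyperplasia_fpr` otherwise, the hyperplasia organ agreeing
with a tumor organ with probability `same_organ_prob`, and tumor types drawn
from non-relevant versus relevant pools with probability
`nonrelevant_tumor_fraction` per draw. Defaults are the empirical operating
characteristics of the reference dataset (prevalence 0.44, sensitivity
0.24, false-positive rate 0.12, concordance 0.42, non-relevant fraction
0.80, hypertrophy 0.23 and weight-finding 0.26 rates). It does **not**
simulate doses, pharmacokinetics, lesion severities, organ-specific
mechanisms, or the correlation between a class's pharmacology and its tumor
spectrum — so passing simulation tests demonstrate that the pipeline's
bookkeeping and estimators behave, not that the biology generalizes.

All draws flow from one seed through a local RNG scope; the caller's random
stream is untouched, and a fixed configuration is bit-reproducible.
Parameter recovery is exercised at two scales chosen to keep the suite
fast: 200 replicates at the reference-dataset size (~290 compounds)
against analytic binomial expectations, and one dataset of ~10^4 compounds
in which recovered stage-1 sensitivity and specificity must sit within
three binomial standard errors of the configured values.

## Degenerate inputs and numerical choices

* Zero-denominator metrics (e.g. sensitivity with no carcinogens) are
  first-class `NA` values flagged `undefined`, never exceptions.
* Empty findings cells accept `-`, the typographic dash, or the empty
  string; repeated tokens are preserved on parse and deduplicated only
  where the operation calls for organ sets (concordance).
* Organ codes may contain an internal space (`soft t`); tumor tokens split
  organ from morphology on the last space.
* Token comparison is case-insensitive except for canonically all-caps
  codes (`SCC`, `SCP`, `UGT`).
* Category enums are validated at every stage boundary; unknown classes,
  duplicate ids and unresolved tokens raise classed errors carrying the
  offending token and row.

## Known limitations

The pipeline reproduces a retrospective evaluation; it does not assess
genotoxicity (the reference compounds are all non-genotoxic by selection),
dose matching between study pairs, or mouse data. The class-decision and
relevance knowledge bases are transcriptions of expert judgment — the
package applies them, it cannot re-derive them — and extending the dataset
with new compounds requires extending those knowledge bases with the same
care.
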