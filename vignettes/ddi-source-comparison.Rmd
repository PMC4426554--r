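---
title: "Comparing drug-drug interaction sources at the ingredient level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing drug-drug interaction sources at the ingredient level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddicompare)
```

## The problem

Drug–drug interaction (DDI) knowledge bases disagree: two well-maintained
public sources can each list on the order of ten thousand interactions yet
share only a quarter to a third of them. Before that disagreement can be
measured, the sources must be made comparable. One source may list
*diltiazem hydrochloride* where another lists *diltiazem*; one may carry
clinical products, another only active moieties. `ddicompare` normalizes
heterogeneous DDI lists to a single representation — unordered pairs of
base ingredients in a shared terminology — and then measures overlap,
reference coverage, ATC class-pair similarity, and detection rates on
prescription data.

## The normalization model

The terminology distinguishes three concept levels, mirroring the
structure of ingredient-oriented drug nomenclatures:

* **ingredient** — a base active moiety (diltiazem);
* **precise ingredient** — a salt or ester of an ingredient (diltiazem
  hydrochloride), linked to its base;
* **clinical drug** — a dispensable product (Lovastatin 20 MG Oral
  Tablet), linked to one or more ingredients and carrying a route class
  (systemic or topical).

Normalizing a raw interaction record proceeds in a fixed order, and every
discarded record is attributed to exactly one cause:

1. **Name mapping.** Each drug name is looked up by exact match on the
   preferred name, then by normalized match (case-folded, whitespace
   collapsed, the punctuation `,.;:'"()/-` removed). A record with an
   unmappable name — including hits on obsolete concepts — is discarded
   (`unmapped_ddis`). The normalization rules are a deliberate local
   stand-in for the fuzzier matching a terminology web service performs;
   they are deterministic and hermetic, which matters more here than
   recall on misspelled names.
2. **Product rejection.** A name resolving to a clinical drug is
   discarded (`multi_ingredient_dropped`): interaction lists under
   comparison assert pairs of moieties, not products, and silently
   expanding a product would manufacture interactions the source never
   asserted. Product expansion is reserved for prescription screening,
   where it is the point.
3. **Salt collapse.** Precise ingredients map to their base. A pair whose
   two members collapse to the same ingredient is dropped
   (`self_pairs_dropped`): a self-interaction is meaningless at the
   ingredient level.
4. **Canonicalization and deduplication.** Pairs are stored with members
   in lexicographic order (object/precipitant roles are not needed for
   matching) and duplicates collapse (`collapsed_duplicates`). When
   duplicates disagree on severity the maximum is kept
   (critical > significant) — the conservative choice for alerting. Free-
   text descriptions merge to the lexicographic minimum so that the
   result is independent of input order.

The audit report satisfies, on every run,

```
output_size = total_input − unmapped_ddis − collapsed_duplicates
              − self_pairs_dropped − multi_ingredient_dropped
```

and this conservation identity is asserted inside `normalize_ddi_list()`
itself, not only in the test suite.

## Comparison statistics

All percentages are rounded **half-up to integers**, computed in exact
integer arithmetic (`round_percent()`); this convention reproduces the
printed coverage figures of the published analyses this pipeline follows
(e.g. 207/360 → 58, 2801/9392 → 30, 328/360 → 91).

Reference coverage is reported per group and in total; the total is
computed on the deduplicated union of group pairs, so a pair shared by
two groups counts once. Severity-stratified coverage partitions one
source's pairs by its severity annotation and measures coverage of each
stratum; the strata recompose the overall shared count exactly before
rounding.

For class-pair analysis, ingredients map to their 4th-level ATC classes.
Two open choices were closed as follows:

* A DDI with an ATC-less member is excluded and counted, never guessed
  into a class.
* An ingredient with several classes fans out to **every** class-pair
  combination; no primary-class heuristic is applied. Consequently the
  sum of per-class-pair shared counts can exceed the plain intersection
  size; equality holds exactly in the single-class case, and the test
  suite asserts both directions.

Same-class pairs are legal and keyed `(c, c)`. The Jaccard score is kept
at full precision and rounded to two decimals only for display.

## Prescription screening

Medication lists are screened in three steps: topical products are
removed (interaction lists at the ingredient level concern systemic
exposure); the remaining clinical drugs are paired; each drug pair
expands to the cross-combination of the two drugs' ingredient sets, so
a one-ingredient drug co-prescribed with a two-ingredient combination
yields two ingredient pairs. Within one list, a duplicate canonical pair
counts once — one list is one co-prescription event — and ingredient
self-pairs contribute nothing. Each list may carry a repeat count, which
weights its pairs' occurrence totals. "Matched by both sources" is
computed on the intersection of the two sources' pair sets, not on
per-source match events.

## The synthetic-data generator

Real DDI releases and prescription extracts are licensed snapshots;
the generator instead emulates their statistical structure with exact
bookkeeping. A generated bundle contains a terminology (configurable
salt rate, multi-ingredient and topical product rates, partial ATC
coverage), two DDI sources with a **planted overlap**, salt-form name
noise (records re-emitted under a salt name, which must collapse back),
out-of-terminology names (which must be discarded and counted),
reference groups, and prescription lists with dedicated co-prescription
events for chosen pairs.

Defaults describe the study conditions the package is exercised under:
two sources of equal size with 30% mutual overlap, a two-level severity
mix (a third critical), salt forms on 30% of ingredients with one in
five records emitted in salt form, 5% unmappable records, 15%
combination products, 10% topical products, 85% ATC coverage, and
prescription lists averaging four drugs. Where the emulated analyses
state a figure (the ~30% cross-source coverage, the two-level severity
annotation, topical exclusion, multi-ingredient expansion) the defaults
follow it; the remaining rates are fixed once at values typical of
ingredient-level drug data and are not tuned afterwards.

Because normalization is deterministic set algebra, recovery tests are
**exact**: the measured overlap must equal the planted overlap, the
audit counters must equal the generator's ledger, and screening totals
must equal an independent nested-loop recount that the generator
performs over its own emitted CSV (kept deliberately separate from the
streaming implementation in `screen()`). Any deviation is a bug, not
sampling error. List lengths follow a truncated geometric distribution
(minimum 1, capped at 10) since no empirical list-length distribution
is available.

What the generator does **not** emulate: real pharmacology (which
ingredients plausibly interact), the class composition of real sources,
misspelled names, and temporal structure in prescriptions. Passing the
recovery suite therefore demonstrates correctness of the set algebra
and accounting on data with the right shape, not fidelity to any real
release.

## Numerical and scale choices

Everything downstream of name mapping is integer set algebra; the only
floating-point quantity is the Jaccard score. Identifier ordering uses
plain string comparison, and generated identifiers use a single case so
ordering does not depend on locale collation. The test suite runs the
full pipeline on bundles of 30–220 interactions per source across ~25
seeds and on random fixtures of up to ~200 pairs for the brute-force
oracles — sizes at which exhaustive nested-loop oracles stay trivially
fast while exercising every discard path; the set algebra itself is
size-independent.

## Known limitations

* Name matching is exact-after-normalization; no fuzzy matching or
  spelling correction (a misspelled salt form maps only if the
  terminology contains the same spelling).
* Name-index collisions after normalization abort terminology loading;
  no disambiguation rule is applied.
* Obsolete concepts are loadable but invisible to lookup; records
  referencing them are counted as unmapped rather than resolved
  historically.
* The reference fixture's curated groups are shipped as names only;
  matching them into a terminology inherits that terminology's
  coverage.
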