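# ddicompare

Tools for evaluating and comparing drug–drug interaction (DDI) knowledge
sources at the ingredient level.

Clinical decision support systems screen medication lists against DDI
knowledge bases, but public sources disagree substantially about what
constitutes an interaction. Comparing them fairly requires putting every
source on a common footing first: drug names must be mapped to a shared
terminology and salt or ester forms (*precise ingredients*, e.g.
doxacurium chloride) collapsed to their base ingredient (doxacurium),
with every record that cannot be mapped accounted for. `ddicompare`
implements that normalization pipeline and the comparisons that sit on
top of it, for anyone evaluating DDI content: terminologists, CDS
implementers, and drug-informatics researchers.

## What it computes

Let `A` and `B` be two DDI sources normalized to sets of unordered
ingredient pairs. The package quantifies:

- **Cross-source overlap** — `|A ∩ B|`, source-specific counts, and the
  mutual coverage percentages `100·|A∩B|/|A|` (all percentages rounded
  half-up to integers).
- **Reference coverage** — coverage of a curated reference list of
  high-severity interactions, defined as groups of object drugs crossed
  with precipitant drugs, reported per group and in total, and
  stratified by the two-level severity annotation (`significant` /
  `critical`) when a source carries one.
- **Class-pair similarity** — after abstracting ingredients to their
  4th-level ATC classes, the per-class-pair Jaccard score
  `J = shared / (shared + onlyA + onlyB)`, which localizes where two
  sources disagree.
- **Prescription screening** — expansion of patient medication lists to
  all unordered ingredient pairs (topical drugs excluded,
  multi-ingredient clinical drugs fanned out to every ingredient
  combination) and the per-source match totals and top co-prescribed
  interacting pairs.

A synthetic-data generator produces a full study bundle — terminology
with salts and combination products, two sources with a planted
overlap, reference groups, prescription lists — together with an exact
ground-truth ledger, so every stage is tested by set-level equality
rather than statistical tolerance.

## Worked example

```r
library(ddicompare)

cfg <- generator_config(seed = 7, size_a = 100, size_b = 100, planted_overlap = 30)
b   <- generate_bundle(cfg, "bundle")

term <- load_terminology(b$paths$concepts, b$paths$relations, b$paths$atc)
na <- normalize_ddi_list(read_ndfrt_records(b$paths$ndfrt), term)
nb <- normalize_ddi_list(read_drugbank_xml(b$paths$drugbank), term)

na$report
#> <ddi_norm_report>
#>   total_input              112
#>   unmapped_ddis            5
#>   unmapped_drugs           5
#>   collapsed_duplicates     7
#>   self_pairs_dropped       0
#>   multi_ingredient_dropped 0
#>   output_size              100

compare_sets(na$set, nb$set)
#> <ddi_overlap> NDFRT (n=100) vs DRUGBANK (n=100)
#>   shared 30 | only NDFRT 70 | only DRUGBANK 70
#>   coverage of NDFRT by DRUGBANK: 30%; of DRUGBANK by NDFRT: 30%
```

The report reads: of 112 raw records in the tabular source, 5 carried a
name absent from the terminology and were discarded, 7 were salt-form
duplicates that collapsed onto an existing base-ingredient pair, and
100 canonical pairs remain. The overlap report then recovers exactly
the 30 planted shared pairs — a 30% mutual coverage rate.

Screening prescription lists against both sources:

```r
lists <- read_prescriptions(b$paths$prescriptions, term)
screen(lists, list(NDFRT = na$set, DRUGBANK = nb$set), term)
#> <ddi_screening> 2236 pair occurrences, 2144 unique pairs
#>   matched by NDFRT     total=18 unique=6
#>   matched by DRUGBANK  total=17 unique=5
#>   matched by both:    total=15 unique=3
```

The packaged reference fixture (`reference_groups_file()`) holds 12
curated groups of high-severity interactions; `build_reference_set()`
expands them to 360 unique drug pairs over 86 unique drugs.

A command-line front end is installed at
`system.file("cli", "ddicompare", package = "ddicompare")` with
subcommands `normalize`, `compare`, `classmap`, `screen` and
`simulate`.

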