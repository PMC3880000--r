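---
title: "Comparative chromosome painting: model, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative chromosome painting: model, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyopaint)
```

## The analysis in one paragraph

Cross-species chromosome painting (Zoo-FISH) hybridizes whole-chromosome
paints of one species onto metaphases of another, revealing which blocks of
each target chromosome descend from which probe chromosome. karyopaint
encodes such experiments as *homology maps* — ordered painted blocks in
ordinal cytogenetic coordinates — and derives from them the quantities a
comparative cytogeneticist reports: fundamental numbers, counts of conserved
chromosomal regions, intact probe chromosomes, *syntenic associations* (two
probe chromosomes joined on one target chromosome, the cladistic character
unit), composition of maps into human (HSA) segment space via a pivot
species, disruption of Evolutionarily Conserved Units (ECUs), and
plesiomorphy inference. Association characters are then polarized with an
outgroup and placed on a fixed molecular phylogeny; a Fitch parsimony
engine with exhaustive enumeration of most parsimonious reconstructions
(MPRs) serves as the internal oracle for placement ambiguity. A
karyotype-evolution simulator with known ground truth closes the loop.

## The packaged dataset

The package ships a comparative painting dataset for four phyllostomid
bats: probes from *Macrotus californicus* (MCA, 2n = 40, FN = 60; 19
autosomal paints plus X) hybridized onto *Glossophaga soricina* (GSO,
2n = 32, FN = 60), *Anoura cultrata* (ACU, 2n = 30, FN = 56) and
*Lonchophylla concava* (LCO, 2n = 28, FN = 50), with the molecular
topology `(((GSO,ACU),LCO),MCA)` and MCA as outgroup. The fixtures are
plain TSV under `inst/extdata/` and are themselves the unit under test:
every acceptance statistic is recomputed from them at run time.

Encoding conventions worth making explicit:

* **Coordinates are ordinal.** A block's position is its pter-to-qter rank
  on the target chromosome (`order_index`), never base pairs. Adjacency
  means consecutive rank; qualifier letters (`t`erminal, `p`roximal,
  `i`nterstitial, `d`istal) address positions within an arm, and composite
  labels such as `12p/qp` mark one contiguous block spanning the
  centromere.
* **Gaps are explicit.** Unpainted material (heterochromatin, the
  NOR-bearing short arm of GSO 15) appears as dedicated gap rows, so
  "contiguous" is decidable. A gap breaks runs and adjacency, and a target
  chromosome carrying a gap row is not fully accounted for by any probe —
  which is why MCA 19, a single conserved block on the bi-armed GSO 15,
  is *conserved* but not *intact*.
* **Block boundaries follow the hybridization figures, not just the arm
  table.** At pure arm granularity the GSO map tallies 23 same-source
  runs; the packaged fixture separately encodes the two MCA 5-derived
  signals on GSO 1p (split by unpainted heterochromatin), which yields the
  reported 24. Likewise LCO 8 is encoded as three signals
  (MCA 7 | MCA 13 | MCA 3), giving the reported LCO total of 26.
* **Ambiguity is preserved, never silently resolved.** Rows like
  "MCA 2p → ACU 7 *or* 9" keep both alternatives in an `alternatives`
  channel. In this dataset every such alternative names the *same* source
  chromosome (only the arm assignment is open), so the source chromosome —
  and hence every chromosome-level statistic — remains certain. Blocks
  whose alternatives name a *different* source chromosome are excluded
  from shared-association claims and from ECU disruption counts.

## Definitions used by the statistics

* **FN** — diploid count of autosomal arms: acrocentric = 1 arm per copy,
  subtelocentric/submetacentric/metacentric = 2; sex chromosomes excluded.
* **Conserved region** — a maximal run of consecutive blocks on one target
  chromosome sharing a single source chromosome. A centromere-spanning
  composite is one run; same-source blocks separated by another source's
  block (or a gap) are distinct runs.
* **Intact** — all blocks of a source chromosome land on one target
  chromosome that carries nothing else (no other source, no gap).
  Inversions do not break intactness: synteny is conserved.
* **Syntenic association** — an adjacent pair of different-source runs. A
  target chromosome combining three sources contributes its *chain* of
  pairwise adjacencies, not all pairs: the characters model pairwise
  fusion products. Tandem and centric fusions are not distinguished in
  the association identity.
* **ECU disruption** — an ECU (one unit per probe chromosome arm; the
  packaged table has 25) is disrupted in a species when its content sits
  on two or more chromosomes of that species.
* **Plesiomorphic chromosome** — intact in the outgroup and in at least
  one ingroup taxon.
* The X chromosome is computed everywhere but excluded from every
  *autosomal* report, and is asserted intact in all four species.

## Character mapping

Association characters are binary (presence/absence), with the outgroup
forced to 0 — the probe karyotype defines absence — and the root state
constrained to the outgroup state when computing parsimony. Under that
convention the packaged data give: `13/3` a unique single gain at the
nectar-feeder ancestor; `9/17` and `18/5` synapomorphies of the GSO+ACU
clade; and `16/19`, present in ACU and LCO but not GSO, *two* tied MPRs
(two independent gains vs. gain at the ingroup ancestor plus loss in GSO).
The placement rule never infers a loss — non-monophyletic presence is
reported as convergent terminal gains — but the report flags every
character whose placement is not the unique MPR, so the divergence between
the rule and the Fitch engine is surfaced, not hidden. For the chromosomes
whose ancestral morphology is assumed acrocentric (13, 17, 18) the matrix
carries an `assumed-acrocentric-ancestor` annotation.

Ties in reports are broken deterministically: characters are ordered by
their canonical names (the conventional orderings `13/3`, `9/17`, `18/5`,
`16/19` are kept for the named associations; all other pairs are written
ascending), nodes by their sorted leaf sets. Re-running the analysis on
identical inputs yields byte-identical JSON.

## The simulator

`simulate_history()` evolves a root karyotype along a tree. Chromosomes
are ordered lists of uniquely labeled arm segments — the atomic unit is
the ancestral chromosome arm, so content conservation is checkable as a
multiset identity, and arm- versus block-resolution painting projections
coincide by construction (no sub-arm breakpoints arise). Event kinds:

| kind | effect | 2n | FN |
|---|---|---|---|
| `rb_fusion` | two acrocentrics → one metacentric | −2 | 0 |
| `rb_fission` | bi-armed → two acrocentrics | +2 | 0 |
| `tandem_fusion` | end-to-end joining | −2 | −2 or −4 (arms lost) |
| `pericentric_inversion` | morphology toggles, synteny unchanged | 0 | ±2 |
| `whole_arm_translocation` | fission + crosswise fusion of two bi-armed | 0 | 0 |

Per-branch event counts are Poisson with mean rate × branch length. Event
feasibility is handled by rejection-resampling among the rate-positive
kinds that still have operands, with a fixed retry budget (default 100) —
simpler than rate renormalization, with a documented bias at extreme
rates; a fusion-only schedule that exhausts its acrocentrics errors out.
Randomness derives from a single root seed combined with a stable hash of
each edge's descendant tip set, so subtree simulations are reproducible
independent of traversal order. A pericentric inversion of a
single-segment acrocentric changes the morphology class while the new
short arm stays below paint resolution — the realistic outcome of a
centromere shift into a conserved block.

The default root karyotype mimics the hypothesized ancestral condition
discussed for this group: 22 autosome pairs, 8 of them bi-armed (2n = 46,
FN = 60), plus an inert X. No rates or branch lengths are known for the
system; the defaults (`rb_fusion = 0.5` per unit branch, unit ingroup
branches) are illustrative only.

`recovery_experiment()` runs the full chain — simulate, project paintings,
extract associations, build the matrix, place characters — and scores it
against the event log: fraction of fusion joints placed on their true
branch (overall and among single-origin joints), false-association rate
(associations observed at tips but never created by an event), and
recovery of the plesiomorphic set, whose truth is taken from an
independent replay of the event log rather than from the painting
projection path. At zero noise the projections are exact, so the false
association rate is 0 and single-origin placement accuracy is 1; accuracy
degrades monotonically as event density grows (homoplasy and overwritten
joints). The outgroup tip of the default recovery tree hangs on a
zero-length branch, which guarantees an identity outgroup profile without
special-casing.

## What the synthetic data do and do not show

The generator emulates the *structure* of painting data: ordered blocks,
fusions/fissions/inversions, whole-arm exchanges, ambiguous signal
assignment (the `noise` channel adds `or` alternatives between sources).
It does not emulate hybridization efficiency, repetitive-DNA
cross-hybridization, signal-strength limits on small segments, breakpoint
reuse, or rate heterogeneity across lineages. Green recovery tests
therefore certify the *pipeline logic* — that what the simulator wrote
down is what the analysis reads back — not the fidelity of any biological
rate model.

## Numerical and design choices

* Test and validation problem sizes: 1,000 random Fitch-vs-enumeration
  cases on trees of up to 8 leaves; 500 seeded histories for the
  conservation/determinism invariants; recovery trends over three rate
  multipliers (0.2, 1, 3) at 15–25 replicates each. These sizes give
  stable verdicts at interactive runtimes.
* The enumeration oracle refuses trees with more than 12 internal nodes
  (4,096 assignments) — beyond that the DP engine is the only route, and
  `mpr_count` is reported as `NA`.
* Morphology classes for a few MCA chromosomes are not fully determined
  by the published descriptions; the packaged karyotype fixes an
  assignment (8, 9, 12, 16 bi-armed; 14, 15 acrocentric) consistent with
  every stated morphology and with FN = 60. Only FN bookkeeping depends
  on it.
* `ecu_id` for composite units is the full segment-composition string
  (e.g. `5a:7b:16b`); single-segment units read naturally (`11a`).
* Degenerate inputs: empty karyotype files, single-leaf trees, empty ECU
  tables, all-zero characters and maps without associations all have
  defined behavior (error or empty result, never silent nonsense).

## Known limitations

* Intra-arm breakpoint order beyond the fixture-encoded block order is
  out of scope, as is ancestral gene-order reconstruction.
* The composition operator is content-oriented: composing through a
  multi-block source region concatenates content with `+`; associativity
  holds on segment-tracing chains where each region resolves to a single
  region.
* No likelihood model, no branch lengths in inference, no tree search:
  the topology is a fixed input, and parsimony is the only optimality
  criterion.
* The placement rule is exactly the published convention; where it is not
  the unique MPR (e.g. `16/19`) the report says so rather than choosing.
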