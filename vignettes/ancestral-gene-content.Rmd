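---
title: "Ancestral gene content by single-gain parsimony: model, assumptions, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral gene content by single-gain parsimony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lecatrace)
```

## The model

`lecatrace` reconstructs the history of gene-family components on a rooted
reference tree from binary presence/absence data under a Dollo model: each
component is **gained exactly once** and afterwards can only be **lost,
never regained**.  The biological justification is that horizontal gene
transfer between eukaryotes is rare, so independent re-invention of an
orthologue is far less plausible than repeated loss.

Three verbal inference rules follow from this model and are what the engine
implements:

1. presence in two lineages implies presence in their last common ancestor
   (the gain node is the MRCA of all presence tips);
2. absence in *every* sampled descendant of a group is read as ancestral
   absence of that group — each maximal such subtree inside the gain
   subtree is one loss event;
3. presence in an ancestor and in one descendant implies presence at every
   node in between (reconstructed states are connected along paths).

Fixing the gain at the MRCA minimizes the loss count among all single-gain
placements: moving the gain to any strict ancestor of the MRCA adds at
least one all-absent child subtree.  `dollo_oracle()` verifies this by
exhaustive enumeration on small trees and is kept as an independent code
path (recursion over subtree tip sets) from the production `dollo_infer()`
(post-order counting); the test suite sweeps all 945 rooted binary six-tip
topologies against it.

**LECA status.**  The root of the reference tree models the Last Eukaryotic
Common Ancestor under the unikont–bikont rooting; because that rooting is
itself a hypothesis, the root bipartition is configuration, not code
(`sides` in `read_ref_tree()`, or derived from the taxon map).  Two rules
are reported side by side and deliberately *not* merged:

* **MRCA** (default): present in LECA iff the gain node is the root —
  equivalently, at least one lineage on each side of the root carries the
  component.
* **CONSERVATIVE** (`k = 2` default): at least *k* major lineages on
  *each* side.

Both are defensible readings of published practice: the stricter two-per-
side criterion is invoked for the core APC/C subunits, yet cohesin-loading
factor Scc4 and Wpl1/Rad61 — each with a single bikont witness — are still
counted ancestral in the 24-component inventory.  Only the MRCA rule
reproduces that inventory, so it is the default; the conservative count
(22) is always available, and the package asserts the nesting property
CONSERVATIVE-PRESENT ⇒ MRCA-PRESENT rather than a single "true" rule.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `mode` | `classify_leca`, CLI `--mode` | `MRCA` | root-ancestor rule (above) |
| `k` | `leca_rule`, CLI `--k` | 2 | min lineages per root side (CONSERVATIVE) |
| `max_missing` | `filter_taxa`, CLI `--threshold` | 0.60 | drop taxa with missing-data fraction above this (dimensionless, fraction of supermatrix columns) |
| `p_root` | `simulate_content` | 1 | probability a simulated component is gained at the root |
| `loss_rate` | `simulate_content` | 0 | expected loss events per unit branch length (Poisson) |
| `censor_missing` | `simulate_content` | 0 | per status-P genome, probability a present component is unobserved |

The 0.60 missing-data cutoff mirrors the filter used when the original
supermatrix discarded its most incomplete taxa ("> 60 % of missing data");
it is a convention, not an estimated quantity.

## Categorical profiles and their dialect

Published lineage-distribution tables print, per lineage × component, the
fraction of sampled species carrying an orthologue as a coarse category.
The reader normalizes every printed spelling — `100`; `≥50`, `>=50`, `>50`
(a typographic rendering of ≥), `Half`, `50`; `< 50`; blank — to the closed
set `ALL / GEQ_HALF / LT_HALF / ABSENT`, and errors with cell coordinates
on anything else.  The boundary case f = 0.5 (e.g. 1 of 2 sampled
choanoflagellates) is GEQ_HALF, matching the printed "Half"/"50" cells.
For ancestral inference *any* category except ABSENT counts as lineage
presence: a component retained by a minority of species in a lineage was
still present in that lineage's ancestor under Dollo.  Lineage profiles are
treated as primary data: the species counts behind each printed cell are
not recoverable, so profiles are binarized, not re-derived.

## What the simulator emulates — and what it does not

`simulate_content()` draws, per component: a gain (root with probability
`p_root`, else a uniformly chosen edge), then along each edge below the
gain a Poisson number of loss events with mean `loss_rate ×` branch length
(unit lengths when the tree has none); one or more events kill the whole
descendant subtree, and multiple events on one branch collapse to one loss
(presence is binary).  Optional censoring flips truly-present cells to
absent in genomes flagged `P` (ongoing sequencing), modeling the caveat
that losses inferred in incomplete genomes are tentative.

Defaults used in validation are the stated world of the analysis: a gain at
the root (`p_root = 1`, the LECA-inventory regime), loss rate 0.2 per unit
branch — a moderate-loss regime in which most components survive in most
lineages, as observed for the APC/C — with 2,000 replicate components for
calibration against the closed-form expectation
`E[losses] = Σ_e P(parent of e alive) · (1 − exp(−λ·len(e)))`.

The generator deliberately consumes its full randomness lattice (gain draw,
every edge's Poisson, every censorable tip's uniform) regardless of
parameter values, so runs at one seed are coupled across parameter
settings; censoring levels then produce *nested* absence sets, which is
what makes the "censoring only moves the inferred gain tipward" sweep a
deterministic property rather than a statistical one.

A green simulation test establishes that the engine is a correct Dollo
reconstructor for data generated under the Dollo model.  It does **not**
establish robustness to what real data add: orthologue-calling errors,
divergent sequences escaping homology detection (apparent loss), hidden
paralogy, or horizontal transfer.  Alignments from `simulate_alignments()`
are occupancy scaffolds of i.i.d. residues with no substitution model; they
validate supermatrix bookkeeping only.

## Numerical and design choices

* **Polytomies** are preserved exactly as read; under Dollo each child of a
  multifurcation is an independent subtree for loss counting.  The bundled
  reference topology keeps the bikont interior and the
  Opisthokonta/Apusozoa/Amoebozoa split as polytomies rather than inventing
  resolution; root-ancestor verdicts depend only on the root bipartition
  and are unaffected, while per-branch loss placement inside those regions
  is (and is documented as) resolution-dependent.
* **Internal node labels**: unlabeled internal nodes get deterministic
  `N<preorder index>` labels so event reports have stable addresses; named
  ancestors (LECA, Opisthokonta, …) in the input are preserved.
* **Missing data accounting** counts whole-partition absence only; `-` gaps
  inside present sequences are alignment information, not missingness.  A
  `gaps_as_missing` flag provides the inclusive accounting.
* **Determinism**: all writers emit byte-identical output for identical
  input (sorted component order, binary-mode connections, fixed numeric
  formatting); the annotated-Newick serializer is the package's own because
  per-node NHX tags cannot be attached through standard tree writers.
* **Degenerate inputs**: an all-absent component yields gain `NONE` /
  `NO_DATA` and is never counted ancestral (components such as the cyclins
  and Cdks, whose deep paralogy defeats orthologue assignment, enter the
  inventory this way); an empty matrix data section, a non-binary cell, an
  unmapped taxon, a ragged alignment and a filter that removes every taxon
  are all hard errors naming the offending element.
* **Genome statuses** for the lineage-level fixtures are unknown (the
  per-species completeness flags are only available in the original
  figure), so the packaged taxon map carries none and tentative-loss
  flagging is exercised on species-level synthetic data.

## Known limitations

* Only gene *content* is modeled: no birth–death rates, no probabilistic
  reconstruction, no transfer events; loss counts are parsimony minima and
  therefore lower bounds.
* The root-side tallies treat every major lineage equally regardless of how
  many species represent it.
* Supermatrix construction stops at concatenation, occupancy and filtering;
  alignment, masking and tree inference are out of scope.
* The original sequence-derived quantities (alignment positions, support
  values) require the primary sequence data and are not reproduced.
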