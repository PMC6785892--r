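---
title: "Curating non-redundant immune receptor-epitope structural benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating non-redundant immune receptor-epitope structural benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epibench)
```

## The problem

Receptor-specific epitope prediction methods — tools that predict what a
*given* antibody or T-cell receptor binds, rather than which antigen surface
patches are generically immunogenic — need training and evaluation sets of
receptor-antigen 3D complexes in which near-duplicate receptor-epitope pairs
have been collapsed. Redundancy in deposited structures is severe: the same
antibody is crystallized with point-mutant antigens, the same peptide-MHC
is solved with many TCR constructs, and full-sequence clustering of
receptors splits chains with identical binding loops into different groups
whenever their frameworks differ.

`epibench` implements a curation pipeline for three kinds of complexes —
antibody-antigen (Ab-Ag), TCR-peptide-MHC (TCR-pMHC) and MHC-ligand — that
filters structures on quality, computes interfaces from coordinates, and
clusters each branch on the features that actually determine recognition:
antigen sequence, receptor CDR loops, epitope 3D conformation, and the MHC
groove (G-domain) sequence.

## Data model and inputs

A complex enters the pipeline as a coordinate file (PDB or mmCIF, parsed via
`bio3d`) plus a curated annotation record (JSON) that assigns chain roles
(heavy/light, alpha/beta, MHC chains, antigen chains), the complex type, and
IMGT numbering for the receptor chains. Chain roles are taken from the
annotation, never inferred from sequence: role inference is a different
problem with its own failure modes, and curated databases already provide
roles.

Parsing policy:

* hydrogens are discarded; all geometry downstream is heavy-atom only,
  matching how deposited crystal structures are built;
* alternate locations collapse to the highest-occupancy conformer, ties
  resolved toward altloc `A`;
* residues are indexed 0-based in file order per chain — this is the order in
  which "first and last contacting residue" spans are evaluated — with author
  numbering retained only for reporting;
* modified residues with a defined parent (MSE, SEP, ...) read as their
  parent amino acid when they carry a CA atom; anything else is non-peptidic
  content. A chain with no standard residue at all is a non-peptidic ligand;
* water, ions and common crystallization additives never join a contact set.

IMGT numbering is an *input* (produced offline by a numbering tool, or
written directly by the fixture generator), not computed internally; this
keeps the package self-contained, with no profile-HMM database dependency.
Each numbered position may carry an explicit residue index (`NA` = the
residue has no coordinates); otherwise positions map 1:1 onto the chain's
standard residues in order. A letter disagreement between numbering and
structure is an error rather than a silent skip.

## Interfaces and core-epitopes

All contact computations use one rule: two residues are in contact when any
heavy-atom pair lies within **4.0 Å** (inclusive — the boundary convention
is documented rather than left implicit, and a fixture at exactly 4.0 Å is
part of the test suite).

* The **epitope** of an Ab-Ag complex is the set of antigen residues
  contacting any antibody chain; its heavy atoms form the binding site used
  for conformational comparison.
* The **core-epitope** of a TCR-pMHC complex (and the **core-peptide** of an
  MHC-ligand complex) is the *contiguous span* of the antigen chain from the
  first to the last residue within 4 Å of the TCR+MHC (resp. MHC) atoms.
  Non-contacting interior residues stay in; dangling overhangs are trimmed.
  With several antigen chains the longest per-chain span wins; no contacts
  at all yields a length-0 core that the minimum-length filter then removes.

## Quality filters

`filter_config()` carries the thresholds, applied in a fixed order
(resolution → R-free → missing CDR backbone → length) so attrition
accounting is reproducible; the order does not change the kept set.

| parameter | default | notes |
|---|---|---|
| `max_resolution` | 3.0 Å | inclusive: 3.0 Å is kept. Structures without a resolution value (e.g. NMR) are excluded while this filter is active. |
| `max_r_free` | disabled | enable by setting a value; R-free is read from the coordinate file header. |
| `drop_missing_cdr` | `TRUE` | a complex is dropped if any CDR position lacks a residue with coordinates or its residue lacks any of N, CA, C. Backbone means chain trace: a missing carbonyl O alone does not trigger the filter. |
| `min_antigen_len` | 50 residues | Ab-Ag only; counts resolved standard residues of the antigen chain. |
| `min_core_len` | 8 residues | TCR-pMHC and MHC-ligand core length. |
| `contact_cutoff` | 4.0 Å | used for epitopes, cores, and contact tables. |

## Clustering

Every threshold-based grouping uses **single-linkage connected components**
of the "similar" relation. The linkage is a deliberate design choice: it is
order-independent, gives the monotonicity property that raising an identity
threshold can never merge clusters (asserted in the tests), and errs on the
side of conservatism for benchmark curation — two complexes end up in
different clusters only if *no* similarity chain connects them. Items are
always processed in sorted structure-id order and clusters numbered by first
appearance, so labels are stable under input reordering.

* **Antigens** (Ab-Ag): global alignment identity (BLOSUM62, gap open 10,
  extend 0.5) at a 70% threshold. The identity denominator is the *shorter*
  sequence, so a resolved fragment clusters with its full-length parent;
  the alignment-length denominator is available as an option.
* **Receptors**: heavy and light (or alpha and beta) chains group
  independently on *exact* CDR1|CDR2|CDR3 identity (IMGT windows 27-38,
  56-65, 105-117). The complex label concatenates per-chain cluster indices
  (`H1_L2`, `A2_B1`); a single-chain receptor such as a nanobody keeps only
  its own prefix (`H3`). Because per-chain indices are embedded in the
  label, users can re-group by heavy chain only by truncating labels.
* **Epitope conformations** (Ab-Ag, within each receptor group): two binding
  sites are compared through their sorted lists of all intra-site heavy-atom
  pair distances. With `m` matched entries between lists of `p_a` and `p_b`
  distances, `PMax = m / max(p_a, p_b)` and `PMin = m / min(p_a, p_b)`. Two
  sites cluster together iff `PMax = 1`, or `PMin = 1`, or
  `PMin >= 0.9 and PMax >= 0.6`. Matching is a greedy two-pointer sweep over
  the sorted lists; on sorted inputs this attains the maximum matching, a
  fact the tests verify against an exhaustive bipartite-matching oracle
  rather than assume. Sites with fewer than two atoms (or no contacts) are
  singletons.
* **Core-epitopes / core-peptides**: sequence identity at 85%.
* **MHC molecules**: each MHC chain is searched against a G-domain
  reference set (class I α1-α2; class II α1 and β1) by local alignment;
  accepted hits must cover ≥ 85% of the reference (subject coverage) with a
  query span ≥ 90% of the reference length, and the best score wins. A
  class I complex clusters on its mapped α1-α2 sequence (`a<i>`), a class II
  complex on the (α1, β1) pair (`a<i>_b<j>`), and anything unmappable — or a
  class II pattern with only one mappable chain — is non-classical,
  clustered on full chain sequence (`n<i>`). Class I and class II `a`
  indices draw from one shared counter in first-appearance order.

A benchmark row joins its cluster labels into a pair-cluster id: Ab-Ag pairs
are (receptor, epitope-conformation); TCR-pMHC forms both the full
(core, TCR, MHC) clusters and the coarser (core, TCR) receptor-epitope
groups — the table reports both, and the full count is necessarily at least
the coarse count; MHC-ligand pairs are (core, MHC). One representative per
pair cluster is chosen: best (numerically lowest) resolution, ties broken by
lexicographically smallest id. Representative selection is reporting
convenience, not part of the clustering.

## Numerical choices

* **Distance-match tolerance `pm_tol` = 0.5 Å.** The binding-site comparison
  tool this scoring follows does not publish its internal tolerance; 0.5 Å
  is of the order of coordinate uncertainty in a ~2.5 Å structure and is the
  single most consequential free parameter in the conformational clustering.
  It is exposed in `filter_config()` and flagged here deliberately: results
  with a different tolerance are not comparable.
* The binding-site atom set is *all* heavy atoms of the epitope residues; no
  atom typing is attempted. This follows the sorted-single-list description
  of the published score rather than any finer-grained re-implementation.
* Alignment scoring (BLOSUM62, 10/0.5) is fixed across identity and
  G-domain searches; letters outside the BLOSUM alphabet read as `X`.
* The G-domain search ranks candidate hits by raw alignment score under the
  two printed coverage thresholds (90/85) instead of an e-value, which would
  depend on database-size parameters that are not meaningful for a
  user-supplied reference set. Note that with cheap gap extension a long
  random sequence can occasionally produce a gappy local alignment that
  passes both coverage thresholds; scores, not coverage alone, decide among
  candidates, but users screening large non-classical sets should treat
  borderline hits with suspicion.
* Boundary conventions are inclusive everywhere a threshold is quoted:
  resolution 3.0 Å is kept, a 50-residue antigen is kept, an 8-residue core
  is kept, a 4.0 Å atom pair is a contact, 70%/85% identity at the threshold
  joins a cluster.

## The synthetic corpus

`fixture_spec()` + `make_corpus()` generate a fully synthetic corpus —
coordinates, annotations, G-domain references, manifest — with planted
ground truth, so the entire pipeline is testable offline. Geometry is
deliberately minimal: serpentine chains with 3.8 Å CA spacing and five
heavy atoms per residue (N, CA, C, O, CB), enough for backbone-completeness
checks and exact contact control. Contact residues are placed so their CB
sits 3.7 Å above a target atom while every atom of any *other* residue
stays above 4 Å, making planted epitope and core residue sets exact under
the inclusive cutoff. Each complex is finished with a random rigid
rotation, which the distance-based machinery must (and does) ignore.

The plant controls, per complex: antigen family (within-family mutants at
~88% identity against a 70% threshold; distinct families far below it),
receptor CDR group (same CDRs under two different frameworks must merge),
epitope conformer (two templates differing in residue count and spread, so
cross-template PMax/PMin falls far below the clustering rule), core-peptide
cluster (1-mutation variants at 88.9% against the 85% threshold), MHC key
(class I grooves, one class II pair, one unmappable chain), and quality
defects (resolutions of 3.2-3.6 Å, an NMR entry with no resolution, a
missing CDR3 residue, a 45-residue antigen, a 7-residue core).

Expected counts are computed in closed form from the design table — never
by running the pipeline — and the generator additionally verifies the plant
with the similarity kernels (`stopifnot` on planted identities, scores and
G-domain recovery) at generation time. The standard profile holds 49
complexes (23 Ab-Ag, 14 TCR-pMHC, 12 MHC-ligand, including 7 non-peptidic);
the test suite runs the standard profile end to end and the minimal profile
(7 complexes) for fast checks, and an identical seed reproduces every file
byte for byte.

What the fixtures do *not* emulate: real antibody/TCR/MHC folds, rotamer
chemistry, crystal contacts, partial-occupancy disorder, engineered-construct
artifacts, or the curation judgement that removes biologically irrelevant
contacts. Passing the plant-recovery tests therefore demonstrates that the
*logic* — filters, interface definitions, scores, clusterings, counts — is
correct, not that the thresholds are optimal for any particular real
data set.

## Problem sizes in the test suite

The suite checks kernels against brute-force oracles at small sizes chosen
to finish in seconds while still exercising the combinatorics: 50 random
contact fixtures of 50-200 atoms per side, 150 random distance-list pairs of
length ≤ 8 against exhaustive maximum matching, 100 random sites for score
self-identity, 30 random ≤ 15-item relations against a BFS component oracle,
and the 49-complex standard corpus for end-to-end plant recovery and
byte-level determinism.

## Known limitations

* The conformational score follows the published *description* (one sorted
  distance list per site); the original binding-site tool bins distances by
  atom type, so absolute score values are not interchangeable between the
  two, even though the clustering rule is applied as printed.
* Chain-role annotation quality is inherited, not checked: a mislabelled
  chain propagates silently.
* Engineered-construct contacts (e.g. affinity tags packing against the
  antigen) are not detected; the published pipeline removes them by manual
  curation, for which no algorithmic rule exists.
* Identity clustering aligns whole sequences; domain-level identity (e.g. a
  shared domain in otherwise unrelated multi-domain antigens) can chain
  clusters together under single linkage.
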