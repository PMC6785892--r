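# epibench

Non-redundant benchmark datasets of immune receptor–epitope structural
complexes, curated from coordinates.

## What this is for

Developers of receptor-specific epitope prediction methods (antibody- and
TCR-aware predictors) need benchmark sets of antibody–antigen, TCR–pMHC and
MHC–ligand 3D complexes in which near-duplicate receptor–epitope pairs are
collapsed. Deposited structures are highly redundant, and clustering
receptors on full-length sequence splits chains with identical binding
loops whenever frameworks differ. `epibench` filters complexes on
structural quality and clusters each branch on the features that determine
recognition, producing benchmark tables with one representative per
distinct receptor–epitope pair.

## The method

For a complex with receptor chain set *R* and antigen chain *A* (heavy
atoms only, solvent excluded):

* **contacts / epitope** — residues *a ∈ A* with
  min<sub>i∈a, j∈R</sub> ‖x<sub>i</sub> − x<sub>j</sub>‖ ≤ 4.0 Å;
* **core-epitope** — the contiguous span of *A* from the first to the last
  residue within 4 Å of TCR+MHC (or MHC-only) atoms, trimming overhangs but
  keeping non-contacting interior residues; complexes with cores < 8
  residues are dropped;
* **quality filters** — resolution ≤ 3.0 Å (inclusive; enabled by default),
  optional R-free cutoff, removal of complexes with missing backbone
  (N, CA, C) in any CDR position, antigen length ≥ 50 residues (Ab-Ag);
* **antigen clustering** — single-linkage at 70 % global-alignment identity
  (BLOSUM62, gap 10/0.5, shorter-sequence denominator);
* **receptor clustering** — exact CDR1|CDR2|CDR3 identity per chain (IMGT
  windows 27–38, 56–65, 105–117), heavy/light and α/β grouped
  independently; labels `H1_L2`, `A2_B1`, `H3` (single-chain);
* **epitope conformation** — sites are compared via sorted lists of all
  intra-site atom-pair distances: with *m* matched entries,
  `PMax = m / max(p_a, p_b)`, `PMin = m / min(p_a, p_b)`; sites cluster
  together iff `PMax = 1` or `PMin = 1` or (`PMin ≥ 0.9` and `PMax ≥ 0.6`);
* **MHC clustering** — chains map onto G-domain references (class I α1–α2;
  class II α1, β1) by local alignment under 90 %/85 % coverage thresholds;
  labels `a<i>`, `a<i>_b<j>`, `n<i>` (non-classical, full sequence);
* **distinct pairs** — Ab-Ag: (receptor, epitope-conformation); TCR-pMHC:
  full (core, TCR, MHC) clusters and coarser (core, TCR) groups; MHC-ligand:
  (core, MHC). One representative per pair (best resolution, then id).

A seeded generator (`make_corpus()`) builds fully synthetic corpora with
planted cluster structure and quality defects, so the entire pipeline is
testable offline; see the methods vignette
(`vignettes/benchmark-curation.Rmd`) for the model, parameter rationale and
limitations.

## Worked example

```r
library(epibench)

gen  <- make_corpus(fixture_spec("standard", seed = 42), "corpus")
corp <- read_manifest(gen$manifest)
out  <- run_benchmarks(corp)
str(out$ab_ag$counts)
```

```
List of 7
 $ total            : int 23
 $ peptidic         : int 20
 $ post_filter      : int 15
 $ distinct_pairs   : int 11
 $ attrition        :List of 4
  ..$ resolution : int 3
  ..$ r_free     : int 0
  ..$ missing_cdr: int 1
  ..$ length     : int 1
 $ antigen_clusters : int 6
 $ receptor_clusters: int 8
```

Of 23 antibody–antigen complexes, 20 have a peptidic antigen; the filters
remove 5 (three for resolution — including an NMR entry with no resolution
value — one for a broken CDR backbone, one 45-residue antigen), and the 15
survivors fall into 6 antigen families, 8 antibody CDR groups and 11
distinct antibody–epitope pairs. The benchmark table itself has one row per
kept complex:

```r
head(out$ab_ag$table[, c("structure_id", "antigen_cluster",
                         "receptor_cluster", "epitope_cluster",
                         "pair_cluster_id", "is_representative")], 3)
```

```
  structure_id antigen_cluster receptor_cluster epitope_cluster pair_cluster_id is_representative
1         ab01             Ag1            H1_L1              E1        H1_L1|E1              TRUE
2         ab02             Ag1            H1_L1              E1        H1_L1|E1             FALSE
3         ab03             Ag1            H1_L1              E2        H1_L1|E2              TRUE
```

Complexes `ab01`–`ab03` share an antigen family and an antibody CDR group,
but `ab03` presents a conformationally different epitope, so it opens a
second antibody–epitope pair (`H1_L1|E2`).

For the TCR branch, `out$tcr_pmhc$counts` reports both `full_clusters`
(core × TCR × MHC: 6 on this corpus) and the coarser
`tcr_epitope_groups` (core × TCR: 5), mirroring how a complex bound by the
same TCR to the same core on two MHC backgrounds is one receptor–epitope
group but two full clusters.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/epibench.R fixtures --seed 42 --profile standard --out-dir corpus
Rscript inst/cli/epibench.R ab-ag --in corpus/manifest.json --out results_ab
```

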