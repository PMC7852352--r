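---
title: "Methods: clonal evolution from single-cell targeted genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal evolution from single-cell targeted genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetracer)
```

## The problem

Bulk sequencing of a tumor averages over millions of cells and can only
deconvolve clonal structure statistically. An alternative is to genotype a
targeted panel of somatic mutation sites (on the order of 60 sites, chosen
from the tumor's own exome) in each of tens to hundreds of single cells.
Every cell then contributes a ternary profile over the panel — mutant (1),
reference (0) or missing — and the combinations of mutations observed across
cells reveal the clones directly: which mutations arose first (the trunk),
which clones descend from which, and, when primary tumor and a metastasis
are sampled together, whether the metastasis branched early and evolved
independently.

`clonetracer` implements that analysis end to end: quality control of the
genotype matrix, clone calling, clone-tree reconstruction with unobserved
("virtual") ancestors, mutation classification across tissues, per-branch
substitution spectra, and a maximum-parsimony tree of the single cells. A
generative simulator with known ground truth accompanies the pipeline and is
the basis of all validation.

## Data model

A `GenotypeMatrix` holds cells × sites calls in {0, 1, NA} plus site
metadata (chromosome, 1-based position, ref/alt alleles, gene, SNV/INDEL
class, optional bulk VAF) and cell metadata (tissue label: `paratumor`,
`tumor`, `metastasis`, `other`). All downstream structures — clones, the
clone tree, spectra, the cell tree — are derived from it.

## The noise model and its estimator

Single-cell genotypes from whole-genome-amplified material suffer three
characteristic errors, which the simulator applies independently per entry:

* **Allele dropout (ADO)** with per-allele probability $d$: a heterozygous
  mutant site loses both alleles with probability $d^2$ (missing call),
  loses only the mutant allele with probability $d(1-d)$ (spurious
  reference call), and is otherwise observed mutant.
* **False positives** with probability $f$: a true reference call is
  observed mutant.
* **Missingness** $m$, applied to every non-missing entry afterwards
  (failed amplicons, low coverage).

At control sites known to be heterozygous germline in *every* cell, the
fraction of non-missing observations that look homozygous is

$$h = \frac{2d(1-d)}{1-d^2} = \frac{2d}{1+d},$$

which inverts to the estimator $\hat d = h/(2-h)$. The estimator is
monotone in $h$, maps $[0,1)$ into $[0,1)$, and is computed from a separate
control matrix rather than from somatic sites, to avoid circularity with
clone calling. At $10^4$ control observations its bias is far below 0.01
(the bundled validation measures it).

Defaults $d = 0.1$, $f = 0.005$, $m = 0.05$ describe a moderately noisy
targeted panel; all three are explicit `simulation_config()` parameters.

## Quality control

Two checks mirror what one would demand of real panel data. First, the
per-site **mutated cell fraction** (mutant calls over non-missing calls,
tumor-compartment cells only) should track the bulk variant allele frequency:
for heterozygous diploid mutations and pure tumor, fraction $= 2 \times$
VAF, so the Pearson correlation between the two (Spearman available as an
option) is reported as a concordance score. Second, **paratumor cells are
negative controls**: a site frequently mutant among them is germline or a
recurrent artifact and is removed (`filter_germline_artifacts()`, default
threshold 0.1).

## Clone calling

Cells are compared by a dropout-tolerant normalized Hamming distance: the
fraction of discordant calls among sites non-missing in both cells, with
pairs sharing fewer than `min_overlap` (default 10) co-observed sites
flagged unreliable and treated as maximally distant. Average-linkage
hierarchical clustering is cut at height `tau`; clusters with at least
`min_cells` cells become clones and the rest of the cells stay unassigned.
Consensus genotypes take the per-site majority among non-missing member
calls, require at least `min_site_coverage` (default 0.5) of members to be
non-missing, and break ties toward reference so that false positives do not
inflate clone mutation sets.

The two thresholds deserve care, and their defaults encode a calibration
against the noise model rather than arbitrary round numbers:

* Under dropout $d$, two cells of the same clone disagree at a shared
  mutant site with probability $2p(1-p)$, $p = 1/(1+d)$ — about 0.165 at
  $d = 0.1$. On a 60-site panel with ~15 mutant sites this puts the
  expected within-clone distance near 0.05–0.07, while clones separated by
  three mutations sit at ≥ 0.08. The default `tau = 0.07` lies in that
  gap. With clean or nearly clean data the geometry inverts — within-clone
  distances collapse to ~0 while three-mutation clone pairs sit at
  3/60 = 0.05 — so `tau` should then be set *below* the minimum expected
  clone divergence (e.g. 0.04). `tau` scales with the noise level, and the
  package deliberately keeps it explicit rather than hiding an adaptive
  rule.
* Cells sharing a dropout at the same mutant site form spurious
  sub-clusters of expected size $n \cdot d/(1+d)$ — about 4.5 cells at 50
  cells/clone and $d = 0.1$. A minimum clone size of 5 would let such
  artifacts through as clones (we observed exactly that in simulation:
  5–6-cell pseudo-clones that break exact trunk recovery); the default
  `min_cells = 10` stays above them with headroom. For datasets with far
  fewer cells per clone, lower it accordingly.

Unassigned cells are reported, not silently dropped: the benchmark
(`recovery_benchmark()`) carries an `unassigned_rate` column next to the
adjusted Rand index, which by default compares the partitions over assigned
cells only (`clone_ari(..., unassigned = "singletons")` makes abstention
count against the index instead).

## Clone tree, virtual ancestors, conflicts

The clone tree is a perfect phylogeny over the clone consensus genotypes:
every mutation arises exactly once and never reverts, with an all-reference
root. Binary characters admit such a tree iff no two sites show all three
patterns (1,0), (0,1), (1,1) across clones (`conflict_test()`). Real data
violate this occasionally; `resolve_conflicts()` greedily removes the site
in the most conflicts (ties: lower mutated-cell fraction, then site id) and
logs every removal — simple, deterministic, auditable, in preference to
probabilistic genotype correction.

Construction orders mutations by containment of their carrying-clone sets.
Whenever two or more sibling subtrees share mutations their parent lacks,
an unobserved ancestor must have carried exactly that shared set: a
**virtual ancestor** node is inserted (at least two children by
construction; a single-child virtual node is never created). This is how an
early-seeded metastasis ancestor that was never itself sampled becomes
visible in the reconstruction. Each edge is labelled with the mutations
acquired on it; `validate_clone_tree()` asserts the cumulative-set
recursion, root-path disjointness and virtual-node arity after every build.

Mutations are then classified over the observed clones: **trunk** (carried
by all clones), **tissue-private-clonal** (all clones of exactly one tissue,
none of any other — the signature of metastasis-private early events),
**tissue-shared** (at least two tissues but not all clones), **subclonal**
(a proper subset of one tissue's clones), or **unassigned** (not placed on
the tree, e.g. removed as conflicting).

## Substitution spectra

Single-base substitutions collapse onto the six pyrimidine-reference
classes (C>A, C>G, C>T, T>A, T>C, T>G); purine-reference pairs are
reverse-complemented (A>T counts as T>A). Per clone-tree edge, the spectrum
of *newly acquired* SNVs is tabulated, with INDELs counted as excluded.
This resolves mutational processes in time along the tree — a trunk
dominated by T>A transversions, for instance, points to early carcinogen
exposure (the aristolochic-acid pattern in liver cancer). Trinucleotide
(96-class) context is deliberately out of scope: a targeted panel carries
no flanking sequence.

The simulator draws SNV ref/alt pairs from a `signature_bias` probability
vector over the six classes (default weighted toward T>A, emulating an
exposure-driven liver-cancer panel; the strand is randomized so both
representations of each class occur).

## Maximum-parsimony cell tree

Each cell becomes a pseudo-sequence over its SNV sites (mutant → alt base,
reference → ref base, missing or INDEL → N). Fitch small parsimony scores a
topology as the minimum number of state changes, with N the full state set
(it never forces a change). Scoring roots the unrooted binary tree on the
pendant edge of the first tip so the classic intersect-else-union recursion
is exact; the kernel is in C++.

Identical sequences are collapsed before the search and re-attached as
zero-length children afterwards. With ≤ 9 unique sequences the search is
exhaustive over all unrooted binary topologies (global optimum, first-found
tie-break in a fixed enumeration order); beyond that, nearest-neighbor-
interchange hill climbing runs from a neighbor-joining start tree
(p-distance, pairwise deletion of N) plus seeded random restarts (default
10), keeping the best score. The heuristic can never report a score below
the optimum; on random 7-taxon alignments it matches the exhaustive optimum
in ≥ 90% of instances (tracked in the test suite).

Branch lengths come from one deterministic most-parsimonious ancestral
reconstruction (Fitch traceback, first-state tie-break with states ordered
A < C < G < T): changes per edge divided by alignment columns, i.e.
substitutions per site; the change counts sum exactly to the parsimony
score. The seed influences only the NNI traversal order and restart
topologies — never the reported score of a given topology.

## What the simulator does and does not emulate

`simulate_dataset()` generates: a clone tree (linear, star, bifurcating or
custom; a trunk edge plus 3–5 mutations per private edge by default, on a
60-site panel), cells per clone with tissue labels (clones given 0 cells
become unobserved ancestors), paratumor cells, the three-parameter noise
model, pseudo-bulk VAFs (purity × carrying-fraction / 2), and a
heterozygous-germline control matrix. `two_tissue_preset()` is the
reference scenario: an observed founder clone carrying only the
10-mutation trunk, a primary-tumor subclone, and two metastasis clones
under an unobserved metastasis ancestor — the "common origin, independent
evolution" structure.

Deliberately not modelled: amplification bias and read-level errors
(genotypes are simulated directly), copy-number events (sites are binary
presence/absence, all mutations heterozygous), doublets, and dependence of
dropout between sites. Passing the recovery benchmarks therefore shows the
inference is correct *under this error model*, not that it is robust to,
say, copy-number-driven loss of heterozygosity, which would masquerade as
dropout concentrated in one clone. Paratumor cells are subjected to the
same noise, so germline/artifact filtering is exercised realistically.

## Numerical and design choices

* Missing is encoded `NA` in memory and `"NA"` in TSV; genotype tokens are
  `"0"`/`"1"`; coordinates are 1-based; alleles uppercase.
* One master seed per simulation; per-stage sub-seeds are derived from it
  deterministically, so any stage can be replayed in isolation and
  identical configurations give byte-identical outputs (the run manifest
  records every parameter).
* Consensus ties break toward reference; conflict removal breaks ties
  toward lower mutated-cell fraction, then lexicographic site id; Fitch
  tracebacks break ties toward the alphabetically first base; exhaustive
  search keeps the first-found optimum in a fixed enumeration order.
* Undefined quantities are reported as such rather than coerced: an
  all-missing site has no mutated-cell fraction, a zero-variance VAF vector
  has no correlation (NA with a warning), fewer than 3 VAF-annotated sites
  is an error.
* Validation problem sizes: 50-replicate recovery runs use the reference
  scenario (4 observed clones × 50 cells, 60 sites); parsimony oracle
  checks use 6 taxa × 20 columns against all 105 topologies and a unit-cost
  Sankoff dynamic program; heuristic-vs-exhaustive comparisons use 7–8
  taxa. These sizes make every brute-force oracle exactly enumerable while
  matching the scale of a real targeted panel.

## Known limitations

* Clone calling is a flat cut of one linkage tree; clones closer than the
  within-clone noise floor (fewer than ~3 private mutations on a 60-site
  panel at $d = 0.1$) cannot be separated at any `tau`, and ~10% of cells
  remain unassigned at the default settings under the reference noise
  model.
* The perfect-phylogeny assumption (no back mutation, no recurrence) is a
  modelling choice; conflicts are resolved by site removal, so a truly
  recurrent mutation would simply be dropped and reported, not modelled.
* The ADO estimator needs a dedicated heterozygous-germline control
  matrix; without one, QC reports no dropout estimate.
* Maximum parsimony is uncorrected for multiple hits; branch lengths are
  substitutions per site under one arbitrary most-parsimonious
  reconstruction, suitable for display and relative comparison, not for
  molecular-clock inference.
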