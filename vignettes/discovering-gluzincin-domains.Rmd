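---
title: "Discovering M60-like gluzincin peptidase domains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering M60-like gluzincin peptidase domains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m60miner)
```

## The problem

Mucosal surfaces are the main interface between animals and their microbiota,
and mucins — heavily O-glycosylated glycoproteins — are both a barrier and a
nutrient source for microbes that live there. A family of extracellular zinc
metallopeptidases (the M60-like domain, Pfam PF13402, related to the
baculoviral M60 enhancins of Pfam PF03272) degrades the mucin peptide
backbone, and its taxonomic distribution tracks host-associated and mucosal
lifestyles. `m60miner` implements, as a reusable and fully tested pipeline,
the computational workflow that supports this kind of domain discovery:

1. iterative curation of a seed multiple sequence alignment;
2. construction of a positional log-odds profile and local scoring of
   protein databases in bits, with extreme-value calibrated E-values;
3. detection of the catalytic zincin (`HEXXH`) and gluzincin
   (`HEXXHX(8,28)E`) motifs;
4. partition of hits into sister subfamilies by bit-score difference;
5. domain-architecture assembly and co-occurrence analysis, with
   extracellular-targeting feature flags;
6. a hypergeometric test for genotype–habitat association.

Every stage can be exercised against a synthetic proteome with known ground
truth, so the pipeline is verifiable without any external downloads.

## Alignment curation

`curate()` applies the classical five-step protocol: extract the conserved
segment (once), then iterate (i) redundancy removal, (ii) re-alignment,
(iii) removal of rare long insert blocks, until nothing changes.

Definitions the protocol needs but that are often left implicit; the choices
here are:

* **Pairwise identity** is the fraction of identically occupied columns
  among columns where at least one of the two rows has a residue; dual-gap
  columns are ignored. This makes the measure invariant under segment
  extraction, which matters because redundancy is judged "across the aligned
  segment". The default threshold is 0.80.
* **Redundancy removal** is greedy and worst-first: while any pair reaches
  the threshold, the most similar pair is resolved by discarding its member
  with fewer residues in the segment; an exact tie discards the
  lexicographically later id, which keeps the operation deterministic.
* **Insert-like columns** are columns whose residue occupancy is *strictly*
  below 0.50 (a column at exactly half occupancy is kept). "Indels larger
  than 2 residues" is read as maximal runs of more than `max_indel_len = 2`
  consecutive insert-like columns; such runs are deleted entire, shorter
  runs are untouched. This is the only reading that operates on the
  alignment itself rather than on individual sequences.
* **Re-alignment** uses an internal progressive aligner: k-mer (k = 3)
  distances, a UPGMA guide tree, and global profile–profile dynamic
  programming with BLOSUM62 expected column scores and affine gaps
  (open 11, extend 1 — the common protein-aligner scale for integer BLOSUM
  scores). Inputs are canonicalised by id before tree construction so the
  result is independent of input order. The aligner's contract (not its
  algorithmic detail) is what the protocol relies on; any external aligner
  producing an `msa` can be substituted through `read_alignment()`.
* **Convergence** means an iteration changed neither rows nor columns;
  `max_iterations` defaults to 20. Dimensions can only shrink, and the
  curation report records every removal with its reason.

The original curation of the M60-like seed alignment reported slightly
different column counts in different places (206 vs 208 columns for the
27-sequence alignment); neither number is treated as a correctness target
here — the tests assert the *behavioural* contract on fixtures with planted
duplicates and insert blocks instead.

## The profile model

`build_profile()` turns a curated alignment into a positional log-odds
model. Columns with occupancy ≥ 0.5 become match states. Emissions use
background-proportional pseudocounts with weight $w$ (default 1):

$$ e_i(a) = \frac{c_{i,a} + 20\, w\, b_a}{n_i + 20\, w} $$

where $c_{i,a}$ counts residue $a$ in column $i$, $n_i$ is the column's
residue count and $b$ is the background (uniform by default).

`score_sequence()` finds the best *local* alignment of the match-state path
to a sequence by dynamic programming over $\log_2 e_i(a)/b_a$ with affine
insert/delete penalties (defaults: open 4 bits, extend 1 bit; inserts emit
at background, so they cost only the transition). This is deliberately a
simplified profile — one insert background, uniform delete penalty, no
forward-sum scoring — because the downstream analyses (hit calling at a
fixed E-value, subfamily partition) depend on relative bit scores rather
than on any particular profile software's internals. Tables produced by
external profile-search tools can be ingested with `read_hit_table()` when
exact interoperability is wanted. Ambiguity letters (B, Z, X, U, O, J)
score exactly 0 bits (background) in match states.

E-values come from `calibrate()`: decoy sequences are drawn residue-wise
from the background at realistic lengths, each decoy keeps its best local
bit score, and a Gumbel law is fitted to those maxima by maximum
likelihood. The E-value of score $s$ against a database of $D$ sequences is
$D \cdot \Pr(S \ge s)$ under the fit, strictly decreasing in $s$; the
default reporting cutoff is $10^{-5}$. Calibration takes an explicit seed
and is the only stochastic step in the scoring path.

`partition_by_score_difference()` implements the subfamily rule: over the
union of targets hit by either of two profiles, compute
$\Delta = s_A - s_B$ with a missing score contributing 0, assign by the
sign of $\Delta$, and report exact zeros as ties rather than silently
assigning them. Swapping the profiles exactly swaps the class counts.

## Motif scanning

`scan_pattern()` evaluates a PROSITE-style pattern subset: literals, `x`
wildcards with repeat ranges, `[..]` classes and `{..}` negated classes.
Scanning is exhaustive: every start position and every expansion of a
variable-range wildcard that matches is reported once per distinct
interval, so one zincin anchor followed by two glutamates in range yields
two gluzincin intervals (a `collapse = "shortest"` mode keeps one match per
anchor for summary counting). Sequence-side ambiguity letters satisfy only
wildcard positions — never literals or classes — which prevents ambiguity
characters from inflating motif counts.

The gluzincin spacer range defaults to (8, 28) residues between the second
histidine and the downstream glutamate. Published descriptions of this
family vary between (8, 28) and (8, 24); the range is therefore an explicit
parameter rather than a constant. Likewise, whether motifs should be
counted protein-wide or only inside a profile hit envelope is not settled
usage, so `scan_pattern()` accepts an optional `region`.

## Architectures and surface features

`assemble_architecture()` resolves overlapping domain hits greedily by
descending bit score, keeping a hit when its overlap with every retained
hit is at most 25% of the shorter interval (the tolerance is a parameter;
interval resolution conventions differ between annotation systems and this
one is the package's own). `cooccurrence_table()` and `combination_query()`
then answer the standard questions — which accessory domains (CBM32,
CBM5_12, CBM51, BACON, …) ride along with a focal peptidase domain, and
which proteins carry a given domain combination.

Surface targeting (signal peptide, transmembrane segments, lipobox) is the
domain of dedicated predictors, and `flag_surface()` treats their tabulated
output as authoritative. When no external prediction is available it falls
back on a clearly-labelled heuristic (Kyte–Doolittle hydrophobic windows
and a lipobox-like regular expression); every value carries a provenance
tag, and unknown values never satisfy the extracellular disjunction — so
`surface_fraction()` counts conservatively. The heuristic is second-class
by design: reproducing published surface-feature percentages requires the
predictor outputs those analyses used, so the statistic is exercised on
synthetic truth via the external-table route instead.

## The habitat association test

For a universe of $N$ taxa with known trait status, $M$ trait-positive,
$n$ genotype-positive (≥ 1 protein carrying the domain, threshold
adjustable) and $m$ doubly positive, `hypergeom_test()` reports the exact
upper tail

$$ p = \sum_{i=m}^{\min(n,M)} \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}} $$

computed via log-gamma and log-sum-exp (exact to better than 12 significant
digits against rational arithmetic on small instances), the distribution
mean $\mu = nM/N$, and the direction: positive when $m > \mu$, negative
when $m < \mu$, `"none"` at exact equality (only the strict inequalities
are meaningful).

The result also carries the *point* probability $\Pr(X = m)$. This matters
for reproducing reference values: the published association values for this
domain family (mucosa 1.7×10⁻⁸, animal host 5.9×10⁻⁶) are recovered
exactly — at the printed precision — by the point probability evaluated on
the printed 2×2 margins (mucosa: 43, 154 / 17, 303 giving N = 517, M = 197,
n = 60, m = 43; animal host: 55, 327 / 17, 333 giving N = 732, M = 382,
n = 72, m = 55), which `replicate_table3()` recomputes. The accompanying
methods text states a slightly different mucosa universe (N = 455, n = 55)
whose tail probability is 2.2×10⁻⁸ and whose mean is μ ≈ 23.8; both
parameterisations are reported, the discrepancy is documented rather than
resolved, and for new analyses the upper tail — not the point mass — is the
defensible test statistic. `adjust_multiple()` provides Benjamini–Hochberg
correction for users testing many traits; the two-trait reference analysis
used none.

The test treats taxa as independent draws; it applies no phylogenetic
correction, which is a known limitation of this class of enrichment test.

## The synthetic proteome generator

`generate()` emits a proteome with full ground truth under one master seed
(all substreams are derived from it by fixed labels, so any fixture is
reproducible in isolation). It emulates exactly the statistical structure
the analysis assumes:

* carrier proteins receive a domain instance sampled column-wise from a
  family profile — each column takes the consensus residue with probability
  equal to the conservation level (default 0.85), otherwise background —
  implanted at a random position in background sequence;
* a sister family derives its consensus by per-column mutation at a
  configured divergence (default 0.35), giving the two-family structure
  the score-difference partition is meant to resolve;
* a gluzincin motif (`HEAAH` + spacer + `E`, spacer uniform on the
  configured range intersected with what fits the domain) is planted inside
  each instance;
* surface features are planted on carriers (signal-peptide prefix with a
  basic residue then a hydrophobic stretch, default prevalence 0.76;
  lipobox `LSGC`, default 0.10), and a synthetic external-prediction table
  consistent with the planting is emitted;
* taxa get a habitat trait through a logistic link on the genotype flag, so
  the genotype–trait log-odds equals the configured log odds ratio
  (default 4; baseline prevalence 0.30 matches the trait-prevalence scale
  of the reference habitat table).

Defaults (80 taxa × 3 proteins of length 300; two families of 40 carriers
each; domain length 80) are chosen so that profile search separates
carriers from background by hundreds of bits — the regime in which the
reference analysis operates — while keeping the whole test battery fast.
`simulate_habitat()` is a lighter generator for calibration studies of the
association test alone; `curation_fixture()` plants exact duplicates and a
low-occupancy poly-W insert block and records what curation must remove.

What the generator does *not* emulate: insertion/deletion evolution inside
domains, phylogenetic correlation among taxa, compositional bias (unless
the Robinson-style `natural_background()` is chosen), multi-domain
proteins beyond the planted family, and partial/fragmented sequences.
Passing the synthetic battery therefore demonstrates correctness of the
computations, not performance on degraded real-world data.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; every file format and
  human-facing report uses 1-based inclusive coordinates.
* Scores are computed in bits end to end; the hypergeometric tail in
  natural-log space with a final exponentiation.
* `pairwise_identity` returns 0 when no column is scorable.
* A best local score ≤ 0 is reported with an empty (NA) envelope.
* A Gumbel fit refuses zero-variance decoy scores; `calibrate` requires at
  least 50 decoys.
* Ties: redundancy removal and partition ties are reported or broken
  lexicographically, never randomly.
* `curate` errors (with the report attached to the message context) if an
  alignment collapses to zero columns.

## Problem sizes used by the test battery

The shipped tests verify: the hypergeometric tail against enumeration over
every universe N ≤ 25 (≈ 24,000 instances); the profile scorer against
exhaustive path enumeration on ≤ 4-state × ≤ 6-residue instances; the motif
scanner against a regex automaton on 10,000 random 40-mers; curation
idempotence and monotone shrinkage on 100 seeded fixtures; ≥ 95% partition
recovery and ≥ 99% enrichment-direction recovery on default synthetic
configurations; and a null type-I fraction ≤ 0.07 at α = 0.05 over 1,000
replicates. These sizes were chosen as the smallest that exercise every
code path with comfortable statistical margins.

## Known limitations

* The profile model is intentionally simpler than full profile-HMM
  packages (no forward scores, no glocal mode, one envelope per target);
  it is not a drop-in replacement for them on real databases.
* The surface heuristic is a stand-in, not a predictor; treat its output
  as provisional wherever external predictions are absent.
* The association test ignores taxon relatedness.
* The progressive aligner optimises a sum-of-pairs proxy and does not
  attempt iterative refinement; for production seed alignments an external
  aligner remains preferable, via the provided interop readers.
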