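---
title: "Methods: habitat-aware comparative pangenomics with novopan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat-aware comparative pangenomics with novopan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`novopan` implements a comparative-genomics workflow for the genus
*Novosphingobium*, a metabolically versatile alphaproteobacterial group
isolated from rhizosphere, contaminated soil, freshwater and marine
habitats. The workflow asks how gene content is distributed across habitats:
which gene families are universal (core), which are private to the genomes
of one habitat, how the core and pangenome scale as genomes accumulate, how
strains cluster by nucleotide identity versus trait profiles, and what the
topology of per-habitat protein-interaction networks looks like. Every stage
is driven either by the bundled metadata of the 27 public *Novosphingobium*
genomes or by a synthetic-data generator with planted ground truth, so the
whole pipeline is testable offline.

# Ortholog clustering

Proteins are compared by Smith–Waterman local alignment (BLOSUM62, affine
gaps open 11 / extend 1 — the standard protein defaults, configurable via
`scoring_config()`). Two statistics are thresholded jointly at their
conventional 75% values:

* **identity** — identical residue pairs over the aligned *non-gap*
  columns. Including gap columns in the denominator is the main alternative
  convention; we use non-gap columns because it matches BLAST-style percent
  identity, which the thresholds were originally formulated against.
* **query coverage** — the aligned span of the query over its full length.
  Coverage is what actually rejects spurious hits: local alignments of
  unrelated proteins routinely reach 40–80% identity over short segments,
  but their coverage stays far below 75%, so no unrelated pair passes the
  joint filter.

Two clustering strategies are built on reciprocal best hits (score ties
broken by higher identity, then lexicographically smaller gene id, so
results are deterministic):

* **BDBH** (`bdbh_clusters()`): every gene of a reference genome (by
  default the first genome of the collection) seeds a cluster; genes of
  other genomes join iff they are reciprocal best hits of the seed. Clusters
  have at most one member per genome, which is what the core/pangenome trend
  curves need. The price of the reference is that accessory families absent
  from the reference genome are never clustered.
* **COG-triangles** (`cog_triangle_clusters()`): reciprocal best hits are
  computed for all genome pairs; three genes in three genomes that are
  pairwise reciprocal form a triangle, and triangles sharing an edge merge
  into clusters. Since a gene must belong to exactly one cluster, we take
  connected components of the triangle edges, which additionally merges
  triangles that share only a gene — the minimal closure that keeps clusters
  disjoint. Reciprocal pairs supported by no triangle are reported
  separately; families present in only two genomes therefore stay out of
  the cluster set by construction.

`collection_pair_stats()` precomputes the all-vs-all alignment statistics
once per genome pair so both algorithms (and threshold sweeps) share them.

# Rarefaction and curve fitting

`rarefy()` adds genomes in random order (10 permutations by default, the
conventional sampling depth for these curves) and records the running core
(families present in all sampled genomes) and pan (present in at least one)
sizes. Core at *n* = 1 is simply the first genome's family count. The
monotonicity of both curves within each permutation is asserted at run
time.

Fits operate on the mean curve over permutations at each *n* — fitting the
mean rather than the pooled points matches the single regression line
normally drawn through such plots. Models:

* core: $F_c(n) = \kappa\, e^{-n/\tau} + \Omega$, with $\Omega$ the
  asymptotic core size;
* pan (default): Heaps' law $F_p(n) = K n^{\gamma_H}$, $\gamma_H > 0$
  indicating an open pangenome;
* pan (alternative): $\kappa_p e^{-n/\tau_p} + tg\cdot n + C$, whose linear
  coefficient is the asymptotic number of new genes per genome.

Nonlinear least squares uses Levenberg–Marquardt with scale-aware starting
values ($\Omega_0$ = smallest mean core, $\kappa_0$ = first-point excess,
$\tau_0 = G/3$); noiseless model data are recovered to relative 1e-6. A flat
signal short-circuits to the obvious degenerate solution ($\kappa = 0$,
$\Omega$ = the constant; $\gamma_H = 0$) rather than risking a singular
gradient in the optimizer, with $\tau$ reported as `NA` since it is not
identified there.

# Habitat set algebra

Habitats with fewer than three genomes, and genomes with no habitat label,
are excluded from the grouping by default (`min_genomes = 3`, overridable).
The habitat core is the intersection of a habitat's genomes;
habitat-specific families subtract the other habitats in one of two modes,
because published descriptions of such comparisons are usually ambiguous
between them:

* `"core"` (default): specific = in this habitat's core, in no other
  habitat's **core**. This is the literal reading of "comparing the core
  genome of each habitat with respect to another".
* `"strict"`: additionally absent from **every individual genome** of the
  other habitats.

Strict sets are always subsets of core-mode sets; both are exposed and
neither is asserted as the published convention. Cloud content is the set of
families whose incidence spans at most two habitats, monotone in the bound.

Pathway completeness is a symbol screen (exact, case-insensitive matching
against a catalog TSV): complete if all required genes are present, partial
with the missing list otherwise, absent if none. The bundled catalog covers
the three environmental sulfur-assimilation routes (sulfate *cysPAUW* +
*cysD*/*cysNC*, sulfonate *ssuABC*/*ssuD*, taurine *tauABC*/*tauD*) and
ectoine biosynthesis (*ectA*, *ectB*, *ectC*, optionally *ectD* for
hydroxyectoine). Annotation itself (gene calling, KO assignment) is out of
scope: the screen consumes symbol inventories.

# Distances and trees

**Fragment ANI** (`ani_fragment()`) chops the query genome into 1,020-bp
fragments, aligns each to the subject on both strands (match +1, mismatch
−1, gap open 2; gap extension 1, a choice the protocol leaves open) and
averages the identity of fragments passing identity ≥ 30% and coverage
≥ 70%. No passing fragment yields `NA`, never 0. The matrix routine reports
the mean of the two directions, since fragmenting is mildly asymmetric. The
ortholog-core mode instead averages global-alignment identities over shared
single-copy core genes.

**Correlation dendrograms** cluster rows by the Pearson distance $1 - r$
with average linkage (the historical default of expression-matrix viewers;
complete and single are exposed). Rows of an ANI matrix are themselves
profiles, so clustering on profile correlation covers both the similarity
and the distance reading of such matrices; a `direct_distance` flag
clusters a precomputed distance matrix instead. Constant rows make $r$
undefined and raise an error naming the rows.

**Poisson distances** use $d = -\ln(1-p)$ on the fraction $p$ of differing
sites after removing all gap-containing columns (complete deletion;
pairwise deletion available). $p \ge 1$ is flagged as infinite rather than
silently truncated. Bootstrap resamples columns with replacement under a
seed.

**Neighbor joining** is the canonical Saitou–Nei agglomeration (via `ape`);
on additive matrices the tree's path lengths reproduce the input exactly,
which the tests verify. Negative branch lengths, which NJ can produce on
non-additive input, are clamped to zero. Bootstrap support is the
percentage of replicate trees containing each bipartition.

# Network topology

Networks are simple undirected graphs; input edge lists are deduplicated
(STRING exports commonly list both directions) with a warning. The
statistics are:

* $P(k) = n_k / N$, the degree distribution;
* $C(k)$: per-node clustering $2E/[k(k-1)]$ ($E$ = edges among the node's
  neighbors), averaged within each degree class; nodes with $k < 2$ have no
  defined coefficient and are excluded;
* $C_n(k_n)$: mean degree of a node's neighbors, averaged within degree
  classes — the realized average over the conditional degree–degree
  distribution.

Exponents come from ordinary least squares on $\log_{10}$–$\log_{10}$
points of the raw (un-binned) profiles, reported sign-positive
(exponent = −slope) with $r^2$; zero-valued points are dropped (log
undefined) and counted. Raw classes plus OLS, rather than logarithmic
binning or maximum-likelihood tail fitting, is deliberate: it is what the
$r^2$-annotated profile plots in this literature correspond to. Logarithmic
binning can be added upstream by the caller; maximum-likelihood estimators
of the tail answer a different question (tail exponent, not profile slope)
and would not be comparable.

Classification follows the standard reading of the three exponents: with
$\gamma$ from $P(k)\sim k^{-\gamma}$, $\beta$ from $C(k)\sim k^{-\beta}$
and $\alpha$ from $C_n(k_n)\sim k_n^{-\alpha}$, a network is *hierarchical*
when $\gamma < 2$, $\beta > 0$ and $\alpha > 0$; *assortative* when
$\alpha < 0$; *scale-free non-hierarchical* when $\gamma \ge 2$ and $C(k)$
is flat ($|\beta| < 0.1$); otherwise inconclusive.

Hubs are ranked by degree with lexicographic tie-breaks. The default rule
selects nodes whose degree strictly exceeds mean + 2 SD — strict so that a
regular graph has no hubs; a `top_n` rule is exposed because hub lists in
the literature are often "the top protein per network" without a stated
criterion.

# The synthetic-data generator

`generate_pangenome_collection()` plants: a universal core in every genome,
a private core per habitat, and cloud families carried independently with a
fixed probability (a cloud family sampled into no genome is given one
member so every planted family exists). Protein lengths are uniform over
100–400 residues by default — the bulk of bacterial protein lengths — and
the mutator substitutes an exact rounded count of positions, uniformly
chosen without replacement, with no indels, which keeps realized identity
analytically predictable.

Each family member is mutated from the family ancestor at **half** the
target divergence. Mutating each member at the full divergence would give
pairwise identities near the square of the target (~81% for a 90% target);
splitting the divergence across the two lineages makes the expected
pairwise identity equal the target, which is the quantity the clustering
thresholds see. The default within-family identity of 90% is a fixture
choice: real ortholog divergence in the genus is not characterized, and 90%
sits safely above the 75% threshold while leaving visible divergence.

The graph generators provide a seeded preferential-attachment graph
(connected, simple) and a deterministic Ravasz-style hierarchical-modular
graph (`module_size^levels` nodes; a complete module is replicated and all
copies' peripheral nodes wire to the root hub, so the $C(k)\sim k^{-1}$
signature is reproducible; the seed only permutes labels). The trait-matrix
generator plants genome blocks with distinct non-constant 0/1 profiles and
flips cells at a given noise rate.

What the generator does **not** emulate: nucleotide-level evolution
(indels, rearrangement, horizontal transfer, phage integration), paralog
expansion, annotation error, draft-genome incompleteness, or
interaction-confidence scores. Passing tests on synthetic data therefore
demonstrate the correctness of the algebra, the clustering logic and the
estimators under clean divergence — not robustness to assembly artifacts or
real ortholog complexity.

# Determinism and problem sizes

Every stochastic routine takes a seed and restores the caller's RNG state;
identical seeds reproduce outputs exactly, byte-identical for the
generator. The bundled analysis scripts use a 12-genome, 70-family
collection, 1,500–2,000-node networks and 1,000 bootstrap replicates; the
test suite uses smaller versions of the same designs (3–5 genomes, 100-node
graphs, 100 replicates), sizes chosen to exercise every code path while
keeping the suite quick to iterate on.

# Known limitations

* The published gene counts for the real 27-genome collection (the 220-gene
  core at 75/75, the 714-gene BDBH core, the 21,915-gene pangenome, and the
  438/346/297/143 habitat-specific counts) require the actual GenBank
  assemblies and are not reproduced here; the bundled table carries the
  metadata (sizes, GC, habitats) from which the collection-level statistics
  are recomputed.
* Likewise the published network exponents derive from STRING-derived
  networks that were not published; the package asserts the estimator
  properties (exact oracle agreement, exponent recovery) and the
  classification of the published exponent triples instead.
* BDBH is reference-bound by design; ortholog recovery below ~80%
  within-family identity degrades as pairs fall under the 75/75 filter.
* Fragment ANI with the built-in aligner is quadratic per fragment-genome
  pair and meant for the simulated genome sizes used here, not for
  multi-megabase assemblies.
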