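# novopan

Habitat-aware comparative pangenomics of the bacterial genus
*Novosphingobium*, packaged as a tested R workflow.

*Novosphingobium* (Alphaproteobacteria, Sphingomonadaceae) strains have
been isolated from rhizosphere, contaminated soil, freshwater and marine
habitats, and public repositories hold 27 genomes spanning those niches.
This package implements the analyses used to ask how gene content tracks
habitat in such a collection:

* **Ortholog clustering** — Smith–Waterman protein alignment with joint
  identity ≥ 75% / query-coverage ≥ 75% filters, reciprocal best hits,
  and both BDBH (reference-seeded, single-copy) and COG-triangles
  (three-way reciprocal triangles merged on shared edges) clustering.
* **Core/pangenome rarefaction** — genomes added in random order (10
  permutations), with Tettelin-style fits: core
  F<sub>c</sub>(n) = κ·e<sup>−n/τ</sup> + Ω and Heaps' law
  pan(n) = K·n<sup>γ</sup>.
* **Habitat gene-set algebra** — per-habitat core genomes, habitat-specific
  families (core-vs-core or strict subtraction), cloud content (families
  spanning ≤ 2 habitats), and pathway-completeness screens (sulfur
  assimilation routes, ectoine biosynthesis).
* **Distances and trees** — fragment-based ANI (1,020-bp fragments, 30%
  identity / 70% coverage filters, both strands), Pearson-correlation
  dendrograms (1 − r, average linkage), Poisson-corrected distances
  d = −ln(1 − p) and neighbor-joining trees with bootstrap support.
* **Network topology** — degree distribution P(k) = n<sub>k</sub>/N,
  per-degree clustering C(k) = 2E/[k(k−1)], neighborhood connectivity
  C<sub>n</sub>(k<sub>n</sub>), log-log power-law exponents (γ, β, α),
  hub identification (degree > mean + 2 SD, or top-n), and the
  hierarchical / assortative classification built on the exponents.
* **Synthetic data** — a generator that plants universal cores,
  habitat-private cores, accessory clouds at controlled protein identity,
  scale-free and hierarchical-modular graphs, and block-structured trait
  matrices, each with ground truth, so every stage is testable offline.

The bundled table `novosphingobium_genomes()` carries the published
metadata (habitat, genome size, GC, accession) of the 27 strains; all
collection-level statistics are recomputed from it at run time.

## Worked example

```r
library(novopan)

# habitat statistics of the real 27-genome collection
tab <- novosphingobium_genomes()
mbp <- setNames(tab$genome_size_bp / 1e6, tab$strain)
grp <- habitat_grouping(data.frame(genome_id = tab$strain,
                                   habitat = tab$habitat))
group_summary(mbp, grp)
#>               group n     mean        sd
#> 1 contaminated_soil 5 5.339136 0.5494260
#> 2        freshwater 6 4.192580 0.3483547
#> 3            marine 5 5.209179 0.2416191
#> 4       rhizosphere 3 6.367227 0.6865580
one_way_anova(mbp, grp)
#> one-way ANOVA: F(3,15) = 16.89, p = 4.487e-05
```

Mean genome size differs strongly between habitats — rhizosphere strains
carry the largest genomes (6.37 Mbp), freshwater the smallest (4.19 Mbp) —
while GC content does not (F(3,15) = 0.29, p = 0.84).

```r
# ortholog recovery on a synthetic collection with planted families
d <- pangenome_design(5, core_size = 60, within_family_identity = 90,
                      gene_length_range = c(100, 400), seed = 101)
col <- generate_pangenome_collection(d)
cl <- cog_triangle_clusters(col)
pam <- presence_absence(cl, col)
fit_core_decay(rarefy(pam, n_permutations = 10, seed = 1))
#> curve_fit [core_exponential]: kappa=0, tau=NA, omega=60; rss=0
```

All 60 planted families are recovered (adjusted Rand index 1.0 against the
truth map), and with no accessory cloud the core curve is flat at Ω = 60.

The numbered scripts under `analysis/` run the full workflow (genome
statistics, simulation, clustering, rarefaction, habitat sets and pathway
screens, ANI/NJ trees, network topology) and write their tables under
`results/`.

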