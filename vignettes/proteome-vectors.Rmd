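---
title: "Proteome vectors for phage comparison: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteome vectors for phage comparison: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagempr)
```

## The representation and its metric

A bacteriophage proteome is treated as a bag of proteins
$\Phi = \{u_1, \dots, u_m\}$, where each $u_i$ is a protein embedding from a
protein language model, mean-pooled over its residues and normalized to unit
length ($\lVert u_i \rVert = 1$). The genome's representation is the plain
average

$$\phi = \frac{1}{m} \sum_{i=1}^{m} u_i ,$$

deliberately **not** re-normalized: because the $u_i$ are unit vectors,
$\lVert \phi \rVert \le 1$, with equality only when all proteins point the
same way, so the norm measures the angular (functional) spread of the
proteome. Normalizing the per-protein vectors first stops highly conserved
proteins (which tend to have larger raw norms) from dominating the average;
each protein function contributes equally to the angular space. Genomes are
compared by the Euclidean distance $\lVert \phi_u - \phi_v \rVert$, computed
in double precision.

### Expected moments under the protein-family mixture

The package's `theory` functions treat cluster membership as fixed and the
embeddings as random: protein $i$ belongs to family $k(i)$ with unit
direction $\mu_{k(i)}$ and compactness $\alpha_{k(i)} \in [0,1]$ (the mean
resultant length), so $E[u_i] = \alpha_{k(i)} \mu_{k(i)}$, and proteins are
drawn independently. Under this convention:

$$E\left[\lVert\phi\rVert^2\right] = \frac{1}{m} + \frac{1}{m^2}
  \sum_{i \neq j} \alpha_{k(i)} \alpha_{k(j)} \, \mu_{k(i)}^{\top}\mu_{k(j)},$$

$$E\left[\phi_u^{\top}\phi_v\right] = \frac{1}{m_u m_v}\left(
  \sum_{k} n^u_k n^v_k \alpha_k^2 +
  \sum_{k \neq l} n^u_k n^v_l \alpha_k \alpha_l \, \mu_k^{\top}\mu_l\right),$$

with $n^u_k$ the number of proteins of genome $u$ in family $k$, and

$$E\left[\lVert\phi_u - \phi_v\rVert^2\right] =
  E\left[\lVert\phi_u\rVert^2\right] + E\left[\lVert\phi_v\rVert^2\right]
  - 2\,E\left[\phi_u^{\top}\phi_v\right].$$

`expected_sq_distance()` evaluates exactly this decomposition (the two
proteomes' embeddings are independent draws, so it describes two *distinct*
genomes, not the same realization twice). The squared-norm term quantifies
intra-genomic functional diversity; the dot-product term counts shared
protein content weighted by family compactness, plus cross-talk between
families that lie close in embedding space. The test suite verifies all
three formulas against term-by-term summation oracles and against
Monte-Carlo simulation (10 000 replicate proteomes per configuration,
agreement within three standard errors, sweeping $K \in \{1,2,5\}$,
$d \in \{8,64\}$, $m \in \{1,5,50\}$).

## The synthetic generator

No protein language model runs at desk scale, so `generate_dataset()`
produces embedding-space data with exactly the structure the method assumes:

* **Protein families** are von Mises–Fisher (vMF) clusters on the unit
  sphere. Sampling uses the tangent-normal decomposition with Wood's
  rejection scheme for the cosine — exact, dimension-robust and seedable.
  Family directions are drawn uniformly at random (near-orthogonal in high
  dimension) with an `orthogonal = TRUE` option for analytic tests, because
  the inter-family dot-product term of the theory needs both regimes.
* **Compactness from concentration.** The $\alpha$ used analytically must
  equal the mean resultant length the sampler realizes. We compute
  $\alpha(\kappa, d)$ by one-dimensional quadrature of the vMF tangent
  marginal $f(t) \propto (1-t^2)^{(d-3)/2} e^{\kappa (t-1)}$, which is
  noise-free and numerically stable at any concentration (no Bessel-function
  ratios, which overflow at large order). A seeded Monte-Carlo estimate of
  the resultant length cross-checks the quadrature in the tests.
* **Nested taxonomy by hierarchical pool sharing.** Each genus, subfamily
  and family owns a small disjoint core pool of protein families; every
  protein of a genome draws its family from the genus pool, subfamily pool,
  family pool or the global remainder with probabilities derived from three
  descending shared-composition fractions. Two genomes then share an
  expected composition fraction `shared[1]` within a genus, `shared[2]`
  within a subfamily and `shared[3]` within a family — the simplest
  mechanism that yields multi-scale clustering, and explicitly a modelling
  choice.

### Default study conditions

| parameter | default | rationale |
|---|---|---|
| taxonomy | 3 families × 2 subfamilies × 3 genera × 8 genomes (144 genomes) | smallest nesting with several taxa at every rank |
| `d` | 64 | desk-scale stand-in for the 2560-dimensional real embeddings |
| `K` | 200 | protein-family pool comfortably larger than all core pools |
| `kappa` | 50 | moderately compact families; $\alpha(50, 64) \approx 0.55$ |
| `m_range` | 60–100 | the modal proteome-size class of curated phage databases is 50–100 CDS |
| `shared` | (0.90, 0.60, 0.30) | the ≥70 % nucleotide-identity genus criterion implies most orthologs are shared within a genus; sharing decays up the ranks |
| `pool_sizes` | (2, 3, 4) | each taxon contributes a handful of signature ("hallmark") protein families |

With these conditions the four distance strata order as
within-genus < within-subfamily < within-family < between-families, flat
cuts of the hierarchy recover genera and subfamilies (maximum AMI across the
eps grid ≈ 0.9–0.99 at genus rank across seeds), and one family in some
realizations splits into two branches — the same phenomenon real phage
families (e.g. highly diverse ones) show in practice, which the branch
extraction tests accommodate deliberately.

**What the generator does not emulate:** real embedding geometry
(anisotropic, heavy-tailed family clusters; inter-family correlations of a
trained model), annotation biases of curated databases, partial or
mis-called genomes, and any sequence-level signal (the synthetic path enters
at the embedding layer). Passing tests therefore demonstrate correctness of
the *method's machinery* under its own statistical assumptions, not
performance on real data.

## Hierarchy construction

With a minimum neighbourhood of two points (`minPts = 2`), every point's
core distance is its nearest-neighbour distance, so the mutual-reachability
distance between any pair equals the raw distance and the density
hierarchy's merge heights coincide with single-linkage agglomeration. The
package therefore builds the dendrogram by single linkage and exposes it as
the cluster hierarchy; an independent minimum-spanning-tree oracle (Prim
scan) verifies the merge heights to 1e-12 on randomized instances.

Flat clusters at a distance threshold `eps` are the connected components of
the graph whose edges are pairs at distance ≤ `eps` (evaluated by
union-find over the merge list, with an exact `<=` comparison); singleton
components are labelled noise, following the DBSCAN* convention. An
independent union-find over all pairwise distances verifies every cut.
Partitions provably coarsen as `eps` grows, and the tests check that too.

Ties in distance are resolved by `hclust`'s deterministic merge order on a
fixed input ordering; relabelling the inputs changes cluster ids but never
the partition (tested).

`extract_branch()` operationalizes "the top node of a taxon's genomes and
all its successors" as the internal node whose leaf set maximizes the F1
score against the annotated taxon, with ties broken toward fewer leaves and
lower height; raw in-taxon/other counts are always reported alongside so
other criteria can be applied post hoc.

## Evaluation choices

* **AMI.** Mutual information adjusted by the exact expected mutual
  information under the hypergeometric fixed-margins model, normalized by
  the arithmetic mean of the entropies (the standard choice of the AMI
  literature). Identical partitions — including the trivial single-cluster
  and all-singletons cases, where the adjustment denominator vanishes —
  score 1; a vanishing denominator otherwise scores 0. A full
  permutation-enumeration oracle fixes the expected value at small n.
* **Noise in AMI.** Each noise point becomes its own singleton cluster
  before comparison, so unclustered genomes are never spuriously merged
  into one class.
* **Sentinels.** Genomes labelled `"unclassified"` (or `NA`) are excluded
  from AMI and silhouette evaluation; adding them never changes the scores
  over the evaluated subset.
* **Silhouette.** Standard $s(i) = (b-a)/\max(a,b)$ on MPR-space distances
  (never on 2D projections), with samples in singleton clusters scoring 0.
* **Eps grid.** Default is a 64-point logarithmic grid spanning the range
  of positive merge heights — the scales at which the partition actually
  changes.
* **Threshold analysis.** `n_pairs` (default 10 000) within- and
  between-taxon pairs are sampled uniformly with replacement; the reported
  threshold maximizes Youden's J = TPR − FPR over midpoints between
  consecutive distinct sampled distances, so in a separable dataset it
  falls strictly inside the within/between gap. The raw sampled distances
  are kept in the report so any other criterion can be recomputed.
* **Atlas.** The 2D atlas is a seeded force-directed layout of the
  symmetrized k-nearest-neighbour graph (`n_neighbors` edges per point,
  inverse-distance weights), rescaled so the smallest nonzero separation
  equals `min_dist`. It is deterministic given its seed, used for
  visualization only, and never feeds back into clustering or distances.

## Query placement

`place_query()` follows the workflow for new proteomes: embed, average,
exact nearest-neighbour search (ties broken lexicographically), then a gate:
if the nearest stored genome is farther than `threshold` the query is
reported `unclassified`; otherwise the k-neighbourhood plus the query is
re-clustered and the subtree returned with the query as a leaf. The
threshold has **no default on purpose** — it is a scientific claim about
what "too far to place" means, and `threshold_analysis()` is the intended
calibration source. Neighbours' annotations are reported, never asserted as
the query's taxonomy. The neighbourhood is the k-nearest-neighbour ball;
expanding along the tree branch instead is a possible extension.

## Numerical and storage choices

* All distance and moment computation is float64; at the distance scales
  reported for real embeddings (within-genus scales near 1e-3 of the
  metric), single precision would be marginal after high-dimensional
  accumulation.
* The vector store is a plain-text directory (`accessions.txt`,
  `matrix.tsv`, `metadata.json`); values are written as shortest
  round-trip decimal strings, read back with R's exact parser, so
  round-trips are bit-exact.
* Degenerate inputs error loudly with classed conditions
  (`phagempr_input_error`, `phagempr_format_error`,
  `phagempr_config_error`): zero-norm embeddings, empty proteomes, negative
  concentration or eps, duplicate accessions, dimension mismatches.
* Every stochastic routine takes an explicit seed and applies it locally
  (the caller's random-number state is restored); the command-line
  interface fans one `--seed` out to named per-stage substreams.
* Problem sizes in the checks: 144-genome default datasets, 10 000
  Monte-Carlo replicates per moment configuration, 50 randomized hierarchy
  instances up to n = 200, 10 000 sampled pairs per threshold pool —
  deliberately desk-scale.

## Known limitations

* The bag-of-proteins average discards protein order, gene synteny and
  copy-number context; distinct compositions can collapse to similar means.
* Analytic moments assume independent embeddings with fixed family
  assignments; real embeddings violate independence within operons and
  duplicated families.
* The condensed hierarchy is exposed at full dendrogram granularity
  (every merge is a node); excess-of-mass cluster selection is out of
  scope, and visualization tools are expected to filter.
* A single eps rarely aligns with one taxonomic rank across all clades —
  the AMI-vs-eps profile exists precisely to make that rank/scale
  dependence visible rather than hide it.
* Real protein language model inference is not bundled: the embedding
  backend is a contract (`name`, `dim`, `embed()`), with deterministic
  mock backends for everything desk-scale.
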