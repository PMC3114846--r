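---
title: "Assessing disease modularity with gene-disease networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing disease modularity with gene-disease networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgnet)
```

## The question

Many diseases arise not from a single broken gene but from the disruption
of a *functional module* — a group of gene products that act together in a
pathway or physically interacting complex. dgnet provides a pipeline for
testing this modularity hypothesis on integrated gene--disease association
data: if the genes associated with a disease (or with a cluster of
related diseases) really form a module, they should share pathway
annotations and interact in a reference protein-interaction network far
more often than size-matched random gene sets.

## Data model

Associations are rows of a TSV (`gene_id`, `disease_id`, `source`,
`original_label`, `evidence`) drawn from curated databases (OMIM-style
mendelian phenotype links, UniProt variant annotations, PharmGKB
pharmacogene relations, CTD chemical--disease curation) and a text-mining
channel. Each source's native label vocabulary is harmonized by an
association ontology into four positive classes (`Marker`,
`GeneticVariation`, `RegulatoryModification`, `Therapeutic`) and a
certainty split `Association` / `NoAssociation`. Explicit
`NoAssociation` evidence (PharmGKB "not related", text-mined "negative
association") is retained in the data model and round-trips through I/O,
but `filter_for_analysis()` removes it before any network is built: only
positive associations define edges.

## Networks and weights

`build_bipartite()` assembles a two-class graph (genes vs diseases) from
a chosen source set — the presets `OMIM`, `CURATED` (all expert-curated
sources), `LHGDN` (text mining) and `ALL` mirror the standard comparison
of source tiers. Edges carry the set of reporting sources;
`simplify_bipartite()` collapses this multiplicity so node degree counts
distinct first neighbors (a disease's degree is its locus heterogeneity,
a gene's degree its pleiotropy).

`project()` produces the monopartite disease (or gene) network: two
diseases are joined iff they share an associated gene. Edge weights use
the overlap coefficient

$$w(u, v) = \frac{|N(u) \cap N(v)|}{\min(a_u, a_v)},$$

where $N(\cdot)$ are bipartite neighbor sets and $a_v = |N(v)|$ is the
annotation count. The weight lies in $(0, 1]$ and equals 1 exactly when
the less-annotated node's neighbors nest inside the other's — the natural
"share everything the smaller node has" boundary condition. Isolated
nodes are kept in the projection so that unclustered singletons remain
countable.

## MCL clustering

Module detection uses the Markov Cluster algorithm on the weighted
adjacency: add self-loops (weight 1, damping period-2 oscillation),
column-normalize, then repeat *expand* (matrix square, simulating
random-walk flow), *inflate* (elementwise power, sharpening flow) and
*prune/renormalize* until the matrix stops changing. Clusters are read
from the attractor structure of the limit matrix; attractor systems
sharing a node are merged, so the output is always a partition of the
non-isolated nodes. Defaults (`inflation = 2`, `expansion = 2`,
`loop_weight = 1`, `prune_threshold = 1e-5`, `convergence_tol = 1e-8`,
`max_iterations = 200`) follow common MCL practice; inflation is the
granularity dial and all parameters are exposed through `mcl_params()`.
The implementation is dense, which is comfortable up to a few thousand
nodes; a non-converged run is reported (`converged = FALSE`), not an
error. Column sums are checked to remain 1 within $10^{-9}$ after every
iteration.

Known behavior worth stating: at inflation 2 MCL yields fairly fine
granularity. On weighted projections whose blocks are only thinly
connected (many two-gene diseases that happen not to overlap), MCL
returns pure *refinements* of the underlying blocks. This is a property
of the algorithm, not a defect; we verified the iteration entry-for-entry
against an independent dense implementation.

## Modularity statistics

**Pathway homogeneity.** For a unit $i$ (a disease's gene set, the
pooled genes of a disease cluster, or a gene cluster) with $n_i$
pathway-annotated genes of which $n_i^j$ share annotation $j$,

$$H_i = \max_j \frac{n_i^j}{n_i}.$$

Unannotated genes are excluded from numerator and denominator; a unit
with no annotated gene is undefined and skipped (never an abort). Ties
on the maximizing term break lexicographically.

**HINscore.** For a gene set of size $n$ whose subgraph induced in a
reference human interaction network (HIN) has $cc$ connected components,

$$\mathrm{HINscore} = \frac{n - cc}{n - 1},$$

which is 1 when the set is one connected component and 0 when no two
members interact. Cluster members absent from HIN count as singleton
components by default (they are real cluster members whose interactions
are simply unobserved); `drop_absent = TRUE` switches to the alternative
reading. Sets with fewer than two genes are undefined.

**Null models.** Three randomizations are provided, matching how each
unit type should be controlled: size-matched draws of annotated genes
from the studied network's annotated gene pool (`sample_genes`, for
diseases and disease clusters); permutation of the clustered-gene
multiset over the fixed cluster-size profile (`shuffle_clusters`, for
gene clusters); and size-matched draws from the network genes present in
HIN (for HINscores). The default is $10^4$ resamples. Statistics are
summarized per size bin (defaults 2--5, 6--10, 11--15, 16--30, 31--50,
51--100, >100, disjoint and covering $[2, \infty)$): real means carry
t-based 95% CIs across units, null means carry percentile (2.5--97.5)
CIs across resampled bin means — the two conventions answer different
questions, so both are reported — and the empirical p-value is
$(1 + \#\{\text{null bin mean} \ge \text{real bin mean}\}) /
(1 + N)$, never exactly 0. Binning is by annotated gene count in
`sample_genes` mode (the draws are size-matched on annotated genes) and
by total unit size for cluster shuffles and HINscores; null units
inherit their real unit's bin, so each bin compares like with like.
A single integer seed drives all resampling and is recorded in every
summary.

**Enrichment.** Per-cluster over-representation uses the one-sided
hypergeometric upper tail (Fisher's exact test), the field-standard ORA
choice, with Benjamini--Hochberg q-values over each unit's tested terms.
The conventional report filter is raw p < 0.05, with q alongside. The
universe defaults to the studied network's annotated genes and is
overridable.

## The synthetic generator

`generate_synth()` emulates the statistical structure the analysis
assumes, with known ground truth. Genes are partitioned into $K$
pathways (the home pathway is the primary annotation; with probability
$q$ = 0.1 by default a second random pathway is added, mimicking
multi-pathway genes). Each disease receives a home pathway (round-robin,
keeping blocks balanced and the benchmark deterministic) and
$m_d = 1 + Z$ genes, $P(Z = z) \propto z^{-\alpha}$ truncated at
$m_{\max} - 1$ — a heavy-tailed locus-heterogeneity law whose defaults
($\alpha = 1.5$, $m_{\max} = 100$, with $10 \times 30$ genes available)
span the observed range from two-gene diseases to 50--100-gene
diseases. Genes are drawn from the home pathway with probability $\pi$
(the planted modularity) and uniformly from the remaining genes
otherwise, without replacement within a disease. Each association is
reported by every source independently with its `source_profile`
probability, with at least one source forced by rejection sampling so
the per-source marginals stay interpretable; this reproduces the small
pairwise overlap between curated sources. The surrogate interaction
network links within-pathway pairs with `hin_p_in` (default 0.3) and
cross-pathway pairs with `hin_p_out` (default 0.005).

What the generator deliberately does not emulate: text-mining noise
models, real identifier vocabularies, disease-class hierarchies, or the
empirical marginals of any particular database snapshot. Passing tests
on synthetic data therefore demonstrate that the statistics and their
nulls behave correctly under the planted mechanism — not that any
particular real-data headline value is reproduced. Absolute published
values (mean homogeneities, specific correlation coefficients, cluster
counts) depend on 2009-era database snapshots and are out of scope by
design.

## Validation choices and problem sizes

The test suite exercises the pipeline at sizes chosen for thorough yet
fast desk-scale validation:

* *Planted-module recovery* uses $K = 5$ pathways of 30 genes, 60
  diseases, and near-uniform locus heterogeneity 2--15
  ($\alpha = 0.1$, $m_{\max} = 15$). The near-uniform choice is what
  makes recovery well-posed: under a strongly heavy-tailed law most
  diseases carry only two genes, two such diseases from one 30-gene
  pathway share a gene with probability ~0.13, and the planted blocks
  are then unidentifiable by any clustering. At $\pi = 0.9$ MCL
  recovers the blocks (ARI $\ge 0.8$ across consecutive seeds); at
  $\pi = 0.2$ recovery collapses (ARI $\approx 0$).
* *Shape properties* (real-above-null homogeneity per bin; negative
  homogeneity-size correlation with heterogeneity spanning 2--100;
  HINscore above null in small bins at `hin_p_in = 0.6`,
  `hin_p_out = 0.01`) run on 200-disease datasets with 500--1000
  resamples.
* *Null calibration* draws units from the null itself (200 replicates
  per statistic, 99 resamples each) and checks the rejection rate at
  $\alpha = 0.05$ stays at or below 7%.
* Exact oracles back every numerical kernel: brute-force common-neighbor
  scans for projections, flood-fill component counts, log-binomial tail
  sums for every hypergeometric configuration with $N \le 60$,
  pair-counting for the adjusted Rand index, and direct-formula Pearson
  and group-by means.

## Numerical and design notes

* Lexicographic ordering breaks all ties (cluster ordering, top terms,
  node pairs), making every output deterministic for a fixed input.
* An empty network side has mean degree 0 by convention so that filtered
  pipelines do not abort.
* Derived child seeds are generated by a fixed integer recurrence and
  stay below $2^{31}$.
* The end-to-end `run_pipeline()` is a pure function of (inputs, config,
  seed): stats outputs are byte-identical across reruns, each artifact
  carries the tool version, a configuration hash and the seed in a `#`
  header, and a `DONE` sentinel distinguishes complete runs from
  partial ones.
* This package is a library-first design: the interface is the exported
  functions plus YAML run configs (`read_run_config()`), not a shell
  binary.

## Limitations

MCL granularity is inflation-dependent and no single inflation matches
every network; absolute cluster counts are therefore not meaningful
reproduction targets. The homogeneity statistic treats pathway catalogs
as flat term sets (no ontology propagation, no cross-catalog identity
mapping). The HINscore conditions on the reference interactome and
inherits its ascertainment biases. The generator's independence
assumptions (per-source inclusion, pathway-conditional gene draws) are
idealizations of much messier curation processes.
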