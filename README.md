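# dgnet

Gene–disease network construction, clustering and modularity statistics.

Many diseases are caused not by a single defective gene but by the
disruption of a *functional module* — genes whose products act together
in a pathway or interacting complex. dgnet is an R package for testing
this modularity hypothesis on integrated gene–disease association data:
it builds bipartite gene–disease networks from multi-source association
tables, projects them to weighted monopartite gene and disease networks,
detects modules with the Markov Cluster algorithm (MCL), and quantifies
how "module-like" the resulting gene sets are — against resampling null
models — using two statistics. It is aimed at computational biologists
studying the shared genetic architecture of mendelian, complex and
environmental diseases, and ships a synthetic-data generator with planted
pathway structure so the entire pipeline can be validated against known
ground truth.

## The statistics

**Overlap-weighted projection.** Two diseases (or genes) are connected
iff they share a bipartite neighbor; the edge weight is the overlap
coefficient

    w(u, v) = |N(u) ∩ N(v)| / min(a_u, a_v),    w ∈ (0, 1],

where `a_v` is the number of bipartite neighbors of `v`. Weight 1 means
the less-annotated node shares all its annotations with the other.

**Pathway homogeneity.** For a unit *i* (a disease's genes, a disease
cluster's pooled genes, or a gene cluster) with `n_i` pathway-annotated
genes of which `n_i^j` share annotation *j*:

    H_i = max_j n_i^j / n_i,    H ∈ [0, 1],

1 when every annotated gene sits in one pathway.

**HINscore.** For a gene set of size `n` whose subgraph induced in a
reference human interaction network (HIN) has `cc` connected components:

    HINscore = (n − cc) / (n − 1),

1 when the set is a single connected component, 0 when no two members
interact; members absent from HIN count as singleton components.

Real per-size-bin means of both statistics are compared with size-matched
random controls (gene draws from the annotated network pool, cluster-size-
preserving shuffles, or HIN-restricted draws), with percentile null CIs
and empirical p-values. Cluster gene sets are additionally tested for
pathway/GO over-representation with the one-sided hypergeometric test
and Benjamini–Hochberg q-values.

## Worked example

Generate a synthetic dataset with five planted pathway modules, run the
pipeline, and check the statistics:

```r
library(dgnet)

cfg <- synth_config(n_pathways = 5, genes_per_pathway = 30, n_diseases = 60,
                    het_alpha = 0.1, het_max = 15, modularity = 0.9, seed = 1)
syn <- generate_synth(cfg)

net  <- simplify_bipartite(build_bipartite(filter_for_analysis(syn$records), "ALL"))
proj <- project(net, "disease")
cl   <- mcl(proj)
net; proj; cl
#> bipartite gene-disease network: 147 genes, 60 diseases, 543 edges (simplified)
#> disease projection: 60 nodes, 473 weighted edges
#> MCL clustering: 5 clusters over 60 nodes (+0 unclustered), 10 iterations

planted_partition_recovery(cl, syn$truth$disease_home_pathway)
#> [1] 1
```

MCL recovers the five planted disease modules exactly (adjusted Rand
index 1). The clusters' pooled gene sets are far more pathway-coherent
than size-matched random draws:

```r
units <- cluster_units(cl, net, "disease")
ns <- null_homogeneity(units, "sample_genes", syn$annotation,
                       pool = intersect(net$genes, annotated_genes(syn$annotation)),
                       n_resamples = 1000, seed = 1)
ns$per_bin[, c("label", "n_units", "real_mean", "null_mean", "p_empirical")]
#>   label n_units real_mean null_mean p_empirical
#> 1 31-50       5 0.7273489 0.2869425 0.000999001
```

All five cluster units fall in the 31–50-gene bin; their mean homogeneity
(0.73) is ~2.5-fold the null mean (0.29) with the smallest empirical p
reachable at 1000 resamples. Each cluster is also significantly enriched
for exactly its planted pathway:

```r
enr <- enrich_units(units, syn$annotation)
head(enr[enr$p_value < 0.05, ], 5)
#>    unit_id term_id  k  K  n   N      p_value      q_value
#> 1       c1    PW01 29 32 40 150 1.087460e-18 5.437299e-18
#> 6       c2    PW02 29 33 37 150 1.514506e-19 7.572529e-19
#> 11      c3    PW03 29 31 45 150 2.861798e-17 1.430899e-16
#> 16      c4    PW04 30 34 42 150 1.054535e-17 5.272674e-17
#> 21      c5    PW05 30 30 39 150 6.581464e-24 3.290732e-23
```

`run_pipeline(run_config(...))` chains all of this (plus HINscore nulls
and on-disk artifacts with a `DONE` sentinel) from file inputs or a YAML
config; see the vignette in `vignettes/disease-modularity.Rmd` for the
model, parameter and design details.

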