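# toxnet

Network topology and expression-signature analysis for chemogenomic
toxin-sensitivity screens in yeast.

## The problem

Genome-wide sensitivity screens (e.g. against the trichothecene
mycotoxins deoxynivalenol, DON, and trichothecin, TTC) yield lists of
deletion strains scored 1–4 for sensitivity. Two questions follow:

1. **Do the responsive genes form a coherent functional module?**
   `toxnet` uses the screen hits as *seeds*, extracts the subnetwork of a
   genome-scale genetic-interaction network induced on those seeds (an
   edge is kept only if *both* endpoints are seeds), and characterizes
   the largest connected component (LCC) with five descriptors:

   - global clustering coefficient (transitivity,
     `3·#triangles / #connected triples`),
   - average shortest-path length over unordered pairs,
   - diameter,
   - parametric sphere-based graph entropy
     `I_f(G) = −Σ_v p(v) log2 p(v)` with
     `p(v) ∝ f(v) = α^{Σ_j c_j |S_j(v)|}` where `|S_j(v)|` is the number
     of nodes at distance exactly `j` from `v`,
   - the information-theoretic distance `d = λ·(log2 n − I_f(G))`, the
     deviation from the maximum-entropy (uniform) node distribution.

   Significance is assessed against a permutation null: `B` draws of the
   same number of seeds, resampled uniformly from the network universe,
   with the add-one empirical p-value
   `p = (1 + #{null ≥ observed}) / (n_valid + 1)`.
   Genes with a multidrug-resistance (MDR) score above 3 are removed
   first as nonspecific, and four seed sets are analysed: DON, TTC,
   their union and their intersection.

2. **Do sensitive mutants carry the slow-growth transcriptional
   signature?** For each expression profile, `toxnet` scores
   `mean(respiration genes) − mean(ribosomal-protein genes)`; positive
   scores are pattern A (the slow-growth signature: ribosomal proteins
   down, respiration up), negative scores are the inverted pattern B.
   Supporting operations: quantile normalization, duplicate-probe
   averaging, fold-change filtering (`|log2 FC| > 0.5` in at least one
   condition), signed-log differences, hierarchical clustering on
   `1 − Pearson` distance with average linkage, and exact hypergeometric
   gene-set overlap tests with Benjamini–Hochberg adjustment (background:
   the 4780 non-essential genes for real yeast lists).

Synthetic-data generators (Erdős–Rényi / Watts–Strogatz /
duplication-divergence networks, planted clustered modules, screen
tables, patterned expression matrices) provide ground truth for every
pipeline stage.

## Worked example

```r
library(toxnet)
g  <- generate_network(1000, "erdos_renyi", list(p = 0.01), rng_seed = 1)
pm <- plant_module(g, 50, p_in = 0.3, rng_seed = 2)          # clustered module
st <- generate_screen_table(pm$network, pm$truth, sens_prob_module = 0.9,
                            sens_prob_background = 0.01, mdr_fraction = 0.05,
                            rng_seed = 3)
seeds <- build_seed_sets(mdr_filter(st$records))             # DON/TTC/UNION/INTERSECTION
sub   <- extract_subnetwork(pm$network, seeds$DON)
prof  <- topology_profile(sub)
prof
#> topology_profile: LCC 47 nodes | clustering 0.3310 | APL 1.8575 | diameter 4 | entropy 3.3716 bits | distance 2.183
ens <- sample_null(pm$network, igraph::vcount(sub), B = 200, rng_seed = 4)
profile_vs_null(prof, ens)[, c("metric", "observed", "null_mean", "z", "p")]
#>            metric observed null_mean       z       p
#> 1        lcc_size   47.000     6.015 15.5470 0.00995
#> 2      clustering    0.331     0.018  4.2706 0.02488
#> 3 avg_path_length    1.858     2.055 -0.3373 0.45274
#> 4        diameter    4.000     3.940  0.0362 1.00000
#> 5         entropy    3.372     2.025  4.4587 0.00498
#> 6        distance    2.183     0.434  3.3576 0.03980
```

The planted 50-gene module is recovered as a 47-node LCC that is far
more clustered (0.33 vs 0.02, p ≈ 0.025) and more structured (entropy
z ≈ 4.5) than subnetworks seeded by random gene sets of the same size —
the signature of a genuine functional module. Average path length and
diameter are not informative here because the random seed sets break
into tiny components.

Command line:

```sh
Rscript inst/scripts/toxnet simulate --config run.cfg --out sim/
Rscript inst/scripts/toxnet topology --config run.cfg --B 200 --seed 1
Rscript inst/scripts/toxnet expression --config run.cfg
```

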