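---
title: "Methods: seed-induced subnetwork topology and slow-growth signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-induced subnetwork topology and slow-growth signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxnet)
```

## Overview

`toxnet` analyses toxin-sensitivity screens in two arms. The *topology
arm* asks whether screen-responsive genes occupy a structured
neighbourhood of the genetic-interaction network; the *expression arm*
asks whether mutants or treatments show the slow-growth transcriptional
signature. This vignette explains the models, the tunable parameters,
the numerical choices, and what the synthetic-data tests do and do not
establish.

## The topology model

A screen yields per-gene DON and TTC sensitivity scores in 0–4 (0
meaning "not a hit"; 1–4 grade severity only). Genes with a
multidrug-resistance (MDR) hypersensitivity score above 3 are removed
first: such mutants respond to nearly any insult and carry no
toxin-specific signal. The remaining hits form four seed sets — DON,
TTC, their union and their intersection — and each induces a subnetwork
of the interaction universe: an edge survives only if *both* endpoints
are seeds; seed genes without surviving edges remain as isolated nodes
until the largest connected component (LCC) is taken. All descriptors
are computed on the LCC:

* **Clustering** is the transitivity `3·#triangles / #connected
  triples`, not the mean of local coefficients — the two differ on
  stars and kites, and transitivity is the standard "global clustering
  coefficient" of the graph-library family this analysis builds on.
* **Average path length** is the mean breadth-first distance over
  unordered node pairs; **diameter** its maximum. Both require a
  connected graph, which the LCC step guarantees.
* **Graph entropy**: each node receives an information functional
  `f(v) = α^{g(v)}` with `g(v) = Σ_{j=1..ρ} c_j |S_j(v)|`, where
  `|S_j(v)|` is the j-sphere cardinality (nodes at distance exactly
  `j`) and `ρ` the diameter. Normalizing `f` over nodes yields a
  probability distribution; its Shannon entropy (bits) is the
  descriptor. Vertex-transitive graphs achieve the maximum `log2 n`
  exactly. The **distance** descriptor is `λ·(log2 n − entropy)`: zero
  exactly at uniformity, growing as structure concentrates probability
  on few nodes.

### Entropy parameters and conventions

The coefficient scheme, base and scale are genuinely open choices — the
analysis tradition fixes only that exponentially decaying sphere
weights ("exp") are used, and no published numeric entropy values exist
to pin the constants. `toxnet` exposes them as parameters with
documented defaults:

| parameter | default | meaning |
|---|---|---|
| `scheme` | `"exp"` | `c_j = ρ e^{−j}`; also `const` (`c_j = 1`) and `lin` (`c_j = ρ−j+1`) |
| `alpha`  | 2       | base of the functional, `> 0`, `≠ 1` |
| `lambda` | 1000 (`entropy_distance`), 1 (profiles/tests) | scale of the distance |

The `exp` weights emphasize near spheres and scale with the diameter so
`c_1` grows on wider graphs; this is recorded as a convention, and all
descriptors are comparable only within a fixed parameter choice — the
null comparison always uses the same parameters on both sides.

### Numerical choices

`g(v)` is `O(ρ·n)` and reaches the thousands on genome-scale LCCs, so
`α^{g(v)}` overflows double precision. All functionals are therefore
carried in the log domain and normalized by max-shift
(`p = exp(log f − max log f)`, renormalized). Probabilities that
underflow to exactly 0 after the shift contribute 0 to the entropy sum;
their true contribution is below double precision. The LCC tie-break
(largest component containing the lexicographically smallest label) is
arbitrary but deterministic; ties essentially never occur on real data.

## The permutation null

Observed descriptors are compared against `B` (default 1000; tests use
50–200) resamples in which the seed set is replaced by the same number
of genes drawn uniformly without replacement from the universe. This
tests the hypothesis "screen hits are topologically special" against
"any gene set of this size"; it deliberately does not preserve degrees
(an edge-rewiring null would answer a different question).

Three choices deserve comment:

* **Add-one estimator.** `p = (1 + #{null ≥ obs}) / (n_valid + 1)`:
  the standard finite-B permutation estimator, never exactly zero.
* **Degenerate samples.** Random seed sets in a sparse universe often
  induce an LCC with fewer than 3 nodes, where the descriptors are
  undefined. Such samples are excluded and counted (`n_degenerate`), so
  users can see when a sparse universe makes the null unreliable,
  rather than silently scoring them 0.
* **Directional alternatives.** Clustering and entropy test `greater`,
  average path length `less`, diameter and distance `two_sided`,
  following the directional claims the topology arm makes. No
  significance threshold is hard-coded; p, z, and the degenerate count
  are all reported.

A structural caveat: null LCCs are typically much smaller than an
observed module's LCC, so path-length and diameter comparisons mix
size effects with shape effects. The LCC-size row of the report makes
this visible.

## Enrichment

Gene-set overlaps use the exact upper-tail hypergeometric
`P(X ≥ k)` summed in log space (stable at `N ≈ 5000` and `p ≈ 1e−10`),
with the background always an explicit argument — for real yeast hit
lists the 4780 non-essential genes. Multiple tests are adjusted with
the Benjamini–Hochberg step-up rule. Published overlap p-values for
such screens rarely state the exact test variant or background;
agreement should be expected in order of magnitude only.

## The expression arm

The pipeline starts from probe-intensity or log-ratio matrices;
background correction and array-level linear modelling are upstream and
out of scope. Operations, in order:

1. **Quantile normalization** (classic: rank, replace by the mean of
   order statistics across arrays; ties get the mean of their rank
   positions' reference values).
2. **Duplicate-probe averaging** into gene rows; unmapped probes are
   dropped with a count.
3. **Fold-change filter**: keep genes with `log2` value strictly above
   `0.5` or strictly below `−0.5` in at least one condition. The strict
   inequality is a declared reading of the directional wording "above";
   boundary values are excluded.
4. **Signed-log differences** for absolute-change analyses: raw
   differences are signed, so a plain log is undefined; the odd map
   `sign(Δ)·log2(1+|Δ|)` is monotone, odd, and equals `log2 Δ` for
   large `Δ`. Rows are then median-centered, matching the heat-map
   preparation convention of the clustering tools this emulates.
5. **Hierarchical clustering** with `1 − Pearson` distance and average
   linkage (the common default of those tools; both are configurable),
   serializable to Newick.
6. **Signature score** `mean(respiration set) − mean(RP set)`:
   pattern A (slow growth) if positive, B if negative, `none` at exactly
   0 or when a required set does not intersect the profile. The score
   formalizes what is usually read off heat maps by eye; the zero
   boundary is surfaced rather than guessed, and the score is invariant
   to profile-wide additive shifts.

## Synthetic data: what it emulates, what it does not

The generators produce the statistical structure the analysis assumes,
with ground truth recorded for every artifact:

* a sparse background network (default for end-to-end tests:
  Erdős–Rényi `n = 1000`, `p = 0.01` — roughly the density regime of
  intermediate-stringency genetic-interaction networks, and small
  enough for tests to run in seconds) containing a planted 50-gene
  module whose within-module edge probability `p_in = 0.3` makes it
  detectably more clustered than background;
* screen tables whose sensitivity concentrates on module genes
  (`sens_prob_module = 0.8–0.9` vs `0.01` background — a strong screen),
  scores uniform on 1–4, with MDR scores (uniform 1–15 on a 5% random
  subset) drawn *independently* of sensitivity so the MDR filter's
  effect on power is measurable;
* expression matrices with disjoint RP and respiration sets (10% of
  genes each), effect `±1` log2 unit, Gaussian noise `sd = 0.5` —
  effect and noise chosen so single-condition calls are reliable but
  not trivial (score sd ≈ 0.07 at 100-gene sets against a separation
  of 2).

Real data differ in known ways the generators do not model: degree
distributions are heavy-tailed rather than Poisson; interaction
false-negative rates are nonuniform; sensitivity scores correlate with
degree; expression noise is gene-dependent and correlated across
conditions. A green test therefore establishes that the *machinery* is
correct and well calibrated under its stated assumptions — not that any
particular biological conclusion transfers.

## Calibration and power, as tested

With random "observed" seeds the empirical p is approximately uniform
(the acceptance suite checks the fraction of runs with `p ≤ 0.05` per
metric lies in `[0.01, 0.12]` over 200 runs); with the planted module,
the clustering p is `≤ 0.05` in at least 18 of 20 runs at `B = 200`.
The occasional miss is informative: a sparse null draw whose LCC is a
single triangle has transitivity 1 and beats any realistic module, so
at small `B` a handful of such draws can push p above 0.05. Raising `B`
(the default is 1000) sharpens the estimate.

## Known limitations

* Descriptors beyond the five implemented (degree-based or
  eigenvalue-based entropies, comparison kernels) are out of scope.
* The null resamples seeds, not edges; degree-preserving nulls are a
  deliberate non-goal.
* Identifier harmonization is the caller's job: node labels are opaque
  case-sensitive strings and screen genes absent from the universe are
  dropped (with a logged count), never aliased.
* The expression arm does not reproduce any specific published
  microarray dataset; it implements the processing conventions needed
  to analyse such data once provided in matrix form.
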