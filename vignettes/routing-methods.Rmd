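---
title: "Thalamic embedding in the connectome: efficiency, routing costs and brain-behaviour statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thalamic embedding in the connectome: efficiency, routing costs and brain-behaviour statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalroute)
library(dplyr)
```

## The question and the data model

thalroute studies how a pivot region — canonically the left thalamus —
is embedded in a child's structural connectome, and how that embedding
relates to reading skill. The data model is a `weighted_connectome`: a
labelled symmetric matrix of streamline counts over 90 AAL grey-matter
regions, with an optional parallel matrix of per-edge mean fractional
anisotropy (FA). Edges carrying fewer than three streamlines are removed
(`threshold_edges()`) to suppress false-positive tracts. Two networks are
analyzed per subject: the whole-brain graph and the *hub-attached reading
network*, the induced subgraph over the union of that subject's hubs
(degree strictly greater than 20) and a fixed list of 13 left-hemisphere
reading regions that includes the thalamus.

## Nodal efficiency

Two standard nodal measures describe the pivot's local wiring:

* **Clustering coefficient (CC)** — the fraction of closed triangles
  around the node. Binary mode is `2T / (k(k-1))`; weighted mode uses the
  Onnela geometric-mean triangle intensity over max-normalized weights,
  which reduces exactly to the binary value on uniform weights.
* **Local efficiency (LE)** — the mean inverse shortest-path length among
  the node's neighbours, with paths restricted to the neighbour-induced
  subgraph (the centre excluded, so two-step detours through it cannot
  masquerade as local routes). Nodes of degree below 2 score 0 in both
  measures.

The weighted variants are the default because streamline-count networks
are weighted; the binary variants exist because they admit exact
closed-form tests and because the field reports both. Every output
records which mode was used.

## The λ-tuned routing model

Communication between a source and a target is modelled as a biased
random walk whose transition probabilities blend local edge costs and
global shortest-path information. With `d_ij` the length of edge `(i,j)`
(by default the reciprocal of the streamline count) and `g_jt` the
geodesic distance from `j` to the target `t`,

$$P_\lambda(Y = j \mid X = i, T = t) \;=\;
  \frac{\exp\!\big(-(\lambda\,(d_{ij} + g_{jt}) + d_{ij})\big)}{Z_{it}},$$

where `Z_it` sums the same expression over the neighbours of `i`. The
exponent is implemented exactly in this form — `d_ij` appears both
λ-scaled and unscaled — because any algebraic "simplification" changes
the probabilities. At `λ = 0` the walk is the unbiased, locally
weight-driven diffusion; as `λ → ∞` all mass concentrates on the
neighbour minimizing `d_ij + g_jt`, i.e. the Dijkstra successor, and the
walk becomes shortest-path routing.

Two costs summarize a strategy, both computed exactly from the absorbing
Markov chain with the target as the absorbing state:

* **Transmission cost** `C^trans(s→t)`: the expected total edge length
  walked before absorption — the solution of `(I − Q)c = r`, where `Q` is
  the transient block and `r_i` the expected one-step length from `i`.
  It is bounded below by the geodesic distance and decreases towards it
  as λ grows.
* **Informational cost** `C^info(s→t)`: the expected number of bits
  (base-2 KL divergence) needed to implement the strategy relative to the
  null walk, accumulated over expected node visits: `(I − Q)c = k` with
  `k_i = KL(P_i \,\|\, P^0_i)`. It is zero at the null and non-decreasing
  in λ.

The null strategy is the `λ = 0` walk (a uniform-over-neighbours null is
available by configuration). Linear systems are solved directly per
target — never by explicit matrix inversion — and transition rows are
built with a row-wise exponent shift so that large λ cannot underflow;
the shift cancels in the normalizer. Nodes with no route to a target are
dropped from that target's transient set and reported.

### The λ grid and averaging windows

Cost spectra are evaluated on a grid of 30 equally spaced `ln(λ)` values.
The package ships two presets: a `"printed"` grid on `[-2.2, 1.45]`, and
the default `"consistent"` grid on `[-5.1, 2.76]`, chosen so that the two
fixed cost-averaging windows — `[-5.1, 0.15]` for transmission cost and
`[-0.14, 2.76]` for informational cost — are representable inside the
grid. Scalar per-subject costs are the arithmetic means of the per-λ
curves over a window, either these fixed closed intervals or data-driven
windows derived from normalized curves (below).

### Pivot aggregation

To score how the reading network communicates *through* the pivot, the
pivot is treated as a temporary target and source: `C_thal` sums, per λ
and per cost kind, the cost from every reading region into the pivot and
from the pivot out to every region. Costs are direction-specific —
`cost(s→t)` generally differs from `cost(t→s)` because transitions are
defined per target — and the asymmetry is preserved, not averaged away.
A mean-over-regions variant is available by flag.

## Null networks and normalized costs

Raw costs are confounded by degree, strength and weight distributions, so
they are normalized against randomized counterparts that preserve those
properties: topology is rewired by degree-preserving double-edge swaps
(10 swap attempts per edge), then the original weight multiset is
reassigned to the new topology by iterative rank-matching against
residual endpoint strengths. Degrees and the weight multiset are
preserved exactly; node strengths to a median relative deviation of a few
percent (the contract tested is ≤ 10%). The normalized curves
`‖C‖ = C(emp) / C(rand)` use the mean over an ensemble (500 members at
study scale; smaller, always-recorded ensembles in tests) of pair-averaged
member costs. The *efficient window* is the set of grid points where a
ratio is strictly below 1 — where the empirical network routes more
cheaply than chance.

## Brain-behaviour statistics

Associations between network measures and reading scores use partial
correlations: Pearson correlation of residuals after projecting both
variables on an intercept plus covariates, with two-sided p-values on
`n − k − 2` degrees of freedom. Age-normed standard scores (SWE, PDE,
passage comprehension) control for sex, mean FA within the hub-attached
network, and handedness; rapid automatized naming (RAN), which is not
age-normed, additionally controls for age. Covariates that are constant
in a cohort (an all-right-handed sample) are dropped with a warning.

Family-wise error over a batch of (metric × score) tests is controlled by
a max-statistic Monte-Carlo permutation scheme: outcome residuals are
permuted Freedman–Lane style with a common permutation across the family,
partial correlations are recomputed, and the family maximum `|r|` forms
the null; corrected p-values use the add-one convention, so they are
never exactly zero and are valid at finite samples. The default family is
(CC, LE) × (SWE, PDE, PC, RAN) — eight tests — and is configurable.

Hierarchical regression asks whether communication costs explain variance
beyond the efficiency measures: Model 1 holds the covariates, Model 2
adds CC and LE of the pivot, Model 3 adds the transmission and
informational costs. Each increment is tested with
`F = (ΔR²/q) / ((1 − R²)/(n − p − 1))`.

## The synthetic cohort generator

Because the motivating MRI cohorts are access-restricted, every stage is
exercised on synthetic cohorts (`generate_cohort()`). The generator
emulates the *statistical* structure the analysis touches and nothing
more:

* a template connectome with a hub clique and a modular, degree-capped
  periphery; the pivot is planted as one of the hubs (the thalamus is a
  canonical hub region), and exactly the planted nodes exceed the degree
  threshold;
* per-subject integer-preserving multiplicative jitter of edge weights
  (log-normal, SD 0.15) and per-edge FA values from a truncated normal on
  `[0.30, 0.60]` (rounded to 4 decimals, the precision such maps
  realistically carry);
* covariates: age uniform on 9–14 years, sex Bernoulli(0.5), handedness
  Bernoulli(0.95 right);
* reading scores on the standard-score scale (mean 100, SD 15; the
  non-planted scores use cohort-typical means and SDs), with the planted
  score built as `score = 100 + 15(ρ z + \sqrt{1-ρ^2}\,ε)` where `z` is
  the standardized target metric computed **through the real pipeline**,
  so recovery tests exercise the exact estimator used on real data.

What the generator does *not* emulate: geometry (no spatial embedding, no
fibre anatomy), test–retest noise, realistic inter-score correlations
(scores other than the planted one are drawn independently), or
hemispheric structure beyond the packaged label lists. Passing tests
therefore demonstrate the correctness and calibration of the estimators,
not anatomical realism.

## Numerical and design choices

* **Weight→length transform**: reciprocal (`d = 1/w`) by default, the
  common convention for streamline counts; `-log(w/max w) + ε` available
  because conclusions can depend on it.
* **Linear solves**: direct `solve((I − Q), b)` per target; the same
  factorization serves transmission and informational costs as two
  right-hand sides.
* **Degenerate inputs**: asymmetric, negative or mislabelled matrices are
  rejected naming the offending cell; unreachable pairs get infinite cost
  and are excluded from averages with a reported count; empty efficient
  windows fall back to the fixed windows in the pipeline, with a warning.
* **Determinism**: every function that draws randomness takes a seed; the
  pipeline derives named sub-seeds (template, subjects, phenotypes,
  nulls per subject, permutations) from one master seed, so reruns are
  byte-identical.
* **Oracle strategy in the tests**: closed-form fixtures and brute-force
  enumeration (triangles, Floyd–Warshall, exhaustive walk enumeration on
  a 3-node graph) check the diffusive and small-graph regimes exactly;
  value iteration provides an inversion-free check of the absorbing-chain
  solves; the Monte-Carlo walk oracle (100,000 walks) is compared at 1%
  in the strong-bias regime (`ln λ ∈ {3, 4, 5}`), where its sampling
  error is several times smaller than the tolerance — in the diffusive
  regime the raw walk estimator cannot resolve 1% at that sample size,
  which is a property of the estimator, not of the analytic costs.
* **Problem sizes in the test suite**: statistical calibration uses
  64-subject cohorts on 30-node connectomes (200 null replicates, 500
  permutations; 20 planted replicates, 1000 permutations); null-model
  contracts use 90-node connectomes with 50-member ensembles; the
  end-to-end determinism check runs 14 subjects at 20 nodes with 4 nulls.

## A worked example

```{r example, eval = FALSE}
x  <- generate_connectome(seed = 1) |> threshold_edges()
nd <- network_definition(reading_network_labels(),
                         identify_hubs(x), "THA.L")
sub  <- hub_attached_subnetwork(x, nd)
spec <- cost_spectrum(sub, pivot_pairs(nd), lambda_grid())
tc   <- thalamic_cost(spec, nd)
window_average_cost(filter(tc, cost == "trans"), c(-5.1, 0.15), "total")
autoplot(spec)
```

## Known limitations

* The routing model requires each analysis component to be connected;
  heavily thresholded subject networks can fragment, and dropped nodes
  are reported rather than imputed.
* Strength preservation in the null model is approximate by construction;
  the exactness trade-off (degrees and weights exact, strengths within
  tolerance) follows the cited two-stage convention.
* Empirical effect sizes from the motivating study are not reproduction
  targets: they derive from restricted MRI data, and the package's claims
  are calibration and correctness claims on synthetic cohorts.
* Detection power of the max-statistic correction at ρ = 0.4, n = 64 over
  an 8-test family with independent scores is approximately 0.7; families
  of strongly correlated tests are corrected less severely and detected
  more often.
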