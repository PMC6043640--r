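---
title: "Influence networks from athlete test batteries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Influence networks from athlete test batteries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprintnet)
```

## The problem and the model

A sprinter's performance depends on aerobic, anaerobic, anthropometric and
biomechanical factors measured in different tests. Analysing each output
against a single outcome discards the interactions between them. `sprintnet`
instead represents the test battery as a complex network: each measured
variable is a node, and two variables are linked when their across-subject
correlation is at least moderate. The graph is *G* = {*N*, *L*, *f*} with a
symmetric connection matrix **C** of normalized link weights; links are
bidirectional because, from observational correlations, influence cannot be
assigned a direction.

Two fixed registries define the node sets: 18 variables for free running on
a track and 23 for tethered running (the same 18 plus power, force, work,
step frequency and step length from the load-cell instrument). The time
limit of the exhaustion test is itself a variable, which is what makes the
counts 18 and 23. Registry order is canonical and every registry variable
appears as a node even when isolated, so networks from different cohorts are
comparable node-for-node.

Three metrics summarise a node's structural role, deliberately capturing
different notions of importance:

* **Degree** counts a node's links; its maximum is the hub.
* **Eigen-importance** is the node's component of the leading eigenvector of
  **C**. It weights a node by the importance of its neighbours, and the
  accompanying leading eigenvalue λ classifies the linear influence dynamics
  S(t) = **C**ᵗS(0) as decaying (λ < 1), marginal (λ = 1) or growing
  (λ > 1).
* **Betweenness** credits a node with the fraction of shortest paths between
  other pairs that pass through it — a bottleneck/broker measure.

Because the three metrics rank different aspects, the composite "performance
node" list aggregates them by Borda count: within each metric, a node ranked
*r* of |N| (descending value, ties averaged) earns |N| − *r* points, and the
composite score is the sum over the three metrics. Borda was chosen as the
simplest scheme consistent with weighting nodes "by their ranking
positions"; it is rank-based, hence invariant to monotone transforms of any
one metric. One caveat is inherent to rank aggregation: Borda is not
independent of irrelevant alternatives, so deleting a low-ranked node can
shift composite scores when that node interleaves with survivors on a single
metric. The top list is provably stable only under removal of nodes that are
dominated on every metric.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `weak` | 0.3 | minimum \|c\| (dimensionless) for a pair to become a link |
| `high` | 0.7 | \|c\| boundary between moderate and high links |
| `method` | `"pearson"` | correlation; `"spearman"` for rank-based |
| `eps` | 1e-10 | power-iteration stopping tolerance on ‖q⁽ᵏ⁾ − q⁽ᵏ⁻¹⁾‖ |
| `max_iter` | 10000 | power-iteration cap; exceeding it is an error, not a silent return |
| `shift` | 1 | diagonal spectral shift used during iteration (see below) |
| `weighted_betweenness` | `FALSE` | measure path length as Σ 1/weight instead of hops |
| `k` | 10 | composite top-list length |

The classification boundaries deserve a note: the partition is
sign-symmetric with 0.3 inclusive toward moderate and 0.7 inclusive toward
high — weak |c| < 0.3, moderate 0.3 ≤ |c| < 0.7, high |c| ≥ 0.7. This is the
only reading under which the three classes partition [−1, 1] exactly, and
the package treats it as definitional: `classify_correlation()` is total on
[−1, 1] and rejects anything outside.

Negative coefficients are retained on links as `c_raw`, but classification,
weights and **C** use magnitudes. The spectral and path metrics require
nonnegative weights, and a strong negative correlation is as much an
influence as a strong positive one. The normalization denominator is the
maximum |c| over *retained* links, not over all candidate pairs, so the
strongest link always has weight exactly 1.

## Numerical choices

**Power method with a spectral shift.** Plain power iteration fails to
converge on bipartite-like graphs — a star's adjacency spectrum is symmetric
(±√k), so iterates oscillate between two mixtures forever. Iterating on
**C** + I instead has the identical eigenvectors, and shifts the spectrum so
the Perron eigenvalue is strictly dominant in magnitude (all eigenvalues of
a symmetric nonnegative matrix lie in [−λ₁, λ₁], hence λᵢ + 1 < λ₁ + 1 in
magnitude unless λᵢ = λ₁). The reported λ is always the Rayleigh quotient on
the *original* **C**. Starting vectors are drawn strictly positive from a
caller-supplied seed (global RNG state is saved and restored), and the sign
convention makes the largest-magnitude component positive, so connected
networks get the strictly positive Perron vector. With degenerate dominant
eigenvalues (e.g. two disconnected identical components) the iteration
converges to a start-dependent mixture inside the dominant eigenspace;
within each component the symmetry of the solution is preserved.

**Betweenness.** Shortest paths are hop counts on the unweighted link
skeleton, with fractional credit σ_st(v)/σ_st, endpoints excluded, each
unordered pair counted once, and unreachable pairs contributing zero —
computed by Brandes' single-source accumulation (BFS per source; O(n²)
Dijkstra per source in the weighted variant). Hop counts are the default
because link selection already thresholds on |c|; treating 1/weight as a
distance is exposed as `weighted = TRUE` since the choice can change the
argmax node. The weighted variant is cross-checked against igraph in the
test suite.

**Ties.** Every per-metric argmax breaks ties by the lexicographically
smallest variable name (byte order), and the composite ranking orders equal
scores the same way. This makes all reports deterministic.

**Degenerate inputs.** Zero-variance columns are rejected by the correlation
stage with the offending column named. An all-zero **C** is a named
degenerate-matrix error for the eigen machinery; a link-free network has no
defined eigen-importance. The influence trajectory accepts any square
nonnegative **C** and classifies the regime with a tolerance of 1e-8 around
λ = 1.

## The synthetic generator

The study's per-athlete raw data are not deposited, so the generator stands
in for them. It emulates exactly two features of the real data: the
published per-variable quartiles, and a user-planted latent correlation
structure.

* **Margins.** Each variable's quantile function is piecewise linear through
  (0.25, q1), (0.5, median), (0.75, q3), with tails extrapolated linearly
  from the adjacent segment and floored at zero (no negative times, masses
  or rates). Only three quantiles per variable are published, which is why
  interpolation was chosen over resampling.
* **Dependence.** A Gaussian copula: latent standard normals with the
  planted correlation matrix, pushed through the margins. Rank correlations
  are preserved exactly (the population Spearman of a planted ρ is
  (6/π)·asin(ρ/2)); Pearson correlations are attenuated slightly by the
  nonlinear margins.
* **Feasibility repair.** Hand-planted targets are often not positive
  semidefinite — a hub tied at 0.85 to five mutually uncorrelated neighbours
  is infeasible (the hub row alone forces a negative eigenvalue). Every
  target therefore passes through `nearest_correlation_repair()`, Higham's
  alternating projections with Dykstra correction onto the PSD cone and the
  unit-diagonal set. Repair *shrinks* infeasible hub ties (to ≈ 0.55 in the
  scenario above) and raises neighbour–neighbour correlations; planted
  structures are scenario parameters, not estimates of the real cohort.

What the generator does **not** emulate: physiological forward structure
(power–velocity relations, VO₂ kinetics), measurement error models,
outliers, or any dependence beyond a Gaussian copula. Passing recovery tests
therefore shows the *pipeline* recovers planted statistical structure — it
says nothing about which variable is the hub in the real cohort, which
cannot be recomputed without the raw data.

Two registry margins are nearly or exactly degenerate (tethered mean R has
q1 = median = q3 = 1.2): these produce constant columns, with a warning if
correlation was planted on them, and at small n even near-degenerate margins
(free-running peak R) can draw a constant column that the correlation stage
then rejects. That is faithful behaviour, not a bug: a variable with no
cohort variance carries no correlational information.

Default cohort size for demonstrations is the study's n = 8, with the
obvious caveat that correlation estimates from eight subjects have standard
errors around 0.35 on the Fisher z scale — at that size, planted-hub
recovery succeeds only in roughly a fifth of replicates, versus ≥ 95/100 at
n = 200 (both rates are recomputed by `scripts/acceptance.R`). Calibration
and property checks in the test suite use n between 200 and 10000 and modest
replicate counts (100 for recovery, 50 random graphs for the betweenness
oracle, matrices up to 23 × 23 for the eigen oracle) — sizes at which the
Monte-Carlo noise is far below the asserted tolerances.

## Statistical limitations

Link selection thresholds on effect size |c| only; no p-values and no
multiple-testing correction are involved, by design fidelity to the
procedure the package implements. With 153–253 candidate pairs and a small
cohort, some retained moderate links will be noise; conclusions should rest
on the metric *pattern*, not on any single link. The networks are static:
per-subject scalar summaries, not time series, so none of the lagged or
directed coupling measures of the wider network-physiology literature apply
here.

## Worked pipeline

```{r example, eval = FALSE}
st  <- structure_hub(sprint_variables("free")$name, "aerobic_capacity",
                     c("c_vo2", "peak_p_vvo2", "peak_p_vo2",
                       "mean_velocity", "peak_vo2_pct"))
tab <- generate_athletes(free_model_preset(), structure = st, n = 200, seed = 42)
run <- run_pipeline(tab, seed = 1)
glance(run)
autoplot(run$network)
autoplot(run$ranking)
write_run_bundle(run, "out/")
```

Identical inputs, configuration and seed always produce byte-identical
bundles (the manifest records the input hash and configuration and contains
no timestamps).
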