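---
title: "Methods: FDR-calibrated scoring and multi-objective module search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FDR-calibrated scoring and multi-objective module search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamod)
```

## The problem

Given an undirected molecular interaction network $G = (V, E)$ with a
differential-expression p-value $p_v$ per gene, an *active module* is a
connected subnetwork whose genes jointly show significant expression change.
Finding the maximum-scoring connected subgraph is NP-hard, and a purely
data-driven score tends to fragment into the few strongest genes. `pamod`
treats module identification as a constrained two-objective problem:
maximise the module's activity *and* its coverage of annotated pathways,
subject to connectedness. The Pareto front then exposes the whole trade-off
between novel signal and prior knowledge instead of committing to one
weighting.

## Node scoring via a beta-uniform mixture

P-values across genes are modelled as a two-component mixture: a
Uniform(0,1) null and a Beta($a$, 1) signal with $0 < a < 1$,

$$f(x \mid a, \lambda) = \lambda + (1-\lambda)\,a\,x^{a-1}.$$

`fit_bum()` estimates $(a, \lambda)$ by maximum likelihood. With
$\hat\pi = \lambda + (1-\lambda)a$ (the density at $x = 1$, an upper bound
on the null fraction), the threshold that controls the estimated FDR upper
bound at level $\alpha$ is

$$\tau = \left(\frac{\hat\pi - \alpha\lambda}{\alpha(1-\lambda)}\right)^{1/(a-1)},$$

and each gene scores $S^{FDR}(x) = (a-1)(\log x - \log\tau)$: zero at
$\tau$, positive below, negative above, unbounded as $x \to 0$.

Numerical choices:

* **Optimiser.** Bounded quasi-Newton (L-BFGS-B) on the box
  $[10^{-6}, 1-10^{-6}]^2$, restarted from the five best points of a coarse
  $5\times5$ grid; the restart with the highest log-likelihood wins
  (objective tolerance $\approx 10^{-8}$ via `factr = 1e7`). The likelihood
  surface is smooth but can be flat in $\lambda$ when the signal is weak;
  the restarts make the fit deterministic and box constraints keep the
  parameters in the open unit square. The test suite checks the optimum
  against an exhaustive parameter-grid oracle.
* **Zero p-values.** The density diverges at $x = 0$, so exact zeros are
  clamped to `p_min` ($10^{-300}$ by default, configurable) before fitting
  and scoring; $p = 1$ is retained as-is.
* **Logarithms.** Natural logs throughout; the scoring formula is a
  log-density ratio, so the base cancels against the likelihood machinery.
* **$\tau > 1$.** When $\alpha \ge \hat\pi$ the power base drops below 1 and
  the formula yields $\tau > 1$; `bum_tau()` clips to 1 with a warning,
  which makes every p-value score positively — the only coherent reading of
  the score at such permissive levels.

### Choosing $\alpha$

$\alpha$ sets the operating point of the whole method: the score of a gene
with $p$-value $x$ is positive only when $x < \tau(\alpha)$. For signal
p-values distributed Beta($a$,1), $\mathbb{E}[\log x] = -1/a$, so the
*expected* score of a signal gene is $(1-a)(1/a + \log\tau)$ — positive only
when $\tau > e^{-1/a}$. We therefore default `search_config(fdr_alpha =)` to
0.01, which on the benchmark's signal strength ($a = 0.1$) puts $\tau$
around $5\times10^{-4}$, comfortably above $e^{-10}$, so typical signal
genes pull a module's score up while background genes (expected score well
below zero) push it down. Much more stringent levels (e.g. $10^{-4}$) are
appropriate when, as in very strongly perturbed datasets, the majority of
genes are highly significant and the analyst wants to shrink the detected
modules; `fit-bum`'s command-line default keeps that stringent level for
threshold exploration.

## Objectives

* **Activity** $S_A = \sum_{x \in A} S^{FDR}(x)$, additive by construction.
* **Coverage** $R_A = |\{i : R_i > R_{ratio}\}|$ with
  $R_i = |V_i \cap V_A| / |V_i|$, a *strict* inequality: a pathway covered
  at exactly the threshold does not count.

The denominator $|V_i|$ uses the pathway as annotated, including genes
absent from the network — a module can then never cover a pathway whose
members were filtered out of the network, which we consider the honest
default. The alternative (restricting $V_i$ to network genes) is available
everywhere via `restrict = TRUE` / `--restrict-pathways-to-network`.

$R_{ratio}$ controls how much of a pathway a module must absorb before the
coverage objective credits it. Too high and the search cannot expand beyond
a tiny core; too low and the objective saturates and stops discriminating.
The two presets used on the study networks were 0.6 (small, 330-gene
network) and 0.8 (1803-gene network); 0.6 is the package default, and the
value should in practice be chosen by a small preliminary sweep.

Internally both objectives are negated (the engine minimises); every
user-facing table reports them on the maximisation scale.

## Connectedness as an algebraic constraint

Feasibility of a module is decided by its algebraic connectivity: the
second-smallest eigenvalue of the induced Laplacian $L = D - A$, positive
iff the subgraph is connected. A dense symmetric eigensolver is used —
modules are small relative to the network, so iterative sparse machinery
would buy nothing at this scale. Conventions: eigenvalues are compared
against $\varepsilon = 10^{-8}$ to absorb floating-point noise; size-1
modules are connected by definition (a $1\times1$ Laplacian has no second
eigenvalue); empty modules are infeasible. The test suite cross-checks the
spectral decision against graph traversal on hundreds of random graphs, and
they never disagree.

## The search engine

A modified NSGA-II over binary membership vectors of length $|V|$. The node
ordering underlying those vectors is fixed at network construction:
lexicographic by gene ID in the C locale. Some ordering must be chosen —
single-point crossover semantics depend on it — and a sorted order is
deterministic, locale-independent and recorded in the result object.

Per generation:

1. **Selection.** Binary tournament under constrained-crowded comparison
   (feasible beats infeasible, then lower rank, then larger crowding
   distance, then a coin flip). When more than
   `tournament_skip_dup_fraction` (default 0.5) of the population are
   duplicate selections the tournament is skipped and the whole population
   reproduces — converged populations need less selection pressure, and a
   fixed duplicate-fraction trigger makes the rule reproducible.
2. **Crossover.** Single-point with probability `crossover_rate` (0.9); the
   cut is uniform on $1 \dots |V|-1$. Offspring may be disconnected; they
   are *not* repaired — the constraint handles them.
3. **Mutation.** Adds `mutation_additions` (default 1) nodes drawn uniformly
   from the module's neighbours that either score positively or belong to a
   pathway. Restricting candidates to neighbours keeps mutation
   growth-connected; there is no deletion operator, so shrinkage arises only
   from crossover. All-zero offspring are simply marked infeasible.
4. **Clearing.** Bit-identical selections in the merged 2N population are
   detected; the first copy keeps its feasibility, the rest are marked
   infeasible and die at replacement. This niching step prevents a converged
   population from flooding the front with copies.
5. **Sorting and replacement.** Constrained fast non-dominated sorting plus
   crowding distance, then truncation to N by (rank, −crowding). Because
   objective-wise extremes always receive infinite crowding distance, the
   best feasible $S_A$ (and $R_A$) ever found survives truncation — the
   elitism property asserted from the run history in the tests.

The stopping criterion is a fixed generation count (default 200) — the
simplest reproducible rule. Population size defaults to 50; seeds are the
top-`population_size` scoring nodes (ties broken by gene ID), each grown by
its positive-scoring neighbours, and when the population exceeds $|V|$
every node seeds one individual. All randomness flows from the single
`seed` in `search_config()`, so a run is bit-reproducible.

**Reporting.** The front is returned deduplicated and sorted by decreasing
$S_A$; the maximum-$S_A$ and maximum-$R_A$ members are the extremes. The
knee — the best-balanced trade-off — is identified as the member at maximum
perpendicular distance from the straight line joining the two extremes
after min–max normalisation of both objectives; the notion of a knee needs
*some* formula, and this one is scale-free and degenerates gracefully
(fronts of one or two members: the max-$S_A$ member is the knee).

## The synthetic benchmark

`generate_benchmark()` emulates exactly the statistical structure the
scoring model assumes: background p-values Uniform(0,1); a planted connected
module (grown by breadth-first expansion from a random start) whose
p-values are Beta($a$,1), sampled by the inverse transform $u^{1/a}$ so any
implementation reproduces the same stream from the same uniform generator;
and a pathway collection in which a few on-target sets draw most of their
members from the planted module while the rest are uniform decoys. The
default benchmark is a 300-node preferential-attachment graph ($m = 2$,
scale-free-ish like interactome degree distributions), a 25-node planted
module with $a = 0.1$, and 20 pathways of 10–30 genes, 5 of them on-target
at overlap 0.8 — sizes at which a full search runs in seconds and the
planted module is neither trivial nor hopeless to recover.

What the generator deliberately does **not** model: BioGRID's exact degree
distribution and multi-edge structure, correlation between p-values of
interacting genes, probe-level microarray noise, and annotation bias in
real pathway databases. Passing the recovery tests therefore demonstrates
that the scoring-plus-search machinery works when the model's assumptions
hold; it does not certify performance on any particular real dataset, where
those assumptions are approximations.

At the benchmark's signal strength only about half the planted genes fall
below $\tau$ — Beta(0.1, 1) has a heavy upper tail — so the
maximum-activity module typically recovers 60–80% of the planted genes with
near-perfect precision, and coverage-oriented front members recover more:
the prior-knowledge objective pulls in planted genes whose individual
p-values are unremarkable. That is the intended behaviour of the method,
visible already at desk scale.

## Problem sizes used by the test suite

Unit tests run on toy graphs (3–30 nodes) against enumeration and traversal
oracles; estimator checks use $10^4$ simulated p-values against a
$100\times100$ likelihood-grid oracle; recovery checks run the full default
benchmark (300 nodes, population 50, 200 generations) over three seeds —
about ten seconds per run. These sizes were chosen so the entire suite
exercises every stage at full fidelity while remaining quick enough to run
on every change.

## Known limitations

* The dense adjacency matrix kept by the search puts a practical ceiling of
  a few thousand nodes on the network — ample for filtered
  differential-expression networks, not for a raw interactome.
* Single-point crossover over a lexicographic node ordering makes the
  search's trajectories (though not the problem) ordering-dependent;
  different orderings can reach different, equally valid fronts.
* The BUM model assumes independent p-values; correlated tests inflate the
  apparent signal component, and $\tau$ inherits that bias.
* Pathway coverage treats gene sets as flat; overlap structure between
  pathways is not modelled.
* Mutation never considers non-neighbouring pathway members, so a module
  cannot jump across network components; this is deliberate (it preserves
  connectedness by construction) but means disconnected signal areas are
  reachable only through crossover plus the constraint filter.
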