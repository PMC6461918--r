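---
title: "Multi-objective optimized breeding: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective optimized breeding: models, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moob)
```

## The problem

Recurrent selection on several traits at once forces a breeder to trade three
things against each other: the expected genetic gain in each trait, and the
loss of genetic diversity (accumulation of co-ancestry) that aggressive
selection causes. Classical answers — tandem selection, independent culling,
and index selection — collapse the problem to a single criterion and ignore
diversity entirely. `moob` instead treats the choice of parents as a
multi-objective optimization problem and hands the breeder the whole Pareto
frontier of efficient compromises, together with tools for picking one point
on it.

## The core model

Let the candidate set hold $m$ individuals with additive genomic relationship
matrix $A$ (computed from markers; no pedigree is used) and per-trait breeding
value vectors $g_1, \dots, g_k$ (GEBVs in practice, centered and scaled so
traits are comparable). A *parental contribution vector* $c$ assigns each
candidate a non-negative proportion of the gametes forming the next
generation, $\sum_i c_i = 1$. Under random mating given $c$:

* expected gain in trait $\ell$: $c' g_\ell$ (maximized),
* expected group co-ancestry: $r(c) = \tfrac12 c' A c$ (minimized).

The frontier module maximizes the vector
$\left[c'g_1, \dots, c'g_k, -\tfrac12 c'Ac\right]$ over the simplex. A
variant penalizes antagonistic trait pairs by replacing $A$ with
$\big(k - 2\sum_{i<j} \Psi_{ij}\big)A$, where $\Psi$ is the genetic
correlation matrix estimated from the breeding values: the more negative the
correlations, the heavier the diversity term weighs. The scaling factor can
be non-positive when correlations are strongly positive; `moob` raises an
error then and the simulator falls back to the unpenalized objective, rather
than silently optimizing a concave-in-the-wrong-direction term.

### Why weighted-sum scalarization recovers the whole front

All objectives are linear except the co-ancestry term, which is concave in
the maximization orientation, and the feasible set (the simplex) is convex.
The attainable objective set is therefore convex, and every Pareto-optimal
point is the maximizer of some non-negative weighted sum. `trace_frontier()`
sweeps a uniform lattice over the weight simplex (default 21 points per axis,
231 scalarizations for two traits), solves each scalarized problem as a
quadratic program, removes duplicates (sup-norm below $10^{-6}$) and
dominated points, and returns the frontier. Weight vectors with zero weight
on the quadratic term make the problem linear; those are answered by the
arg-max vertex directly instead of a degenerate QP.

### The quadratic programming solver

The scalarized problem — maximize $d'c - \tfrac{w_q}{2} c'Qc$ over the
simplex — is solved by a primal active-set method on the non-negativity
bounds (`solve_qp()`), with the sum-to-one constraint kept in the working set
throughout. $A$ is jittered by $10^{-8} I$ whenever its smallest eigenvalue
falls below $10^{-10}$, guaranteeing strict convexity. KKT stationarity
residuals are checked to $10^{-6}$ and returned with each solution; an
accelerated projected-gradient fallback covers the (never observed in tests)
case of active-set non-convergence. Tests cross-check the solver against a
dense simplex grid at resolution 0.01 and against an independent QP
implementation. Warm starts along the weight sweep keep a full frontier trace
at $m = 100$ in the hundred-millisecond range, which is what makes the
simulator's per-cycle re-optimization affordable.

The classical single-trait formulation — minimize $\tfrac12 c'Ac$ subject to
$c'b = \rho$ — is provided as `constrained_min_coancestry()`; sweeping
$\rho$ reproduces the $k = 1$ frontier and serves as an independent
cross-check of the tracer. At boundary values of $\rho$ the gain constraint
and the sum constraint become linearly dependent; that case is detected and
solved directly on the pinned support.

## Choosing a point on the frontier

* `ideal_point()` is the componentwise best of each objective over the
  frontier (usually infeasible).
* `select_by_global_criterion()` min-max normalizes every axis over the
  frontier and returns the solution minimizing the weighted Euclidean
  distance to the normalized ideal point. The norm exponent is exposed
  (default 2). A degenerate axis (zero range) contributes zero distance by
  definition rather than erroring. Ties break toward lower co-ancestry, then
  input order.
* `find_knee()` uses the chord rule on two chosen axes: the knee is the
  point with maximal perpendicular distance to the segment joining the
  frontier endpoints after min-max normalization. Collinear frontiers are
  flagged (`no_knee`) instead of inventing a knee.
* `som_fit()` trains a batch Kohonen self-organizing map (Gaussian
  neighborhood, radius decaying linearly from $\max(u,v)/2$ to $0.5$,
  codebook initialized on the first two principal axes of the normalized
  objectives, hence deterministic) as a topology-preserving 2-D summary of
  high-dimensional frontiers.

The weight triplet used by the simulation protocol — 0.95 on co-ancestry and
0.025 on each trait gain for populations up to 200 (0.9/0.05/0.05 for larger
ones) — is stored in `strategy_config()` in *objective order* (gains first,
co-ancestry last), i.e. `c(0.025, 0.025, 0.95)`.

## Non-dominated selection

`nondominated_sort()` peels a population of multi-trait breeding values into
dominance frontiers (level 1 = non-dominated). Ties on all objectives share a
level. `dominance_weights()` converts the sort into contributions: the
selected quota is filled frontier by frontier, and an included individual on
level $\ell$ receives raw weight $L^\ast - \ell + 1$ (deepest included level
$L^\ast$), a level only partially covered spreading its remaining allocation
equally over its members. The linear-in-rank scheme is this package's
concrete choice — the originating idea prescribes only "higher weights to
lower dominance order" — and a reciprocal ($1/\ell$) alternative sits behind
the `scheme` argument.

## Genomic mating

Where contribution vectors stop at *how much* each parent contributes,
`search_mating_frontier()` chooses *which pairs to cross*. A plan of
$n$ crosses is scored on $2k + 1$ objectives: per-trait mid-parent gain and
per-trait expected within-cross variance (both maximized — variance is
opportunity for transgressive segregation), and expected progeny inbreeding
$A_{ij}/2$ (minimized). Aggregation over crosses is the multiplicity-weighted
*mean*, so plan size does not inflate objectives (the alternative, sums, is a
documented non-default reading).

The closed-form cross variance assumes fully inbred parents and unlinked
loci: progeny lines fixed at random for either parental allele contribute
$\sum_l \beta_l^2$ over the segregating loci (its meaning is pinned down in
tests by exhaustively enumerating all $2^s$ fixed progeny genotypes).
`simulated_cross_variance()` instead simulates doubled-haploid progeny
through the meiosis model and therefore honors linkage; it converges to the
closed form for unlinked maps and drops below it for loci linked in
repulsion. Phase is recovered from dosages only for inbred parents; for
heterozygous candidates the search accepts phased haplotypes explicitly (the
simulator passes its own).

The search is an elitist non-dominated-sorting genetic algorithm over
fixed-size plans (tournament on dominance level with crowding-distance
tie-break, cross-list recombination, endpoint-replacement mutation, defaults:
100 plans, 200 generations, mutation rate 0.1 per cross, selfing allowed).
The returned archive is the non-dominated, objective-distinct set of all
plans evaluated; on instances small enough to enumerate it attains the exact
non-dominated set in the tests.

## The simulator

`make_founders()` builds the study conditions: two complementary fully
inbred founders, a population of $N$ F1 genotypes carried through 100
generations of random mating, 1000 SNPs on each of 3 chromosomes (1 Morgan
each, uniform positions — the genetic length is this package's choice, the
source design being silent), and two traits from 200 QTL per chromosome.

Two structural choices deserve explanation:

* **Antagonistic trait architecture.** Per-trait QTL effects are drawn
  independently from a standard normal; at 100 designated loci per
  chromosome the trait-2 sign is forced opposite to trait-1's. Forcing
  opposite signs on *independent* draws (rather than sign-flipping copies of
  the same effects) gives an expected genetic correlation of
  $-\tfrac{1}{\pi} \approx -0.32$ rather than zero, reproducing the stated
  negative founder correlation; the tests check the sign across seeds.
* **Heritability by construction.** Environmental noise is drawn with
  variance equal to the current genotypic variance (h² = 0.5) and
  *recalibrated every cycle*, holding heritability constant through the
  program as the genetic variance erodes.

Meiosis uses Poisson crossover counts (mean = map length in Morgans),
uniform crossover positions and no interference — the Haldane model, verified
against the closed-form recombination fraction at 10 cM. The base population
for all strategy comparisons applies 10 rounds of phenotypic tandem selection
at 50% intensity to the founders and is frozen per replicate, so every
strategy starts from the identical population.

Genomic strategies are driven by per-trait GBLUP with shrinkage
$(1 - h^2)/h^2$, trained on the current population's phenotypes at
odd-numbered cycles; even-numbered cycles are predicted from the stored model
through the cross-relationship matrix, and genetic-correlation estimates are
carried forward the same way. This is a deliberate simplification of a full
multi-trait REML mixed model: the genetic correlation enters only the
penalized co-ancestry objective and reporting, where a moment estimate from
the GEBVs suffices.

Offspring are produced by sampling both parents of each of $N$ offspring
independently in proportion to the contribution vector (random mating given
contributions); mating-plan strategies instead allocate the $N$ offspring
evenly across the plan's crosses. Tandem alternates traits by cycle parity
and independent culling defaults to the 40th-percentile threshold per trait
(relaxed jointly until at least two survivors remain) — both schedule details
the source design leaves open.

Inside the simulator the frontier is traced at lattice resolution 11 (66
scalarizations) rather than the standalone default 21: the selection step
keeps a single global-criterion pick, and doubling the lattice density moves
that pick by less than the cycle-to-cycle Monte-Carlo noise while tripling
the per-cycle cost.

## What the experiments compute

`run_experiment()` runs every strategy from the same base population per
replicate and reports final-cycle *standardized* gains: per trait,
$(\bar g_{\text{final}} - \bar g_{\text{base}})/\sigma_{g,\text{base}}$, and
their sum as the combined gain. `strategy_margin()` expresses the focal
strategy's mean combined gain as a percentage over the best competitor.
The sum of standardized per-trait gains is this package's reading of
"combined gain" for the headline comparison; per-trait means are reported
alongside so the margin can be attributed. The scale used by
`scripts/acceptance.R` — $N = 100$, 10 replicates, 16 genomic cycles — is
the problem size the package adopts for a desk-scale replication of the
30-replicate design.

## What the synthetic data does and does not capture

The generator reproduces the statistical skeleton of the study: biallelic
SNP genomes with realistic LD decay from a two-founder bottleneck plus 100
generations of random mating, antagonistic pleiotropy between two traits,
constant heritability, and drift at finite population size. It does not
model multi-environment trials, genotype-by-environment interaction,
non-additive gene action, genotyping error, or selection on phenotyping
cost — so passing tests demonstrate correctness of the machinery and the
qualitative strategy ranking under these idealized conditions, not
performance guarantees on any particular crop dataset.

## Numerical conventions

* Contributions: entries below $-10^{-9}$ are errors; tiny negatives above
  that are clipped; sums must be within $10^{-8}$ of one.
* Frontier deduplication: sup-norm $10^{-6}$ in objective space.
* Dominance is strict-in-one/no-worse-in-all; exact duplicates share a
  frontier level.
* All file indices are 1-based; genetic positions are Morgans in files.
* Every stochastic entry point takes an explicit seed; identical inputs and
  seeds reproduce outputs bit-for-bit (the run manifest records the seed,
  inputs, and outputs of each CLI call).

## Known limitations

* The QP active-set solver assumes a positive-definite (after jitter)
  relationship matrix; rank-deficient user-supplied matrices are repaired by
  jitter, which perturbs co-ancestry values by up to $10^{-8}$.
* The mating-plan search is heuristic; optimality is only guaranteed (and
  tested) on exhaustively enumerable instances.
* GBLUP assumes the additive infinitesimal model; with few QTL of large
  effect, variable-selection predictors would be more accurate, and the
  simulated ranking of genomic strategies could shift.
* Self-organizing maps are a visualization aid; cluster boundaries on the
  map carry no inferential weight.
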