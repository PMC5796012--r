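---
title: "Joint parsimony/likelihood tree search with redistribution and consensus branches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint parsimony/likelihood tree search with redistribution and consensus branches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moearc)
```

## The problem

Maximum parsimony (MP) and maximum likelihood (ML) are the two classical
optimality criteria for phylogenetic inference from aligned DNA sequences,
and they regularly disagree: the tree minimizing the number of implied
substitutions is usually not the tree maximizing the probability of the
data under a Markov substitution model. `moearc` treats inference as a
two-objective minimization over unrooted binary tree topologies (with
branch lengths carried along but not optimized),

\[
  f(T) = \bigl(\; \mathrm{MP}(T),\; -\ln L(T) \;\bigr),
\]

and searches for a Pareto front of mutually non-dominated trees with a
decomposition-based evolutionary algorithm, **MOEA-RC**. Its two
distinguishing operators are a *redistribution* survivor selection over
weight-vector sub-populations and *consensus branches* computed from
sub-population elites that are protected from disruption by the genetic
operators. Disabling the consensus machinery gives the ablation **MOEA-R**,
which the package exposes through a single configuration switch
(`consensus = FALSE`) so the contribution of branch protection can be
measured directly.

## Objectives

**Parsimony.** The Fitch algorithm on column-compressed site patterns,
implemented in C++ over 4-bit state sets. Gaps, `N` and `?` are full
ambiguity `{A,C,G,T}`; IUPAC codes map to their standard state sets, for
both objectives. A site therefore never forces a change through missing
data. The score is invariant to the arbitrary internal rooting because the
pairwise set operations at the basal trichotomy coincide with rooting on
one of its edges.

**Likelihood.** Felsenstein pruning under GTR+GAMMA, also in C++, with
per-node rescaling of partial likelihoods to avoid underflow. The rate
matrix is built from stationary frequencies $\pi$ and six symmetric
exchangeabilities, normalized to one expected substitution per unit branch
length, and exponentiated through the eigendecomposition of its
symmetrized form. Among-site rate variation uses $k$ equal-probability
discrete gamma categories with mean-of-bin rates (so the rates average
exactly 1); the default is $k = 4$ and shape $\alpha = 1$. The category
count and the mean-rate convention are stated explicitly in the
configuration because different programs discretize differently, and the
choice changes likelihood values.

Two numerical guards matter in practice:

* **Branch-length floor** (`bl_floor`, default $10^{-6}$): the genetic
  operators can create extremely short edges; without a floor a
  zero-length edge between differing states gives a site likelihood of 0
  and $-\infty$ log-likelihood. The floor only affects the likelihood
  computation, never the stored lengths. Tests that verify closed-form
  limits disable it.
* **No branch-length optimization** inside the objective. The search is
  over topologies; lengths are inherited and recombined by the operators
  (initial lengths are exponential with mean 0.1 substitutions/site, a
  typical scale for moderately divergent data). An inner optimization loop
  would change the method under study and multiply the cost of every
  evaluation.

## Normalization and reference points

Raw MP (an integer in the hundreds or thousands) and $-\ln L$ (often tens
of thousands) live on incomparable scales, so all scalarizations use
normalized objectives
$\bar f_i = (f_i - z_i) / (z^{\mathrm{nad}}_i - z_i)$, where $z$ and
$z^{\mathrm{nad}}$ are the best and worst value of each objective observed
so far. The package tracks them as *running extremes over the whole run*
rather than per-generation ranges: per-generation ranges shrink as the
population converges, which makes the normalization (and hence the
selection pressure) oscillate; running extremes only tighten
monotonically. A degenerate objective whose observed range is a single
point normalizes to 0.

## Redistribution

Given $n$ evenly spaced weight vectors $w_i = (\tfrac{i-1}{n-1},
1-\tfrac{i-1}{n-1})$, each solution in the merged parent+offspring
population $C$ (size $2m$) is assigned to the weight minimizing its
*relative degree*

\[
  \mathcal{R}(x, w_i) = \Bigl|\; \frac{\bar f_1}{\bar f_1 + \bar f_2} - w_{i1} \;\Bigr|,
\]

with the ratio of the all-zero vector defined as $1/2$ (a solution at the
reference point is equally good in both directions) and ties going to the
lowest index. Within each sub-population, members are ranked by the
weighted sum $G(x \mid w_i) = w_{i1}\bar f_1 + w_{i2}\bar f_2$ — on
*normalized* objectives, otherwise the weights would be meaningless against
the raw scales. Survivor selection then repeatedly deletes the globally
worst member (largest $G$; exact ties resolved against the highest
population index, for determinism) among sub-populations whose current
size exceeds the capacity $m/n$, re-checking sizes after every removal,
until exactly $m$ survive. Under-full sub-populations never lose members:
keeping even mediocre solutions in a sparsely populated search direction
preserves coverage of the front. This trims to $m$ *overall* rather than
forcing every set to exactly $m/n$; the capacity is only a ceiling for
deletion eligibility, which is why $m$ must be divisible by $n$.

## Consensus branches

For each sub-population $i$, the best `elites_per_set` members (default 5,
ranked by $G$ under their own set's weight) of $i$ and of its two nearest
neighbor sets (boundary sets take their two nearest indices, so three sets
always contribute) form a profile of $k \le 3\,m/n$ trees. From this
profile the package computes a set of *consensus branches* — bipartitions,
never materialized as a consensus tree — that the operators treat as
protected within that search direction. Neighbors are included because a
single sub-population holds too few elites for a meaningful consensus,
while neighboring weight vectors search nearly the same direction.

The default rule is majority-rule(+): the strict-majority core (splits in
more than $k/2$ trees) extended by *net support* — a split enters iff the
number of profile trees containing it exceeds the number of trees holding
a conflicting split, trees doing neither abstaining. Two conflicting
splits cannot both have support exceeding rejection (every tree containing
one rejects the other), so the returned set is automatically pairwise
compatible, hence realizable on a single tree, and it always contains the
core. On profiles of *fully resolved* trees every absent split is
contradicted, so the extension coincides with the majority core; it only
adds splits when the profile contains unresolved trees. A plain
`"majority"` switch is available.

A frequency-ordered greedy augmentation (add every observed split
compatible with what has been accepted, most frequent first) was
considered and rejected: on the near-random elites of the first
generations it accepts splits seen in a *single* tree up to a fully
resolved split set, i.e. it canonizes noise and freezes the search
immediately. The net-support rule protects nothing on random profiles and
grows exactly as the elites genuinely agree, which is the premise of
branch protection in the first place.

Consensus is recomputed every generation, after redistribution and before
breeding. With fewer than three sub-populations consensus is disabled with
a warning.

## Operators and protection

**Parent selection** is binary tournament: Pareto dominance on the raw
objectives decides if it can; otherwise the smaller sum
$\bar f_1 + \bar f_2$ wins; exact ties are resolved by a fair coin.

**Crossover** (probability 0.8 per pair) is Prune-Delete-Graft: a random
edge of the donor defines a subtree of 1 to $n-3$ leaves; those leaves are
deleted from a copy of the recipient (degree-2 nodes suppressed, merged
lengths summed); the subtree is grafted onto a random edge of the reduced
recipient, splitting that edge's length in half, the subtree keeping its
stem length. Each selected pair produces two children, one in each
donor/recipient direction, because a single PDG application yields only
one offspring. The graft is explicit edge-matrix surgery (a new node in
the middle of the target edge) rather than a call into general-purpose
tree-binding utilities, which proved fragile for mid-edge grafts in
stress testing.

**Mutation** (probability 0.2 per child) is one nearest-neighbor
interchange on a random internal edge, each of the two alternative local
topologies with probability 1/2; every subtree keeps its own subtending
branch length.

**Protection.** A child produced by grafting into recipient $p_2$ must
retain every protected bipartition of its recipient's sub-population that
$p_2$ actually contained. Enforcement is rejection sampling: prune/graft
choices are redrawn up to `t_max = 20` times; on exhaustion the child is
an unmodified copy of $p_2$, making the contract absolute. NNI simply
never selects a protected edge (and returns the tree unchanged if every
internal edge is protected); since one NNI changes exactly one
bipartition, this is enforcement by construction. For children created by
copying (the 20% of pairs without crossover), the parent's own
sub-population set is used. When the two parents belong to different
sub-populations the recipient's set protects the child — the child's
material is mostly the recipient's, so its search direction is the natural
owner.

## The main loop

1. Initialize $N$ trees: uniformly random topologies (sequential random
   edge attachment, which is exactly uniform over unrooted binary
   topologies) with exponential(mean 0.1) branch lengths, or user-supplied
   starting trees.
2. Evaluate (MP, $-\ln L$); update $z$, $z^{\mathrm{nad}}$.
3. Redistribute into $n$ sub-populations.
4. Compute consensus branches per sub-population (skipped in MOEA-R).
5. Breed $N$ offspring with protected PDG/NNI.
6. Merge with parents and return to step 2 until the stop condition: a
   generation count (default) or an evaluation budget, where one
   evaluation is one scoring of one tree and unchanged copies inherit
   their parent's objectives instead of being re-scored.

All randomness flows from the single configured seed, so runs are
bit-reproducible. The per-generation trace records running best
objectives, the Pareto front size, the hypervolume of the normalized front
(reference point $(1.1, 1.1)$ — a within-run convergence diagnostic; for
comparing *different* runs compute hypervolumes of the raw fronts against
a common reference point), the reference points, the number of protected
branches, and the evaluation counter.

## The simulator

`simulate_alignment()` draws a root sequence from $\pi$, assigns each site
one gamma-category rate held constant across the tree (matching the
rates-across-sites model the likelihood assumes), and evolves states edge
by edge through the same transition matrices the scorer uses.
`make_benchmark()` wraps it into a reproducible fixture: a uniformly
random tree with exponential(0.1) branch lengths, mildly randomized GTR
parameters (frequencies near 1/4, exchangeabilities in $[0.5, 2]$,
$\alpha = 1$, 4 categories), and a simulated alignment. It emulates
homogeneous, indel-free evolution on a known tree; it does *not* emulate
alignment error, compositional heterogeneity, rate variation across
lineages, or real gap structure. Passing tests on simulated data therefore
demonstrate internal correctness and the value of consensus protection
under the model's own assumptions, not robustness to model violation.

## Scales used by the test suite

The shipped tests run the whole system at desk scale, chosen so the suite
exercises every code path in a few minutes: oracle comparisons on 4-8
taxon trees against brute-force enumeration; a fixed 20-taxon/500-site
benchmark; and an ablation experiment of ten seeded runs each of MOEA-RC
and MOEA-R at population 40, 4 sub-populations, 50 generations. The
package defaults (population 100, 10 sub-populations, 100 generations)
reflect standard practice for the published algorithm class and are what
`run_config()` gives without arguments.

## Known limitations

* Branch protection is double-edged at small scales: once a
  sub-population's elites converge, all $n-3$ branches become protected,
  PDG falls back to copies and that search direction freezes. The
  ablation experiment shows run-to-run variance in whether protection has
  locked in a good or a mediocre topology by then. Larger populations and
  taxon sets (where elites rarely become identical) are the intended
  regime.
* Branch lengths are never optimized, so reported likelihoods are
  conservative relative to ML programs that fit lengths per topology.
* The likelihood model is GTR+GAMMA only (simpler models are parameter
  special cases, not separate code paths); no invariant-sites mixture, no
  partitioned models, no protein data.
* Objective evaluation is single-threaded by design; determinism under a
  seed was preferred over parallel throughput.
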