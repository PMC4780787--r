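---
title: "Species networks from quartet concordance factors: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species networks from quartet concordance factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcfnet)
```

## The model

`qcfnet` estimates an explicit, level-1, semi-directed phylogenetic network
from multi-locus data summarized as quartet concordance factors (CFs). A
*semi-directed* network is an unrooted network in which only the two edges
converging on each hybrid node keep their direction; a *level-1* network is
one in which reticulation cycles do not share edges. The estimand is the
network topology together with branch lengths **t** in coalescent units and,
for each reticulation, the inheritance probability $\gamma$ — the proportion
of the genome the hybrid population received from its minor parent.

The data model couples the multispecies coalescent (incomplete lineage
sorting, ILS) with hybridization: within a population branch of length $t$
carrying $j$ gene lineages, each pair coalesces at rate 1; at a hybrid node,
each lineage independently descends from the minor parental population with
probability $\gamma$. For a 4-taxon set $\{a,b,c,d\}$ there are exactly three
unrooted gene-tree quartets, $q_1 = ab|cd$, $q_2 = ac|bd$, $q_3 = ad|bc$, and
the CF of a quartet is the proportion of the genome whose true gene tree
displays it. On a species *tree* with internal edge $t$ the expected CFs are
the classical $(1 - \tfrac23 e^{-t},\ \tfrac13 e^{-t},\ \tfrac13 e^{-t})$.

Expected CFs on a network do not depend on where the network could be
rooted, which is why only the semi-directed structure is estimable. The
pseudolikelihood of a network given gene counts $\mathbf X_s$ over 4-taxon
sets $s$ is the product of multinomial likelihoods
$\prod_s \prod_i \mathrm{CF}_{q_i(s)}^{X_{q_i(s)}}$; its log is computed by
`log_pseudolik()` with expected CFs clamped below at $10^{-12}$.

## Exact quartet CFs: closed forms and the enumeration engine

`expected_cf()` extracts the 4-taxon subnetwork induced by a quartet
(suppressing other leaves, fusing paths and dropping reticulations that
become invisible) and evaluates its expected CFs. Three closed forms cover
the common cases:

* a **species tree** (internal length = sum of the path);
* a **single-descendant hybrid** (`expected_cf_hybrid_single`): the hybrid
  taxon's lineage descends from the major parent with probability
  $1-\gamma$ (quartet internal length $t_1$) or the minor parent
  (length $t_1 + t_2$); the CFs are the $\gamma$-mixture of two species
  trees;
* a **cherry-descendant hybrid** (`expected_cf_hybrid_double`): two taxa
  below the hybrid may coalesce before it ($1 - e^{-t_1}$); otherwise each
  chooses a parental path independently, giving the weighted average of four
  species trees with weights $(1-\gamma)^2$, $2\gamma(1-\gamma)$,
  $\gamma^2$.

All closed forms are validated, in the test suite, against an independent
**coalescent-history enumeration engine** (`enumerate_histories_cf`) that
works on any rooted level-1 network with four sampled lineages. The engine
rests on one observation: a quartet's topology is decided by the *first*
coalescence among the four sampled lineages (any two merges on disjoint
branches are automatically compatible). It therefore propagates, from the
leaves to the root, the probability that no pair has yet coalesced together
with the probabilities that each split has been decided; within an edge with
$j$ lineages the first event happens with probability $1 - e^{-\binom j2 t}$
and picks a uniform pair, and at a hybrid node the undecided lineages are
routed over all $2^j$ minor/major assignments with the appropriate
$\gamma$-weights. The engine is also cross-checked against Monte-Carlo
simulation with $10^5$ loci per parameter point.

Two exact local reductions remove undetectable reticulations
(`reduce_undetectable_cycle`): a 2-cycle crossed by at most two lineages is
replaced by a single edge with
$e^{-t'} = (1-\gamma)^2 e^{-t_{maj}} + \gamma^2 e^{-t_{min}} +
2\gamma(1-\gamma)$, and a triangle traversed by a single lineage re-attaches
its pendant at distance $-\log(w + (1-w)e^{-t_c})$ from the parent whose
side holds the quartet's remaining pair ($w$ = that parent's inheritance).
Both transformations are verified against the engine on parameter grids.

For speed, `log_pseudolik()` compiles each 4-taxon set into an evaluation
*plan* once per topology (tree / mixture / merged-2-cycle / triangle closed
forms, with the engine as the general fallback) and re-evaluates only
arithmetic when the optimizer changes parameters.

### The five canonical quartet networks

Exhaustive attachment of one hybridization to the unrooted quartet tree
yields, up to tip relabeling, five semi-directed level-1 networks: 2-cycles
("bubbles") on an internal or external edge, two triangle placements, and
the 4-cycle. Construction actually produces six distinct directed graphs:
a bubble has two orientations, differing only in which of its two
subdivision points is called the hybrid. Both orientations describe the same
undetectable bubble on the same tree edge (their CFs coincide with a species
tree's for every parameter value), and `canonical_quartet_networks()`
identifies them, returning five networks. Only the 4-cycle is detectable
from 4 taxa; with 5 or more taxa the placement and direction of a 4-cycle
hybridization also become identifiable, which the test suite reproduces
computationally on a pair of 5-taxon diamonds differing only in the hybrid's
position.

## Identifiability and the searchable space

Detectability and parameter identifiability depend on the cycle size $k$ and
the taxon counts of the subtrees hanging off the cycle. The search space
excludes 2-cycles entirely and triangles unless all three subtrees have at
least two taxa (*good triangle*). Within the admitted classes
(`apply_identifiability_constraints`):

* **good triangle**: the cycle tree edge joining the two parents is pinned
  to 0;
* **bad diamond I** ($k=4$; hybrid and both parents subtend single taxa,
  the opposite node two or more): $\gamma$ and the two cycle tree edges
  collapse onto the two identifiable products
  $z_1 = \gamma(1 - e^{-t_{minor\,side}})$ and
  $z_2 = (1-\gamma)(1 - e^{-t_{major\,side}})$, which the optimizer treats
  as the free parameters (the CFs are invariant to the choice of
  representative, a property the tests verify);
* **bad diamond II** ($k=4$; two or more taxa below the hybrid, single taxa
  elsewhere): the hybrid's child edge is pinned to 0. This is a
  normalization of a one-dimensional near-ridge: a generating network with a
  positive child edge is approximated, not reproduced exactly, under the
  pinned model.

Two further normalizations are applied throughout. First, hybrid-edge
*lengths* are excluded from estimation whenever the hybrid subtends a single
taxon: at most one lineage ever crosses those edges, so their lengths fuse
into an external edge and are invisible to every quartet (they are set to 0
by convention). Second, a degree-2 root splits one edge into two of which
only the sum is identifiable, so networks are re-normalized to their
unrooted-style representation (`net_unroot`) before parameters are mapped.
External edge lengths are never estimated (one sampled individual per
taxon).

## Estimation

`snaq()` fits the network by multi-run hill climbing (`snaq_search`):

1. branch lengths of the starting tree are initialized from the average
   observed CF of the quartets spanning each internal edge, transformed by
   $t = -\log(1 - \tfrac32\bar{\mathrm{CF}})$ and clamped to
   $[10^{-10}, 10]$. This printed transform is not the exact inversion of
   the species-tree CF formula (that would be
   $-\log(\tfrac32(1-\bar{\mathrm{CF}}))$, available via
   `init_formula = "consistent"`); we default to the printed version and do
   not guess further, since it only supplies starting values;
2. a proposal is drawn uniformly among the currently legal move types —
   move the origin of a hybridization, move its target, reverse its
   direction, NNI on a tree edge, or add a hybridization while $h < h_m$ —
   and checked for searchability (binary, level-1, $h \le h_m$, rootable,
   admissible cycle classes);
3. branch lengths and inheritance probabilities of the candidate are
   re-optimized with BOBYQA (bound-constrained, derivative-free;
   $t \in [0, 10]$, $\gamma \in [0,1]$, minor/major re-designated when
   $\hat\gamma$ crosses 0.5); the move is accepted only if the optimized
   score improves by more than $10^{-6}$;
4. boundary estimates are resolved as part of the search: a reticulation
   optimized to $\hat\gamma \approx 0$ is removed, re-attachment is
   attempted at edges adjacent to its former endpoints (keeping the first
   searchable improvement) and otherwise the hybridization is deleted;
   a branch optimized to $\hat t \approx 0$ triggers an immediate NNI
   proposal on that branch;
5. a run ends after 100 consecutive failed proposals (configurable), and a
   final tightly-converged polish pass (with one more boundary resolution)
   closes the run. The best of `runs` independent runs is returned.

Deletion of a hybridization is never *proposed*: since the pseudolikelihood
cannot decrease when a reticulation is added, the expected outcome is
$h = h_m$ exactly unless the data push $\hat\gamma$ to 0. Each run is seeded
deterministically (`seed + run - 1`); the whole fit is reproducible.

Numerical choices: expected CFs are clamped at $10^{-12}$; quartet counts
are the tabled CFs times `ngenes`, rounded (`weighting = "fractional"` keeps
them fractional); optimizer tolerances are `rhoend = 1e-4` within the search
and `1e-6` for baselines and the final polish, with jittered restarts; new
hybridizations start at $\gamma = 0.1$. Uncovered or missing internal branch
lengths default to 1 before optimization.

## Observed CFs, uncertainty, and model selection

`count_quartets()` tabulates, for every 4-taxon set, the genes whose tree
restricted to the set displays each quartet; genes missing any of the four
taxa, or unresolved on them, are skipped for that set, and an optional
support threshold drops genes whose displaying branch is weakly supported
(the maximum support along the inducing path; branches without support
always pass). Tables read from CSV follow the four-taxon/three-CF column
layout with optional 95% credibility bounds; `resample_cf_table()` redraws
each CF uniformly from its interval and renormalizes — the conservative
parametric bootstrap used by `bootstrap_networks()`. `summarize_bootstrap()`
reports, against a reference network, the support for each major-tree edge
(equivalence = same bipartition) and for each minor hybrid edge (same type
and same hardwired cluster under its head), together with the frequency
table of alternative placements. The number of reticulations is chosen by a
slope heuristic (`slope_heuristic`): the score profile over $h$ is fit by
two least-squares segments at every possible integer breakpoint, the
breakpoint with the smallest total squared error wins, and near-linear
profiles (relative improvement below a threshold) resolve to $h = 0$. The
two-segment formalization is our own concrete reading of "where the score
switches from a sharp to a slow linear decrease"; it is affine-invariant.

## The synthetic-data generator

`simulate_gene_trees()` implements the network multispecies coalescent
exactly as the CF formulas assume (a compiled per-gene simulation:
exponential waiting times truncated at edge lengths, independent
$\gamma$-routing at hybrid nodes, standard coalescent above the root), so it
serves as the Monte-Carlo oracle for every formula as well as the generator
for end-to-end experiments. Population sizes are constant everywhere —
coalescent units absorb them. What it does *not* emulate: sequence-level
noise and gene-tree estimation error (optionally approximated by per-gene
quartet misclassification, `error_rate`), linkage between loci, missing
taxa, or rate variation. Passing tests therefore demonstrate correctness of
the model and estimator under the model's own assumptions, not robustness to
real-data violations of them.

`paper_sim_networks()` regenerates the four simulation-design networks with
$(n,h) \in \{(6,1), (6,2), (10,1), (15,3)\}$ and minor inheritance 0.2/0.3:
topologies are drawn by simulating a coalescent tree and attaching
hybridizations between random edge pairs, rejecting non-level-1 proposals,
then screened for the designed features (a 4-cycle on 6 taxa, including a
bad diamond I when $h = 2$; a bad diamond II on 10 taxa). Because raw
coalescent trees frequently carry internal edges of a few hundredths of a
coalescent unit — which would drown every quartet in ILS — internal tree
edges are floored at 0.2 coalescent units: the study emulates informative
loci with moderate discordance. Exact branch lengths of the
original study networks are not public, so comparisons at that level are
qualitative by design.

## Problem sizes used in the tests

The shipped test suite runs the complete pipeline at desk scale, a deliberate
design choice: oracle grids use 50+ parameter points with $10^5$ loci per
Monte-Carlo check; root-invariance sweeps 200 random networks with up to 8
taxa and 2 reticulations; the end-to-end experiment simulates $10^4$ loci
from the 6-taxon single-hybridization design and runs 10 independent search
runs per replicate for 10 replicates, with the consecutive-failure limit set
to 12 (searches on 6 taxa converge within a handful of accepted moves; the
larger default limit mainly adds post-convergence rejections). Search-space
connectivity is exercised on the fully enumerable 5-taxon space rather than
6 taxa.

## Known limitations

* Level-1 only; overlapping cycles are rejected, not modeled.
* One sampled individual per taxon; external edge lengths are not estimated.
* The pseudolikelihood is not a likelihood: information criteria do not
  apply, which is why model selection uses the slope heuristic and bootstrap
  stability instead.
* Hill climbing with local moves carries no global optimality guarantee;
  multiple runs and the boundary rules mitigate, but cannot eliminate,
  local optima.
* The bad-diamond-II normalization ($t_{child} = 0$) slightly restricts the
  CF family (see above); estimated networks of that class should be read
  through their identifiable parameters.
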