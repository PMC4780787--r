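# qcfnet — species networks from quartet concordance factors

`qcfnet` infers **explicit phylogenetic networks** — species trees expanded
by hybridization, introgression or gene-flow edges — from multi-locus data,
for biologists whose study system does not fit a strictly bifurcating tree.
The input is not sequence data but **quartet concordance factors (CFs)**:
for every 4-taxon set, the proportions of the genome whose gene tree
displays each of the three possible quartets, either counted directly from a
gene-tree collection or taken from the summary output of a Bayesian
concordance analysis.

## The model in brief

The estimand is a **level-1 semi-directed network**: unrooted, with only the
two edges converging on each hybrid node directed, reticulation cycles not
sharing edges, branch lengths *t* in coalescent units and an inheritance
probability γ per reticulation. Gene trees follow the multispecies
coalescent on the network: within a branch of length *t* each lineage pair
coalesces at rate 1 (incomplete lineage sorting), and at a hybrid node each
lineage descends from the minor parent with probability γ. On a species tree
with internal edge *t* the expected quartet CFs are

    CF(major) = 1 − (2/3) e^−t ,  CF(each minor) = (1/3) e^−t ,

and on a network they are γ-weighted mixtures of such terms (computed
exactly by closed forms and a coalescent-history enumeration engine). The
network is estimated by **maximum pseudolikelihood**: the product over
4-taxon sets *s* of multinomial likelihoods

    L = ∏_s CF_q1(s)^X_q1 · CF_q2(s)^X_q2 · CF_q3(s)^X_q3 ,

maximized by hill climbing over network space with the branch lengths and γ
re-optimized (derivative-free, bound-constrained) for every candidate
topology. Reticulations whose parameters are provably not identifiable are
either excluded from the search space or reparameterized onto their
identifiable combinations; see the methods vignette
(`vignettes/methods.Rmd`) for the full account.

## A worked example

Simulate 3,000 loci from a 6-taxon network with one hybridization
(γ = 0.3), count quartets, and re-estimate the network:

```r
library(qcfnet)

truth <- parse_enewick(paste0(
  "((((a:0.5)#H1:0.3::0.7,(b:1,c:1):0.6):0.5,",
  "(#H1:0.4::0.3,d:1):0.7):0.4,(e:1,f:1):0.3);"))

tab <- simulate_cf_table(truth, ngenes = 3000, seed = 7)
head(tab, 3)
#>   taxon1 taxon2 taxon3 taxon4   CF12_34   CF13_24   CF14_23 ngenes
#> 1      a      b      c      d 0.1330000 0.1450000 0.7220000   3000
#> 2      a      b      c      e 0.1533333 0.1596667 0.6870000   3000
#> 3      a      b      c      f 0.1520000 0.1636667 0.6843333   3000

fit <- snaq(tab, start_tree_nj(tab), h_max = 1, runs = 3, seed = 1)
fit
#> Maximum-pseudolikelihood species network
#>   taxa: 6   hybridizations: 1 (h_max = 1)
#>   log pseudolikelihood: -36958.553   (3 runs)
#>   ((a:0.123)#H1:0::0.634,(b:0.121,c:0.060):0.598,((e:0.125,f:0.031):0.730,(d:0.479,#H1:0::0.366):0.475):0.522);
```

(Branch lengths abbreviated here; the printed string carries full precision.)

The fitted eNewick says: taxon `a` is a hybrid; it inherited most of its
genome (γ̂ = 0.63) from a parent next to the `(b,c)` clade and the rest
(the `#H1 ... ::0.366` minor edge) from the lineage leading to `d` — the
generating network's reticulation (true minor γ = 0.3), on the correct
topology. `coef(fit)` tabulates all edge lengths and inheritance probabilities,
`fitted(fit)`/`residuals(fit)` compare expected and observed CFs, and
`plot(fit)` draws the major tree with the minor hybrid edge as an arrow.

Uncertainty and model choice:

```r
scores <- sapply(0:2, function(h)
  -snaq(tab, start_tree_nj(tab), h_max = h, runs = 2, seed = 1)$loglik)
scores
#> [1] 37195.70 36958.55 36958.55
slope_heuristic(scores)   # kink in the score profile -> chosen h
#> [1] 1
```

`bootstrap_networks()` + `summarize_bootstrap()` give edge and
hybrid-placement supports from CF credibility intervals.

## File formats

* **Extended Newick** (`parse_enewick` / `write_enewick`): hybrid nodes are
  tagged `#H<k>` and appear exactly twice — once carrying the subtree (under
  the major parent), once as a bare stub (under the minor parent); the
  inheritance probability is the *third* colon field of a hybrid edge,
  `(...)#H1:length:support:gamma`, and a value given on one edge implies
  1 − γ on its partner. The edge with γ ≥ 0.5 is the major edge.
* **CF tables** (`read_cf_table` / `write_cf_table`): CSV with columns
  `taxon1..taxon4, CF12_34, CF13_24, CF14_23`, optional `ngenes` and
  per-CF 95% credibility bounds `*_lo`, `*_hi`.
* Gene trees are plain Newick, one per line (read with `ape::read.tree`).

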