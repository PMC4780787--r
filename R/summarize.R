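## ---------------------------------------------------------------------------
## Bootstrap summaries, slope-heuristic selection of h, and evaluation
## distances.
## ---------------------------------------------------------------------------

#' Bootstrap networks from CF credibility intervals
#'
#' Resamples the CF table `B` times from its 95% credibility intervals
#' ([resample_cf_table()]) and re-runs the network search on each replicate.
#'
#' @param table a `cf_table` with `*_lo` / `*_hi` bounds
#' @param start_tree starting topology passed to [snaq_search()]
#' @param h_max,runs,seed,... search settings (see [snaq_search()])
#' @param B number of bootstrap replicates
#' @return list of `phynet` networks of length `B`; each element records its
#'   replicate seed in attribute `"seed"`
#' @export
bootstrap_networks <- function(table, start_tree, B = 100L, h_max = 0L,
                               runs = 3L, seed = 42L, ...) {
  if (B < 1L) stop("B must be >= 1")
  out <- vector("list", B)
  for (b in seq_len(B)) {
    bseed <- seed + 1000L * b
    rt <- resample_cf_table(table, seed = bseed)
    res <- snaq_search(rt, start_tree, h_max = h_max, runs = runs,
                       seed = bseed, ...)
    out[[b]] <- structure(res$net, seed = bseed)
  }
  out
}

## hardwired clusters of the minor hybrid edges and of the major-tree edges
minor_edge_clusters <- function(net) {
  lapply(which(net$hybrid & !net$major), function(e)
    sort(net$labels[subtree_below(net, net$edge[e, 2L])]))
}

major_tree_splits <- function(net) {
  mt <- major_tree(net)
  cl <- edge_clusters(mt)
  keep <- vapply(cl, function(x)
    length(x) >= 2L && length(x) <= mt$ntax - 2L, TRUE)
  unique(lapply(cl[keep], function(x) {
    comp <- sort(setdiff(mt$labels, x))
    if (paste(x, collapse = ",") < paste(comp, collapse = ",")) x else comp
  }))
}

#' Summarize bootstrap networks against a reference
#'
#' For each internal edge of the reference's major tree, the percentage of
#' bootstrap networks whose major tree contains an equivalent edge (same
#' bipartition); for each minor hybrid edge of the reference, the percentage
#' of bootstrap networks containing an equivalent minor hybrid edge (same
#' type and same hardwired cluster below its head), plus the table of
#' alternative placements with their frequencies.
#'
#' @param nets list of bootstrap `phynet` networks
#' @param reference the reference `phynet`
#' @return list with `edge_support` (data frame: split, support %) and
#'   `hybrid_support` (data frame: cluster, support %), and
#'   `hybrid_alternatives` (placement frequency table across replicates)
#' @export
summarize_bootstrap <- function(nets, reference) {
  for (nt in nets) if (!setequal(nt$labels, reference$labels))
    stop("bootstrap networks and reference disagree on taxa")
  B <- length(nets)
  ref_splits <- major_tree_splits(reference)
  boot_splits <- lapply(nets, major_tree_splits)
  edge_support <- data.frame(
    split = vapply(ref_splits, paste, "", collapse = ","),
    support = vapply(ref_splits, function(s)
      100 * mean(vapply(boot_splits, function(bs)
        any(vapply(bs, identical, TRUE, y = s)), TRUE)), 1))
  ref_min <- minor_edge_clusters(reference)
  boot_min <- lapply(nets, minor_edge_clusters)
  hybrid_support <- data.frame(
    cluster = vapply(ref_min, paste, "", collapse = ","),
    support = vapply(ref_min, function(s)
      100 * mean(vapply(boot_min, function(bm)
        any(vapply(bm, identical, TRUE, y = s)), TRUE)), 1))
  alt <- sort(table(unlist(lapply(boot_min, function(bm)
    vapply(bm, paste, "", collapse = ",")))), decreasing = TRUE)
  alternatives <- data.frame(cluster = names(alt),
                             frequency = 100 * as.integer(alt) / B)
  list(edge_support = edge_support, hybrid_support = hybrid_support,
       hybrid_alternatives = alternatives)
}

#' Choose the number of hybridizations by the slope heuristic
#'
#' Finds where the profile of network scores (negative log pseudolikelihood
#' against h = 0, 1, ...) switches from a sharp to a slow, roughly linear
#' decrease: the integer breakpoint minimizing the total sum of squares of a
#' two-segment piecewise-linear least-squares fit. Ties, and profiles whose
#' best two-segment fit improves on a single line by less than `kink_tol`
#' (relatively), resolve to the smallest h.
#'
#' @param scores numeric vector of scores at h = 0, 1, ..., length >= 3
#' @param kink_tol relative improvement threshold to declare a kink
#' @return the chosen h (integer)
#' @export
slope_heuristic <- function(scores, kink_tol = 1e-8) {
  n <- length(scores)
  if (n < 3L) stop("need at least 3 scores")
  if (any(diff(scores) > 0))
    warning("scores are not non-increasing in h")
  h <- seq_len(n) - 1L
  sse <- function(idx) {
    if (length(idx) < 2L) return(0)
    f <- stats::lm.fit(cbind(1, h[idx]), scores[idx])
    sum(f$residuals^2)
  }
  total <- vapply(2:(n - 1L), function(b)
    sse(1:b) + sse(b:n), 1)
  single <- sse(1:n)
  scale <- sum((scores - mean(scores))^2)
  if (scale == 0 || (single - min(total)) / max(scale, 1e-300) < kink_tol)
    return(0L)
  ## breakpoint index b (1-based position in h): chosen h = h[b]
  b <- which(total <= min(total) + 1e-12 * max(1, abs(min(total))))[1L] + 1L
  h[b]
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the nontrivial bipartitions of two
#' unrooted trees on the same taxa (phangorn's implementation).
#'
#' @param tree1,tree2 `phylo` or tree-like `phynet` objects
#' @return integer distance
#' @export
robinson_foulds <- function(tree1, tree2) {
  t1 <- if (inherits(tree1, "phynet")) as_phylo(tree1) else tree1
  t2 <- if (inherits(tree2, "phynet")) as_phylo(tree2) else tree2
  if (!setequal(t1$tip.label, t2$tip.label)) stop("leaf sets differ")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}

#' Hardwired cluster distance between rooted networks
#'
#' Symmetric difference of the multisets of hardwired clusters (for each
#' edge, the set of leaves reachable below it along directed paths) of two
#' rooted networks on the same taxa.
#'
#' @param net1,net2 rooted `phynet` networks (same taxa)
#' @return integer distance
#' @export
hardwired_cluster_distance <- function(net1, net2) {
  if (!setequal(net1$labels, net2$labels)) stop("taxon sets differ")
  keys <- function(net) sort(vapply(edge_clusters(net), paste, "",
                                    collapse = ","))
  k1 <- keys(net1); k2 <- keys(net2)
  ## multiset symmetric difference
  all <- unique(c(k1, k2))
  sum(vapply(all, function(k) abs(sum(k1 == k) - sum(k2 == k)), 1))
}

#' Does an estimated hybridization match a true one?
#'
#' Reduces both networks to the single reticulation of interest (suppressing
#' the minor hybrid edges of all others), roots both at the outgroup, and
#' declares a match when the hardwired cluster distance between the two
#' reductions is zero — i.e. the estimated reticulation connects the same
#' donor edge to the same recipient edge of the major tree.
#'
#' @param true_net,est_net `phynet` networks on the same taxa
#' @param which_hybrid index of the reticulation of interest (in the order of
#'   [hybrid_cycles()]) in each network
#' @param outgroup taxon used to root both reductions
#' @return logical
#' @export
hybridization_match <- function(true_net, est_net, which_hybrid = c(1L, 1L),
                                outgroup) {
  which_hybrid <- rep_len(which_hybrid, 2L)
  reduce1 <- function(net, keep_idx) {
    hcs <- hybrid_cycles(net)
    if (keep_idx > length(hcs)) stop("hybrid index out of range")
    drop <- setdiff(seq_along(hcs), keep_idx)
    for (i in drop) {
      minor <- which(net$hybrid & !net$major &
                       net$edge[, 2L] == hcs[[i]]$hybrid)
      pair <- which(net$hybrid & net$edge[, 2L] == hcs[[i]]$hybrid)
      net$hybrid[pair] <- FALSE; net$gamma[pair] <- NA_real_
      net$major[pair] <- TRUE
      net <- suppress_degree2(delete_edges(net, minor))
    }
    root_with_outgroup(net, outgroup)
  }
  r1 <- reduce1(true_net, which_hybrid[1L])
  r2 <- reduce1(est_net, which_hybrid[2L])
  hardwired_cluster_distance(r1, r2) == 0L
}
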