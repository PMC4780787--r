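## ---------------------------------------------------------------------------
## Heuristic search over semi-directed level-1 network space.
##
## Proposals (chosen uniformly among currently legal types):
##   1 "origin" : move the origin (donor attachment) of a hybridization
##   2 "target" : move its target (the hybrid node)
##   3 "flip"   : reverse the direction of the hybridization
##   4 "nni"    : nearest-neighbor interchange on an internal tree edge
##   5 "add"    : add a hybridization (only while h < h_max)
## Hybridization deletion is never proposed; it happens through the gamma = 0
## boundary of the optimizer.
## ---------------------------------------------------------------------------

allowed_classes <- c("triangle_good", "diamond_good", "diamond_bad_I",
                     "diamond_bad_II", "k5plus")

#' Is a candidate network inside the searchable space?
#'
#' True when the network is binary level-1 with at most `h_max`
#' hybridizations, admits a valid root placement, and every reticulation
#' cycle class is identifiable enough to search over (2-cycles and triangles
#' with single-taxon subtrees are excluded).
#'
#' @param net a `phynet` (or NULL, which is unsearchable)
#' @param h_max maximum number of hybridizations
#' @return logical with attribute `"reason"` when FALSE
#' @export
is_searchable <- function(net, h_max) {
  fail <- function(msg) structure(FALSE, reason = msg)
  if (is.null(net)) return(fail("no candidate"))
  bad <- check_phynet(net)
  if (length(bad)) return(fail(bad[[1L]]))
  if (n_hybrids(net) > h_max)
    return(fail(sprintf("h = %d exceeds h_max = %d", n_hybrids(net), h_max)))
  v <- validate_level1(net)
  if (length(v)) return(fail(v[[1L]]))
  cls <- vapply(hybrid_cycles(net), function(x) x$class, "")
  off <- setdiff(cls, allowed_classes)
  if (length(off))
    return(fail(paste("cycle class outside search space:", off[[1L]])))
  TRUE
}

## cluster (sorted label string) below an edge's child
edge_cluster_key <- function(net, e) {
  paste(sort(net$labels[subtree_below(net, net$edge[e, 2L])]), collapse = "|")
}

subtree_below <- function(net, v) {
  seen <- logical(net$nnode); seen[v] <- TRUE
  frontier <- v
  while (length(frontier)) {
    nxt <- net$edge[net$edge[, 1L] %in% frontier, 2L]
    nxt <- unique(nxt[!seen[nxt]])
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen[seq_len(net$ntax)])
}

## remove one hybridization: deletes the minor edge, clears the major pair,
## fuses degree-2 nodes. Returns list(net, recipient_key, donor_key, gamma,
## length): cluster keys locate the fused recipient/donor edges afterwards.
remove_hybridization <- function(net, hx) {
  minor <- hx$minor_edge
  U <- net$edge[minor, 1L]
  gam <- net$gamma[minor]
  len <- net$length[minor]
  recipient_key <- edge_cluster_key(net, which(net$edge[, 1L] == hx$hybrid))
  other <- setdiff(which(net$edge[, 1L] == U), minor)
  donor_key <- if (length(other)) edge_cluster_key(net, other[[1L]]) else NA
  pair <- c(hx$minor_edge, hx$major_edge)
  net$hybrid[pair] <- FALSE
  net$gamma[pair] <- NA_real_
  net$major[pair] <- TRUE
  net <- delete_edges(net, minor)
  net <- suppress_degree2(net)
  net <- net_unroot(net)
  list(net = net, recipient_key = recipient_key, donor_key = donor_key,
       gamma = gam, length = len)
}

find_edge_by_cluster <- function(net, key) {
  for (e in which(!net$hybrid)) {
    if (edge_cluster_key(net, e) == key) return(e)
  }
  NA_integer_
}

## one NNI variant on internal tree edge e; swaps a random child subtree of
## the edge's child node with a random other child of its parent node
nni_move <- function(net, e) {
  u <- net$edge[e, 1L]; v <- net$edge[e, 2L]
  if (v <= net$ntax || net$hybrid[e]) return(NULL)
  vkids <- which(net$edge[, 1L] == v)
  ukids <- setdiff(which(net$edge[, 1L] == u), e)
  if (!length(vkids) || !length(ukids)) return(NULL)
  a <- if (length(vkids) == 1L) vkids else sample(vkids, 1L)
  b <- if (length(ukids) == 1L) ukids else sample(ukids, 1L)
  net$edge[a, 1L] <- u
  net$edge[b, 1L] <- v
  out <- reorient_any(net)
  if (is.null(out) || length(check_phynet(out))) return(NULL)
  net_unroot(out)
}

## eligible NNI edges: internal tree edges between two tree-ish nodes
nni_edges <- function(net) {
  hyb <- hybrid_node_ids(net)
  which(!net$hybrid & net$edge[, 2L] > net$ntax &
          !(net$edge[, 2L] %in% hyb))
}

#' Propose one search move
#'
#' Draws a move type uniformly among the currently legal ones and applies a
#' random instantiation. The candidate may still fail [is_searchable()].
#'
#' @param net current `phynet` (normalized, searchable)
#' @param h_max maximum number of hybridizations
#' @param forced_nni_edge optional edge index: propose an NNI on this edge
#'   (used after a zero-length boundary)
#' @return list(net = candidate or NULL, move = tag)
#' @export
propose_move <- function(net, h_max, forced_nni_edge = NULL) {
  if (!is.null(forced_nni_edge)) {
    return(list(net = nni_move(net, forced_nni_edge), move = "nni0"))
  }
  h <- n_hybrids(net)
  types <- c(if (h >= 1L) c("origin", "target", "flip"),
             if (length(nni_edges(net))) "nni",
             if (h < h_max) "add")
  for (try in seq_len(10L)) {
    mv <- if (length(types) == 1L) types else sample(types, 1L)
    cand <- switch(mv,
      nni = {
        es <- nni_edges(net)
        nni_move(net, if (length(es) == 1L) es else sample(es, 1L))
      },
      add = {
        es <- which(!net$hybrid)
        if (length(es) < 2L) NULL else {
          de <- sample(es, 2L)
          add_hybridization(net, de[1L], de[2L], gamma = 0.1, length = 0.1)
        }
      },
      {
        hcs <- hybrid_cycles(net)
        hx <- hcs[[if (length(hcs) == 1L) 1L else sample(length(hcs), 1L)]]
        rm <- remove_hybridization(net, hx)
        rec <- find_edge_by_cluster(rm$net, rm$recipient_key)
        don <- find_edge_by_cluster(rm$net, rm$donor_key)
        tree_edges <- which(!rm$net$hybrid)
        if (mv == "origin") {
          if (is.na(rec)) NULL else {
            cand_d <- setdiff(tree_edges, rec)
            d <- if (length(cand_d) == 1L) cand_d else sample(cand_d, 1L)
            add_hybridization(rm$net, d, rec, gamma = rm$gamma,
                              length = max(rm$length, 0.01, na.rm = TRUE))
          }
        } else if (mv == "target") {
          if (is.na(don)) NULL else {
            cand_r <- setdiff(tree_edges, don)
            r <- if (length(cand_r) == 1L) cand_r else sample(cand_r, 1L)
            add_hybridization(rm$net, don, r, gamma = rm$gamma,
                              length = max(rm$length, 0.01, na.rm = TRUE))
          }
        } else {
          if (is.na(rec) || is.na(don)) NULL else
            add_hybridization(rm$net, rec, don, gamma = 1 - rm$gamma,
                              length = max(rm$length, 0.01, na.rm = TRUE))
        }
      })
    if (!is.null(cand)) return(list(net = cand, move = mv))
  }
  list(net = NULL, move = "none")
}

#' Resolve optimizer boundary estimates
#'
#' Implements the two boundary rules of the search: a hybridization whose
#' inheritance was optimized to 0 (or 1) is removed and re-attachment is
#' attempted at edges neighboring its former attachment points, keeping the
#' first searchable improvement, otherwise the hybridization is deleted; a
#' branch length optimized to 0 schedules an immediate NNI proposal on that
#' branch.
#'
#' @param opt an [optimize_parameters()] result for the current network
#' @param table the `cf_table` being fit
#' @param h_max,weighting,score_tol search settings
#' @return list(opt = possibly changed fit, forced_nni_edge, actions)
#' @export
handle_boundary <- function(opt, table, h_max, weighting = "counts",
                            score_tol = 1e-6, restarts = 3, rhoend = 1e-5) {
  actions <- character(0)
  net <- opt$net
  gone <- unique(c(opt$flags$gamma0, opt$flags$gamma1))
  if (length(gone)) {
    ## handle one reticulation per call (others resolve on later passes)
    e0 <- gone[[1L]]
    ## the edge to delete is the pair member with gamma ~ 0
    hv <- net$edge[e0, 2L]
    pair <- which(net$hybrid & net$edge[, 2L] == hv)
    dele <- pair[which.min(net$gamma[pair])]
    hcs <- hybrid_cycles(net)
    hx <- hcs[[which(vapply(hcs, function(x) x$hybrid, 1L) == hv)]]
    hx$minor_edge <- dele
    hx$major_edge <- setdiff(pair, dele)
    rm <- remove_hybridization(net, hx)
    ## neighborhood: the fused recipient/donor edges and edges sharing a node
    seeds <- c(find_edge_by_cluster(rm$net, rm$recipient_key),
               find_edge_by_cluster(rm$net, rm$donor_key))
    seeds <- seeds[!is.na(seeds)]
    nodes <- unique(as.vector(rm$net$edge[seeds, , drop = FALSE]))
    nbr <- which(apply(matrix(rm$net$edge %in% nodes, ncol = 2L), 1L, any) &
                   !rm$net$hybrid)
    pairs <- expand.grid(d = nbr, r = nbr)
    pairs <- pairs[pairs$d != pairs$r, , drop = FALSE]
    if (nrow(pairs)) pairs <- pairs[sample(nrow(pairs)), , drop = FALSE]
    for (i in seq_len(nrow(pairs))) {
      cand <- add_hybridization(rm$net, pairs$d[i], pairs$r[i],
                                gamma = 0.1, length = 0.1)
      if (!isTRUE(is_searchable(cand, h_max))) next
      o2 <- optimize_parameters(cand, table, weighting = weighting,
                                restarts = restarts, rhoend = rhoend)
      if (o2$score > opt$score + score_tol &&
          !length(c(o2$flags$gamma0, o2$flags$gamma1))) {
        return(list(opt = o2, forced_nni_edge = NULL,
                    actions = c(actions, "reattached")))
      }
    }
    o3 <- optimize_parameters(rm$net, table, weighting = weighting,
                              restarts = restarts, rhoend = rhoend)
    return(list(opt = o3, forced_nni_edge = NULL,
                actions = c(actions, "deleted")))
  }
  forced <- NULL
  if (length(opt$flags$tzero)) {
    e <- opt$flags$tzero[[1L]]
    if (e %in% nni_edges(net)) {
      forced <- e
      actions <- c(actions, "nni_scheduled")
    }
  }
  list(opt = opt, forced_nni_edge = forced, actions = actions)
}

#' Heuristic pseudolikelihood search for a species network
#'
#' Multi-run hill climbing over semi-directed level-1 networks: from a
#' starting tree with CF-initialized branch lengths, moves are proposed at
#' random, every candidate's branch lengths and inheritance probabilities are
#' re-optimized, and a move is accepted only when it improves the log
#' pseudolikelihood by more than `score_tol`. A run stops after
#' `max_failures` consecutive rejected proposals.
#'
#' @param table a `cf_table`
#' @param start_tree starting topology (`phylo` or `phynet`, typically a
#'   tree)
#' @param h_max maximum number of hybridizations
#' @param runs independent runs (best result returned)
#' @param seed integer seed; run r uses seed + r - 1
#' @param max_failures consecutive failed proposals before stopping
#' @param score_tol minimal score improvement counted as progress
#' @param weighting see [log_pseudolik()]
#' @param init_formula branch-length initialization transform, see
#'   [init_branch_lengths()]
#' @return list with `net` (best network), `score`, `h`, `runs` (per-run
#'   summaries), `trace` (data frame: run, step, move, accepted, score)
#' @export
snaq_search <- function(table, start_tree, h_max = 0L, runs = 10L,
                        seed = 42L, max_failures = 100L, score_tol = 1e-6,
                        weighting = "counts", init_formula = "printed",
                        restarts = 0L, rhoend = 1e-4) {
  if (!nrow(table)) stop("the CF table covers no 4-taxon set")
  start <- net_unroot(as_phynet(start_tree))
  tab_taxa <- unique(as.vector(as.matrix(table[, paste0("taxon", 1:4)])))
  if (!all(tab_taxa %in% start$labels))
    stop("start tree and CF table disagree on taxa: ",
         paste(setdiff(tab_taxa, start$labels), collapse = ", "))
  trace <- list()
  best <- NULL
  run_summaries <- list()
  for (r in seq_len(runs)) {
    set.seed(seed + r - 1L)
    net <- init_branch_lengths(start, table, formula = init_formula)
    ## the baseline must be tightly converged: otherwise a proposal can
    ## "improve" on it by optimizer slack alone
    cur <- optimize_parameters(net, table, weighting = weighting,
                               restarts = max(restarts, 2L), rhoend = 1e-6)
    failures <- 0L
    step <- 0L
    forced <- NULL
    while (failures < max_failures) {
      step <- step + 1L
      prop <- propose_move(cur$net, h_max, forced_nni_edge = forced)
      forced <- NULL
      accepted <- FALSE
      if (!is.null(prop$net) && isTRUE(is_searchable(prop$net, h_max))) {
        opt <- optimize_parameters(prop$net, table, weighting = weighting,
                                   restarts = restarts, rhoend = rhoend)
        hb <- handle_boundary(opt, table, h_max, weighting = weighting,
                              score_tol = score_tol, restarts = restarts,
                              rhoend = rhoend)
        opt <- hb$opt
        if (opt$score > cur$score + score_tol) {
          cur <- opt
          accepted <- TRUE
          failures <- 0L
          ## a zero-length branch in the accepted state triggers an
          ## immediate NNI on that branch; edge indices of rejected
          ## candidates do not carry over
          forced <- hb$forced_nni_edge
        } else failures <- failures + 1L
      } else failures <- failures + 1L
      trace[[length(trace) + 1L]] <-
        data.frame(run = r, step = step, move = prop$move,
                   accepted = accepted, score = cur$score)
    }
    ## final polish: tighter convergence on the run's best network, then a
    ## last pass of the boundary rules (a gamma that only the coarse search
    ## tolerance kept away from 0 is resolved here)
    cur <- optimize_parameters(cur$net, table, weighting = weighting,
                               restarts = 2L, rhoend = 1e-6)
    if (length(c(cur$flags$gamma0, cur$flags$gamma1))) {
      hb <- handle_boundary(cur, table, h_max, weighting = weighting,
                            score_tol = score_tol, restarts = 1L,
                            rhoend = 1e-6)
      cur <- hb$opt
    }
    run_summaries[[r]] <- list(score = cur$score, h = n_hybrids(cur$net),
                               seed = seed + r - 1L, steps = step)
    if (is.null(best) || cur$score > best$score) best <- cur
  }
  list(net = best$net, score = best$score, h = n_hybrids(best$net),
       runs = run_summaries, trace = do.call(rbind, trace))
}

#' Naive starting tree from a CF table
#'
#' Neighbor joining on the dissimilarity d(i, j) = mean over sampled 4-taxon
#' sets containing both taxa of (1 - CF of the split grouping i with j): a
#' crude quartet-based starter for [snaq()] when no better tree is at hand.
#'
#' @param table a `cf_table`
#' @return an unrooted `phylo` tree
#' @export
start_tree_nj <- function(table) {
  taxa <- sort(unique(as.vector(as.matrix(table[, paste0("taxon", 1:4)]))))
  n <- length(taxa)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  N <- matrix(0, n, n)
  cf <- as.matrix(table[, cf_cols])
  for (r in seq_len(nrow(table))) {
    tx <- as.character(table[r, paste0("taxon", 1:4)])
    id <- match(tx, taxa)
    for (a in 1:3) for (b in (a + 1):4) {
      q <- pair_topology(a, b)
      d <- 1 - cf[r, q]
      i <- id[a]; j <- id[b]
      D[i, j] <- D[i, j] + d; D[j, i] <- D[i, j]
      N[i, j] <- N[i, j] + 1; N[j, i] <- N[i, j]
    }
  }
  D <- D / pmax(N, 1)
  ape::nj(stats::as.dist(D))
}
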