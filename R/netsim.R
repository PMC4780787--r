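## ---------------------------------------------------------------------------
## Gene-tree simulation under the network multispecies coalescent.
## ---------------------------------------------------------------------------

## resolve lengths for simulation: external NA -> 0 (they only shift leaf
## branch lengths), internal NA -> error
sim_lengths <- function(net) {
  len <- net$length
  ext <- net$edge[, 2L] <= net$ntax
  len[ext & is.na(len)] <- 0
  if (anyNA(len))
    stop("internal branch lengths must be set before simulation")
  if (any(!is.finite(len)) || any(len < 0))
    stop("branch lengths must be finite and >= 0")
  len
}

#' Simulate gene trees under the coalescent with hybridization
#'
#' Traces gene lineages from the leaves toward the root of the network:
#' within an edge of length t (coalescent units) carrying j lineages, each
#' pair coalesces at rate 1; at a hybrid node every remaining lineage
#' independently descends from the minor parent with probability gamma; the
#' lineages surviving at the root coalesce under the standard coalescent.
#'
#' @param net a `phynet` with branch lengths and gamma values
#' @param ngenes number of unlinked loci to simulate
#' @param seed optional integer seed
#' @return a `multiPhylo` list of `ngenes` gene trees with branch lengths in
#'   coalescent units
#' @export
simulate_gene_trees <- function(net, ngenes, seed = NULL) {
  stopifnot(ngenes >= 1)
  if (!is.null(seed)) set.seed(seed)
  len <- sim_lengths(net)
  gam <- ifelse(is.na(net$gamma), 0.5, net$gamma)
  ord <- rev(topo_order(net))
  res <- .sim_gene_trees_cpp(net$edge, len, net$major, gam, net$ntax,
                             net$nnode, ord, net$labels, as.integer(ngenes),
                             TRUE)
  trees <- ape::read.tree(text = paste(res$newick, collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- c(trees)  # ngenes == 1
  trees
}

## fast path: per-gene displayed quartet counts for a 4-taxon network,
## in canonical order of the sorted taxon labels
sim_quartet_counts <- function(net, ngenes, seed = NULL) {
  stopifnot(net$ntax == 4L)
  if (!is.null(seed)) set.seed(seed)
  len <- sim_lengths(net)
  gam <- ifelse(is.na(net$gamma), 0.5, net$gamma)
  ord <- rev(topo_order(net))
  res <- .sim_gene_trees_cpp(net$edge, len, net$major, gam, net$ntax,
                             net$nnode, ord, net$labels, as.integer(ngenes),
                             FALSE)
  rk <- match(net$labels, sort(net$labels))  # leaf id -> canonical rank
  q <- mapply(function(i, j) pair_topology(rk[i], rk[j]), res$pair_i, res$pair_j)
  tx <- sort(net$labels)
  setNames(tabulate(q, 3L),
           c(paste0(tx[1], tx[2], "|", tx[3], tx[4]),
             paste0(tx[1], tx[3], "|", tx[2], tx[4]),
             paste0(tx[1], tx[4], "|", tx[2], tx[3])))
}

#' Simulate a quartet concordance-factor table
#'
#' Composition of [simulate_gene_trees()] and [count_quartets()], with an
#' optional gene-tree estimation error: each gene's displayed quartet is
#' replaced, with probability `error_rate` independently per 4-taxon set, by
#' one of the three quartets drawn uniformly.
#'
#' @param net a `phynet`
#' @param ngenes number of loci
#' @param seed optional integer seed
#' @param sets 4-taxon sets as in [count_quartets()] (default: all)
#' @param error_rate per-gene, per-set probability of a misestimated quartet
#' @return a `cf_table` data frame
#' @export
simulate_cf_table <- function(net, ngenes, seed = NULL, sets = NULL,
                              error_rate = 0) {
  if (ngenes < 1) stop("ngenes must be >= 1")
  trees <- simulate_gene_trees(net, ngenes, seed)
  if (is.null(sets)) sets <- quartet_sets(net$labels)
  tab <- count_quartets(trees, sets)
  if (error_rate > 0) {
    X <- as.matrix(tab[, c("CF12_34", "CF13_24", "CF14_23")]) * tab$ngenes
    for (i in seq_len(nrow(X))) {
      flip <- stats::rbinom(1L, tab$ngenes[i], error_rate)
      if (flip == 0L) next
      keep <- as.vector(stats::rmultinom(1L, tab$ngenes[i] - flip,
                                         pmax(X[i, ], 1e-12)))
      X[i, ] <- keep + as.vector(stats::rmultinom(1L, flip, rep(1 / 3, 3)))
    }
    tab[, c("CF12_34", "CF13_24", "CF14_23")] <- X / rowSums(X)
  }
  tab
}

#' The four simulation-design networks
#'
#' Regenerates level-1 networks with the simulation study's shapes:
#' (n, h) = (6, 1), (6, 2), (10, 1) and (15, 3), with minor-edge inheritance
#' 0.2 or 0.3. The topologies are drawn by the stated recipe (a coalescent
#' tree with hybridizations between random edge pairs, rejecting level > 1)
#' under fixed internal seeds, screened so that the 6-taxon networks carry
#' k = 4 cycles (a bad diamond I for h = 2) and the 10-taxon network a bad
#' diamond II.
#'
#' @return named list of four `phynet` networks
#' @export
paper_sim_networks <- function() {
  cached <- get0("sim_nets", envir = .qcfnet_cache)
  if (!is.null(cached)) return(cached)
  find_net <- function(n, h, gamma, want, seed0) {
    for (s in seq.int(seed0, seed0 + 5000L)) {
      set.seed(s)
      net <- tryCatch(rnetwork(n, h, gamma = gamma), error = function(e) NULL)
      if (is.null(net)) next
      ## moderate incomplete lineage sorting: coalescent trees often carry
      ## vanishingly short internal edges, which would swamp every quartet
      ## with discordance; the study emulates informative loci, so internal
      ## edges are floored at 0.2 coalescent units
      internal <- !net$hybrid & net$edge[, 2L] > net$ntax
      short <- internal & !is.na(net$length) & net$length < 0.2
      net$length[short] <- 0.2
      cls <- vapply(hybrid_cycles(net), function(x) x$class, "")
      if (want(cls)) return(net)
    }
    stop("no matching network found")
  }
  out <- list(
    n6h1 = find_net(6L, 1L, 0.3, function(cls)
      cls == "diamond_good", 101L),
    n6h2 = find_net(6L, 2L, c(0.3, 0.2), function(cls)
      setequal(cls, c("diamond_bad_I", "diamond_good")), 201L),
    n10h1 = find_net(10L, 1L, 0.3, function(cls)
      cls == "diamond_bad_II", 301L),
    n15h3 = find_net(15L, 3L, c(0.2, 0.3, 0.3), function(cls)
      any(cls %in% c("diamond_good", "diamond_bad_I", "diamond_bad_II")) &&
        all(cls %in% c("diamond_good", "diamond_bad_I", "diamond_bad_II",
                       "k5plus", "triangle_good")), 401L)
  )
  assign("sim_nets", out, envir = .qcfnet_cache)
  out
}

.qcfnet_cache <- new.env(parent = emptyenv())
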