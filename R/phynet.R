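#' @useDynLib qcfnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim runif rexp setNames coef logLik simulate fitted residuals
#' @importFrom utils combn head tail
NULL

## ---------------------------------------------------------------------------
## Semi-directed level-1 phylogenetic networks
##
## Internal representation: a rooted DAG stored in ape-like arrays.
##  - nodes are integers; 1..ntax are leaves (labels[i] names leaf i),
##    remaining ids are internal nodes, one of which is the root.
##  - edge: E x 2 matrix (parent, child), all edges directed away from root.
##  - hybrid edges (the two edges into a hybrid node) keep their direction
##    under any re-rooting; tree edges are re-orientable.
##  - gamma: inheritance probability of each hybrid edge (NA on tree edges);
##    major: TRUE for tree edges and for the major member of each hybrid pair.
## The object has semi-directed semantics: two networks are considered equal
## when they agree after forgetting the root (see sd_hash, phynet_equal).
## ---------------------------------------------------------------------------

new_phynet <- function(edge, length, hybrid, gamma, major, labels, root,
                       validate = TRUE) {
  storage.mode(edge) <- "integer"
  dimnames(edge) <- NULL
  names(length) <- names(hybrid) <- names(gamma) <- names(major) <- NULL
  net <- structure(list(
    ntax = length(labels),
    labels = as.character(labels),
    nnode = max(edge),
    edge = edge,
    length = as.numeric(length),
    hybrid = as.logical(hybrid),
    gamma = as.numeric(gamma),
    major = as.logical(major),
    root = as.integer(root)
  ), class = "phynet")
  if (validate) {
    bad <- check_phynet(net)
    if (length(bad)) stop("invalid network: ", paste(bad, collapse = "; "))
  }
  net
}

#' Number of hybrid nodes in a network
#' @param net a `phynet` network
#' @return integer count of reticulations
#' @export
n_hybrids <- function(net) length(hybrid_node_ids(net))

hybrid_node_ids <- function(net) {
  sort(unique(net$edge[net$hybrid, 2L]))
}

#' Taxon labels of a network
#' @param net a `phynet` network
#' @return character vector of leaf labels
#' @export
taxa <- function(net) net$labels

node_indeg <- function(net) tabulate(net$edge[, 2L], net$nnode)
node_outdeg <- function(net) tabulate(net$edge[, 1L], net$nnode)

## edges incident to each node (undirected view), as a list of edge indices
incident_edges <- function(net) {
  E <- nrow(net$edge)
  lst <- vector("list", net$nnode)
  for (e in seq_len(E)) {
    a <- net$edge[e, 1L]; b <- net$edge[e, 2L]
    lst[[a]] <- c(lst[[a]], e)
    lst[[b]] <- c(lst[[b]], e)
  }
  lst
}

## Structural sanity checks shared by constructors; returns character vector
check_phynet <- function(net) {
  out <- character()
  E <- nrow(net$edge)
  if (E != length(net$length) || E != length(net$hybrid) ||
      E != length(net$gamma) || E != length(net$major))
    return("edge attribute lengths disagree")
  indeg <- node_indeg(net); outdeg <- node_outdeg(net)
  if (anyDuplicated(net$labels)) out <- c(out, "duplicate leaf labels")
  leaves <- seq_len(net$ntax)
  if (any(outdeg[leaves] != 0L) || any(indeg[leaves] != 1L))
    out <- c(out, "leaves must have indegree 1, outdegree 0")
  if (indeg[net$root] != 0L) out <- c(out, "root has an incoming edge")
  if (!(outdeg[net$root] %in% c(2L, 3L)))
    out <- c(out, "root must have outdegree 2 or 3")
  hyb <- hybrid_node_ids(net)
  for (v in setdiff(seq_len(net$nnode), c(leaves, net$root))) {
    if (v %in% hyb) {
      if (indeg[v] != 2L || outdeg[v] != 1L)
        out <- c(out, sprintf("hybrid node %d must have indegree 2, outdegree 1", v))
      he <- which(net$hybrid & net$edge[, 2L] == v)
      if (length(he) != 2L) {
        out <- c(out, sprintf("hybrid node %d needs exactly 2 hybrid parent edges", v))
      } else {
        g <- net$gamma[he]
        if (all(!is.na(g)) && abs(sum(g) - 1) > 1e-6)
          out <- c(out, sprintf("gamma values at hybrid node %d do not sum to 1", v))
        if (any(!is.na(g) & (g < 0 | g > 1)))
          out <- c(out, sprintf("gamma outside [0,1] at hybrid node %d", v))
        if (sum(net$major[he]) != 1L)
          out <- c(out, sprintf("hybrid node %d needs exactly one major edge", v))
      }
    } else {
      if (indeg[v] != 1L || outdeg[v] != 2L)
        out <- c(out, sprintf("tree node %d must have indegree 1, outdegree 2", v))
    }
  }
  if (any(net$hybrid & !(net$edge[, 2L] %in% hyb)))
    out <- c(out, "hybrid edge into a non-hybrid node")
  if (any(!is.na(net$length) & net$length < 0)) out <- c(out, "negative edge length")
  ## acyclicity / reachability from root
  if (!length(out)) {
    seen <- logical(net$nnode)
    frontier <- net$root; seen[frontier] <- TRUE
    repeat {
      nxt <- net$edge[net$edge[, 1L] %in% frontier, 2L]
      nxt <- unique(nxt[!seen[nxt]])
      if (!length(nxt)) break
      seen[nxt] <- TRUE; frontier <- nxt
    }
    if (!all(seen)) out <- c(out, "graph not connected from root")
  }
  out
}

## ---------------------------------------------------------------------------
## Orientation / rooting
## ---------------------------------------------------------------------------

## Re-orient all tree edges away from node `p`, keeping hybrid edge directions.
## Returns the oriented phynet or NULL when no consistent orientation exists
## (i.e. p lies below a hybrid node in the semi-directed sense).
orient_network <- function(net, p) {
  E <- nrow(net$edge)
  inc <- incident_edges(net)
  newpar <- integer(E); newpar[net$hybrid] <- net$edge[net$hybrid, 1L]
  seen <- logical(net$nnode)
  seen[p] <- TRUE
  queue <- p
  indeg <- integer(net$nnode)
  indeg[net$edge[net$hybrid, 2L]] <- indeg[net$edge[net$hybrid, 2L]] + 1L
  done <- net$hybrid
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    for (e in inc[[u]]) {
      a <- net$edge[e, 1L]; b <- net$edge[e, 2L]
      v <- if (a == u) b else a
      if (net$hybrid[e]) {
        ## traversable only in its fixed direction
        if (a == u && !seen[b]) { seen[b] <- TRUE; queue <- c(queue, b) }
        next
      }
      if (!done[e]) {
        done[e] <- TRUE
        newpar[e] <- u
        indeg[v] <- indeg[v] + 1L
        if (indeg[v] > (if (v %in% net$edge[net$hybrid, 2L]) 2L else 1L))
          return(NULL)
        if (!seen[v]) { seen[v] <- TRUE; queue <- c(queue, v) }
      }
    }
  }
  if (!all(seen) || !all(done)) return(NULL)
  edge <- net$edge
  for (e in which(!net$hybrid)) {
    a <- edge[e, 1L]; b <- edge[e, 2L]
    if (newpar[e] != a) edge[e, ] <- c(b, a)
  }
  net$edge <- edge
  net$root <- as.integer(p)
  net
}

## All nodes from which a consistent orientation exists
valid_root_nodes <- function(net) {
  cand <- setdiff(seq_len(net$nnode), seq_len(net$ntax))
  keep <- logical(length(cand))
  for (i in seq_along(cand)) keep[i] <- !is.null(orient_network(net, cand[i]))
  cand[keep]
}

## Try to (re)orient after a structural edit: prefer current root, else any.
reorient_any <- function(net) {
  o <- orient_network(net, net$root)
  if (!is.null(o)) return(o)
  for (p in setdiff(seq_len(net$nnode), seq_len(net$ntax))) {
    o <- orient_network(net, p)
    if (!is.null(o)) return(o)
  }
  NULL
}

#' Root a semi-directed network with an outgroup taxon
#'
#' Places the root on the external edge leading to `taxon`, provided that
#' position is compatible with the direction of all hybrid edges (the root can
#' never sit below a hybrid node).
#'
#' @param net a `phynet` network
#' @param taxon outgroup leaf label
#' @return a `phynet` rooted on the outgroup's external edge (root outdegree 2)
#' @export
root_with_outgroup <- function(net, taxon) {
  i <- match(taxon, net$labels)
  if (is.na(i)) stop("taxon '", taxon, "' is not a leaf of the network")
  e <- which(net$edge[, 2L] == i)
  if (net$hybrid[e]) stop("outgroup '", taxon, "' is a hybrid node descendant")
  ## subdivide the external edge with a new root node
  newnode <- net$nnode + 1L
  up <- net$edge[e, 1L]
  net$edge[e, ] <- c(newnode, i)
  half <- net$length[e] / 2
  net$edge <- rbind(net$edge, c(newnode, up))
  net$length[e] <- half
  net$length <- c(net$length, half)
  net$hybrid <- c(net$hybrid, FALSE)
  net$gamma <- c(net$gamma, NA_real_)
  net$major <- c(net$major, TRUE)
  net$nnode <- newnode
  o <- orient_network(net, newnode)
  if (is.null(o)) {
    bad <- which(net$hybrid)
    stop("invalid rooting: '", taxon, "' cannot be an outgroup; the placement ",
         "conflicts with the direction of hybrid edge(s) ",
         paste(bad, collapse = ", "))
  }
  ## the previous root may have become a degree-2 pass-through node
  suppress_degree2(o)
}

## drop the root node if it has become degree-1, promoting its child
suppress_root_if_degree2 <- function(net) {
  repeat {
    if (node_outdeg(net)[net$root] != 1L) return(net)
    e <- which(net$edge[, 1L] == net$root)
    child <- net$edge[e, 2L]
    keep <- setdiff(seq_len(nrow(net$edge)), e)
    net$edge <- net$edge[keep, , drop = FALSE]
    net$length <- net$length[keep]
    net$hybrid <- net$hybrid[keep]
    net$gamma <- net$gamma[keep]
    net$major <- net$major[keep]
    net$root <- child
    net <- compact_nodes(net)
  }
}

## remove edges by index, then drop isolated nodes and renumber
delete_edges <- function(net, idx) {
  keep <- setdiff(seq_len(nrow(net$edge)), idx)
  net$edge <- net$edge[keep, , drop = FALSE]
  net$length <- net$length[keep]
  net$hybrid <- net$hybrid[keep]
  net$gamma <- net$gamma[keep]
  net$major <- net$major[keep]
  compact_nodes(net)
}

## renumber nodes 1..nnode keeping leaves 1..ntax first; drops isolated nodes
compact_nodes <- function(net) {
  used <- sort(unique(c(net$edge, net$root, seq_len(net$ntax))))
  map <- integer(max(used)); map[used] <- seq_along(used)
  stopifnot(all(map[seq_len(net$ntax)] == seq_len(net$ntax)))
  net$edge[] <- map[net$edge]
  net$root <- map[net$root]
  net$nnode <- length(used)
  net
}

## Suppress all degree-2 internal nodes (one in, one out), summing lengths.
## A fused edge is hybrid iff one of the two fused edges was hybrid.
suppress_degree2 <- function(net) {
  repeat {
    indeg <- node_indeg(net); outdeg <- node_outdeg(net)
    v <- which(indeg == 1L & outdeg == 1L)
    v <- setdiff(v, seq_len(net$ntax))
    if (!length(v)) break
    v <- v[[1L]]
    ein <- which(net$edge[, 2L] == v)
    eout <- which(net$edge[, 1L] == v)
    net$edge[ein, 2L] <- net$edge[eout, 2L]
    net$length[ein] <- net$length[ein] + net$length[eout]
    if (net$hybrid[eout]) {
      net$hybrid[ein] <- TRUE
      net$gamma[ein] <- net$gamma[eout]
      net$major[ein] <- net$major[eout]
    }
    net <- delete_edges(net, eout)
  }
  suppress_root_if_degree2(net)
}

## ---------------------------------------------------------------------------
## Level-1 validation via biconnected components
## ---------------------------------------------------------------------------

## Biconnected components of the undirected multigraph; list of edge-index sets.
## Hand-rolled (edge-stack lowpoint DFS) because it sits on the hot path of the
## topology search and must handle parallel edges (2-cycles).
bicomponents <- function(net) {
  n <- net$nnode
  inc <- incident_edges(net)
  comps <- list()
  disc <- integer(n); low <- integer(n)
  timer <- 0L
  estack <- integer(0)
  ## iterative DFS
  for (start in seq_len(n)) {
    if (disc[start] != 0L) next
    stack <- list(list(v = start, parent_edge = 0L, ei = 1L))
    timer <- timer + 1L; disc[start] <- low[start] <- timer
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      if (fr$ei <= length(inc[[v]])) {
        e <- inc[[v]][fr$ei]
        stack[[length(stack)]]$ei <- fr$ei + 1L
        if (e == fr$parent_edge) next
        a <- net$edge[e, 1L]; b <- net$edge[e, 2L]
        w <- if (a == v) b else a
        if (disc[w] == 0L) {
          estack <- c(estack, e)
          timer <- timer + 1L; disc[w] <- low[w] <- timer
          stack[[length(stack) + 1L]] <- list(v = w, parent_edge = e, ei = 1L)
        } else if (disc[w] < disc[v]) {
          estack <- c(estack, e)
          low[v] <- min(low[v], disc[w])
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          u <- stack[[length(stack)]]$v
          pe <- fr$parent_edge
          low[u] <- min(low[u], low[v])
          if (low[v] >= disc[u]) {
            ## pop component up to and including pe
            k <- match(pe, rev(estack))
            take <- estack[(length(estack) - k + 1L):length(estack)]
            estack <- estack[seq_len(length(estack) - k)]
            comps[[length(comps) + 1L]] <- take
          }
        }
      }
    }
  }
  comps
}

#' Check the level-1 condition and hybrid-node degrees
#'
#' A network is level-1 when every edge belongs to at most one cycle of the
#' underlying undirected graph, i.e. reticulation cycles do not overlap.
#'
#' @param net a `phynet` network
#' @return character vector of violations; empty when the network is valid
#' @export
validate_level1 <- function(net) {
  out <- character()
  hyb <- hybrid_node_ids(net)
  comps <- bicomponents(net)
  big <- comps[vapply(comps, length, 1L) > 1L]
  hybseen <- integer(0)
  for (comp in big) {
    nodes <- unique(as.vector(net$edge[comp, ]))
    if (length(comp) != length(nodes)) {
      out <- c(out, sprintf(
        "edges %s lie in overlapping cycles (blob with %d edges, %d nodes)",
        paste(sort(comp), collapse = ","), length(comp), length(nodes)))
      next
    }
    hin <- intersect(nodes, hyb)
    nhe <- sum(net$hybrid[comp])
    if (length(hin) != 1L || nhe != 2L)
      out <- c(out, sprintf("cycle on edges %s must contain exactly one hybrid node",
                            paste(sort(comp), collapse = ",")))
    hybseen <- c(hybseen, hin)
  }
  orphan <- setdiff(hyb, hybseen)
  if (length(orphan))
    out <- c(out, sprintf("hybrid node %d has parent edges not forming a cycle",
                          orphan))
  if (!length(valid_root_nodes(net)))
    out <- c(out, "no valid root placement exists")
  out
}

## ---------------------------------------------------------------------------
## Hybrid cycles and identifiability classes
## ---------------------------------------------------------------------------

## number of taxa reachable from `node` without crossing edges in `avoid`
subtree_taxa <- function(net, node, avoid_edges) {
  inc <- incident_edges(net)
  seen <- logical(net$nnode); seen[node] <- TRUE
  queue <- node
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    for (e in setdiff(inc[[u]], avoid_edges)) {
      v <- setdiff(net$edge[e, ], u)
      if (!seen[v]) { seen[v] <- TRUE; queue <- c(queue, v) }
    }
  }
  which(seen[seq_len(net$ntax)])
}

#' Hybridization cycles and their identifiability classes
#'
#' For each hybrid node, reports the number of nodes `k` in its undirected
#' cycle, the taxon counts of the subtrees hanging off the cycle, and the
#' identifiability class: `cycle2` (k = 2, undetectable), `triangle_good`
#' (k = 3 with all three subtrees of 2+ taxa), `triangle_other`,
#' `diamond_good`, `diamond_bad_I`, `diamond_bad_II` (k = 4), or `k5plus`.
#'
#' @param net a valid level-1 `phynet`
#' @return a list with one record per hybrid node: `hybrid` (node id), `k`,
#'   `ns` (taxon counts: below the hybrid, then walking the cycle starting on
#'   the major-edge side), `class`, plus cycle node/edge bookkeeping
#' @export
hybrid_cycles <- function(net) {
  viol <- validate_level1(net)
  if (length(viol)) stop("not a level-1 network: ", viol[[1L]])
  comps <- bicomponents(net)
  big <- comps[vapply(comps, length, 1L) > 1L]
  out <- list()
  for (comp in big) {
    he <- comp[net$hybrid[comp]]
    v <- net$edge[he[1L], 2L]
    ## order cycle nodes walking from the hybrid along the major edge
    hmaj <- he[net$major[he]]; hmin <- he[!net$major[he]]
    nodes_cyc <- unique(as.vector(net$edge[comp, ]))
    walk <- c(v, setdiff(net$edge[hmaj, ], v))
    while (length(walk) < length(nodes_cyc)) {
      u <- walk[[length(walk)]]
      nxt <- setdiff(unique(as.vector(net$edge[comp[apply(
        net$edge[comp, , drop = FALSE] == u, 1L, any)], ])), walk)
      walk <- c(walk, nxt[[1L]])
    }
    ## a degree-2 root subdividing a cycle edge is representational only
    deg <- tabulate(as.vector(net$edge), net$nnode)
    drop <- walk[deg[walk] == 2L]
    walk <- setdiff(walk, drop)
    ns <- vapply(walk, function(u) length(subtree_taxa(net, u, comp)), 1L)
    k <- length(walk)
    nh <- ns[[1L]]
    cls <- if (k == 2L) "cycle2"
    else if (k == 3L) { if (all(ns >= 2L)) "triangle_good" else "triangle_other" }
    else if (k == 4L) {
      npar <- ns[c(2L, 4L)]; nopp <- ns[[3L]]
      if (all(npar == 1L) && nopp == 1L && nh >= 2L) "diamond_bad_II"
      else if (all(npar == 1L) && nh == 1L && nopp >= 2L) "diamond_bad_I"
      else "diamond_good"
    } else "k5plus"
    out[[length(out) + 1L]] <- list(
      hybrid = v, k = k, ns = unname(ns), class = cls,
      cycle_nodes = walk, cycle_edges = comp,
      major_edge = hmaj, minor_edge = hmin)
  }
  out[order(vapply(out, function(x) x$hybrid, 1L))]
}

## ---------------------------------------------------------------------------
## Major tree
## ---------------------------------------------------------------------------

#' Extract the major tree of a network
#'
#' Suppresses the minor hybrid edge (inheritance below 0.5, or the stored
#' minor designation when gamma is exactly 0.5 or unset) at every reticulation
#' and fuses the resulting degree-2 nodes, summing branch lengths.
#'
#' @param net a `phynet` network
#' @return a `phynet` tree (no hybrid edges) on the same taxa
#' @export
major_tree <- function(net) {
  if (!any(net$hybrid)) return(net)
  minor <- which(net$hybrid & !net$major)
  net <- delete_edges(net, minor)
  net$hybrid[] <- FALSE
  net$gamma[] <- NA_real_
  net$major[] <- TRUE
  suppress_degree2(net)
}

## ---------------------------------------------------------------------------
## Conversions to/from ape
## ---------------------------------------------------------------------------

#' Convert a tree-like `phynet` to an ape `phylo` object
#' @param net a `phynet` with no hybrid edges
#' @return an object of class `phylo`
#' @export
as_phylo <- function(net) {
  if (any(net$hybrid)) stop("network has hybrid edges; extract a tree first")
  ape::read.tree(text = write_enewick(net))
}

#' Convert an ape `phylo` tree to a `phynet`
#' @param tree an object of class `phylo`
#' @return a `phynet` with no hybrid edges
#' @export
as_phynet <- function(tree) {
  if (inherits(tree, "phynet")) return(tree)
  stopifnot(inherits(tree, "phylo"))
  E <- nrow(tree$edge)
  len <- if (is.null(tree$edge.length)) rep(NA_real_, E) else tree$edge.length
  new_phynet(tree$edge, len, rep(FALSE, E), rep(NA_real_, E), rep(TRUE, E),
             tree$tip.label, ape::Ntip(tree) + 1L)
}

## ---------------------------------------------------------------------------
## Equality and canonical hashing (semi-directed semantics)
## ---------------------------------------------------------------------------

## cluster (set of leaf labels) below the child of each edge, following all
## directed paths
edge_clusters <- function(net) {
  below <- vector("list", net$nnode)
  order <- topo_order(net)
  for (v in rev(order)) {
    if (v <= net$ntax) { below[[v]] <- net$labels[v]; next }
    kids <- net$edge[net$edge[, 1L] == v, 2L]
    below[[v]] <- sort(unique(unlist(below[kids])))
  }
  lapply(net$edge[, 2L], function(v) below[[v]])
}

## parents-before-children topological order of nodes
topo_order <- function(net) {
  indeg <- node_indeg(net)
  queue <- net$root
  ord <- integer(0)
  indeg_left <- indeg
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    ord <- c(ord, u)
    for (e in which(net$edge[, 1L] == u)) {
      v <- net$edge[e, 2L]
      indeg_left[v] <- indeg_left[v] - 1L
      if (indeg_left[v] == 0L) queue <- c(queue, v)
    }
  }
  ord
}

## canonical string of the rooted network (labels kept or anonymized).
## Every occurrence of a hybrid node carries its fully expanded subtree, so
## the string does not depend on major/minor designations or edge order;
## hybrid tags are renumbered by first appearance to make it canonical.
rooted_canonical <- function(net, labeled = TRUE) {
  hyb <- hybrid_node_ids(net)
  rec <- function(v) {
    if (v <= net$ntax)
      return(if (labeled) net$labels[v] else "*")
    if (v %in% hyb) {
      kid <- net$edge[which(net$edge[, 1L] == v), 2L]
      return(paste0("(", rec(kid), ")#", match(v, hyb)))
    }
    kids <- net$edge[which(net$edge[, 1L] == v), 2L]
    paste0("(", paste(sort(vapply(kids, rec, "")), collapse = ","), ")")
  }
  s <- rec(net$root)
  ## renumber hybrid tags canonically by first occurrence in the string
  occ <- regmatches(s, gregexpr("#[0-9]+", s))[[1L]]
  for (i in seq_along(unique(occ))) {
    s <- gsub(paste0(unique(occ)[i], "(?![0-9])"), paste0("@H", i), s, perl = TRUE)
  }
  s
}

#' Canonical hash of a semi-directed network topology
#'
#' Minimum, over all valid root placements, of a canonical rooted string;
#' invariant to node numbering and to the stored orientation. With
#' `labeled = FALSE` it is also invariant to tip relabeling.
#'
#' @param net a `phynet`
#' @param labeled keep leaf labels (default) or anonymize them
#' @return a character scalar
#' @export
sd_hash <- function(net, labeled = TRUE) {
  net <- net_unroot(suppress_degree2(net))
  roots <- valid_root_nodes(net)
  min(vapply(roots, function(p) rooted_canonical(orient_network(net, p), labeled), ""))
}

## full equality given matched taxa: same semi-directed topology, lengths and
## gammas within tolerance. Compares edges by (cluster, type) signature after
## rooting both networks the same way.
phynet_equal <- function(a, b, tol = 1e-9, check_numeric = TRUE) {
  if (!setequal(a$labels, b$labels)) return(FALSE)
  a <- net_unroot(a); b <- net_unroot(b)
  if (sd_hash(a) != sd_hash(b)) return(FALSE)
  if (!check_numeric) return(TRUE)
  sig <- function(net) {
    cl <- edge_clusters(net)
    type <- ifelse(!net$hybrid, "t", ifelse(net$major, "hM", "hm"))
    key <- paste(vapply(cl, paste, "", collapse = "|"), type)
    data.frame(key = key, len = net$length, gamma = net$gamma,
               stringsAsFactors = FALSE)
  }
  ## root both at the same (valid for both) position, by outgroup-ish cluster:
  ## use the canonical minimal rooting for each
  can_root <- function(net) {
    roots <- valid_root_nodes(net)
    ss <- vapply(roots, function(p) rooted_canonical(orient_network(net, p), TRUE), "")
    orient_network(net, roots[order(ss)[1L]])
  }
  sa <- sig(can_root(a)); sb <- sig(can_root(b))
  sa <- sa[order(sa$key), ]; sb <- sb[order(sb$key), ]
  if (!identical(sa$key, sb$key)) return(FALSE)
  okl <- mapply(function(x, y) (is.na(x) && is.na(y)) ||
                  (!is.na(x) && !is.na(y) && abs(x - y) <= tol), sa$len, sb$len)
  okg <- mapply(function(x, y) (is.na(x) && is.na(y)) ||
                  (!is.na(x) && !is.na(y) && abs(x - y) <= tol), sa$gamma, sb$gamma)
  all(okl) && all(okg)
}

#' @export
print.phynet <- function(x, ...) {
  cat(sprintf("semi-directed level-1 network: %d taxa, %d hybridization(s)\n",
              x$ntax, n_hybrids(x)))
  cat(write_enewick(x), "\n")
  invisible(x)
}
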