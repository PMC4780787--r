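## ---------------------------------------------------------------------------
## Network construction: edge subdivision, adding hybridizations, random
## level-1 networks, and the canonical 4-taxon enumeration.
## ---------------------------------------------------------------------------

## split edge e at a new node; returns list(net, node, upper_edge, lower_edge)
subdivide_edge <- function(net, e, frac = 0.5) {
  newnode <- net$nnode + 1L
  p <- net$edge[e, 1L]; c0 <- net$edge[e, 2L]
  l <- net$length[e]
  net$edge[e, ] <- c(p, newnode)
  net$edge <- rbind(net$edge, c(newnode, c0))
  net$length[e] <- l * frac
  net$length <- c(net$length, l * (1 - frac))
  ## a subdivided hybrid edge keeps its hybrid character on the lower part
  ## (the part whose child is the hybrid node)
  net$hybrid <- c(net$hybrid, net$hybrid[e])
  net$gamma <- c(net$gamma, net$gamma[e])
  net$major <- c(net$major, net$major[e])
  net$hybrid[e] <- FALSE; net$gamma[e] <- NA_real_; net$major[e] <- TRUE
  net$nnode <- newnode
  list(net = net, node = newnode, upper = e, lower = nrow(net$edge))
}

#' Add a hybridization between two edges
#'
#' Subdivides the donor and recipient edges and inserts a minor hybrid edge
#' from the donor point into the new hybrid node on the recipient edge. The
#' result is re-oriented; `NULL` is returned when no valid semi-directed
#' orientation exists (e.g. the proposal creates a directed loop).
#'
#' @param net a `phynet`
#' @param donor_edge,recipient_edge edge indices (must differ)
#' @param gamma inheritance probability of the new minor edge
#' @param length length given to the new hybrid edge
#' @return a `phynet`, or `NULL` if the placement is invalid
#' @export
add_hybridization <- function(net, donor_edge, recipient_edge, gamma = 0.1,
                              length = 0.1) {
  if (donor_edge == recipient_edge) return(NULL)
  if (net$hybrid[recipient_edge] || net$hybrid[donor_edge]) return(NULL)
  s1 <- subdivide_edge(net, donor_edge)
  s2 <- subdivide_edge(s1$net, recipient_edge)
  net2 <- s2$net
  U <- s1$node; H <- s2$node
  net2$edge <- rbind(net2$edge, c(U, H))
  net2$length <- c(net2$length, length)
  net2$hybrid <- c(net2$hybrid, TRUE)
  net2$gamma <- c(net2$gamma, gamma)
  net2$major <- c(net2$major, FALSE)
  ## the recipient edge's lower segment keeps pointing at the original child;
  ## its upper segment becomes the major partner edge
  emaj <- s2$upper
  net2$hybrid[emaj] <- TRUE
  net2$gamma[emaj] <- 1 - gamma
  net2$major[emaj] <- TRUE
  out <- reorient_any(net2)
  if (is.null(out)) return(NULL)
  if (length(check_phynet(out))) return(NULL)
  out
}

## add a 2-cycle ("bubble") on one edge: both parallel edges into the lower
## subdivision point
add_bubble <- function(net, e, gamma = 0.3) {
  s1 <- subdivide_edge(net, e)           # upper point
  s2 <- subdivide_edge(s1$net, s1$lower) # lower point
  net2 <- s2$net
  X1 <- s1$node; X2 <- s2$node
  mid <- s2$upper                        # edge X1 -> X2
  net2$edge <- rbind(net2$edge, c(X1, X2))
  net2$length <- c(net2$length, net2$length[mid])
  net2$hybrid[mid] <- TRUE; net2$gamma[mid] <- 1 - gamma; net2$major[mid] <- TRUE
  net2$hybrid <- c(net2$hybrid, TRUE)
  net2$gamma <- c(net2$gamma, gamma)
  net2$major <- c(net2$major, FALSE)
  out <- reorient_any(net2)
  if (is.null(out) || length(check_phynet(out))) return(NULL)
  out
}

## fuse a degree-2 root for hashing/equality: semi-directed semantics ignore
## where the root subdivides an edge
net_unroot <- function(net) {
  repeat {
    kids <- which(net$edge[, 1L] == net$root)
    if (length(kids) != 2L) return(net)
    if (all(net$hybrid[kids])) return(net)
    e1 <- kids[1L]; e2 <- kids[2L]
    ## e1 will supply the new root (its child node): it must be a tree edge
    ## with an internal child; e2's identity (possibly hybrid) is kept on the
    ## fused edge, which still points at e2's child
    if (net$hybrid[e1] ||
        (net$edge[e1, 2L] <= net$ntax && !net$hybrid[e2] &&
           net$edge[e2, 2L] > net$ntax)) {
      tmp <- e1; e1 <- e2; e2 <- tmp
    }
    x <- net$edge[e1, 2L]; y <- net$edge[e2, 2L]
    if (x <= net$ntax) return(net)  # would have to root at a leaf: keep
    net$edge[e2, ] <- c(x, y)
    net$length[e2] <- net$length[e1] + net$length[e2]
    keep <- setdiff(seq_len(nrow(net$edge)), e1)
    net$edge <- net$edge[keep, , drop = FALSE]
    net$length <- net$length[keep]; net$hybrid <- net$hybrid[keep]
    net$gamma <- net$gamma[keep]; net$major <- net$major[keep]
    net$root <- x
    net <- compact_nodes(net)
    out <- reorient_any(net)
    if (is.null(out)) stop("internal error: could not re-orient after unrooting")
    net <- out
  }
}

#' Random level-1 network
#'
#' Simulates a coalescent tree on `n` taxa (ape::rcoal) and adds `h`
#' hybridizations by repeatedly drawing a donor and a recipient edge at
#' random, rejecting proposals that break the level-1 condition or admit no
#' valid rooting. Used as the synthetic topology generator.
#'
#' @param n number of taxa
#' @param h number of hybridizations
#' @param gamma inheritance probability assigned to each new minor edge
#'   (recycled)
#' @param taxa optional taxon labels (default t1..tn)
#' @param classes optional character vector: admissible cycle classes; when
#'   given, hybridizations whose cycle class is not listed are rejected
#' @return a `phynet`
#' @export
rnetwork <- function(n, h, gamma = 0.3, taxa = paste0("t", seq_len(n)),
                     classes = NULL) {
  tr <- ape::rcoal(n, tip.label = taxa)
  net <- as_phynet(tr)
  gamma <- rep_len(gamma, max(h, 1L))
  added <- 0L
  tries <- 0L
  while (added < h) {
    tries <- tries + 1L
    if (tries > 500L) stop("could not place ", h, " level-1 hybridizations")
    cand <- which(!net$hybrid)
    de <- sample(cand, 1L); re <- sample(setdiff(cand, de), 1L)
    net2 <- add_hybridization(net, de, re, gamma = gamma[added + 1L],
                              length = stats::rexp(1, 2))
    if (is.null(net2)) next
    if (length(validate_level1(net2))) next
    if (!is.null(classes)) {
      cls <- vapply(hybrid_cycles(net2), function(x) x$class, "")
      if (!all(cls %in% classes)) next
    }
    net <- net2
    added <- added + 1L
  }
  net
}

#' The canonical 4-taxon single-hybridization networks
#'
#' Exhaustive enumeration of the semi-directed level-1 binary networks on 4
#' taxa with one reticulation: a hybridization is attached between every
#' ordered pair of distinct edges of the unrooted quartet tree under every
#' rooting (covering both directions of the recipient edge), and a 2-cycle
#' bubble is placed on every edge. Results are deduplicated up to tip
#' relabeling by canonical form; the two semi-directed orientations of a
#' 2-cycle describe the same bubble on an edge and are identified.
#'
#' @return list of `phynet` networks (unit-ish branch lengths, gamma 0.3)
#' @export
canonical_quartet_networks <- function() {
  base <- parse_enewick("((a:1,b:1):1,c:1,d:1);")
  nets <- list()
  rootings <- lapply(c("a", "b", "c", "d"), function(tx)
    root_with_outgroup(base, tx))
  rootings <- c(list(base), rootings)
  for (b in rootings) {
    E <- nrow(b$edge)
    for (de in seq_len(E)) for (re in seq_len(E)) {
      if (de == re) next
      net <- add_hybridization(b, de, re, gamma = 0.3, length = 1)
      if (is.null(net)) next
      if (length(validate_level1(net))) next
      nets[[length(nets) + 1L]] <- net_unroot(net)
    }
  }
  for (e in seq_len(nrow(base$edge))) {
    net <- add_bubble(base, e, gamma = 0.3)
    if (!is.null(net) && !length(validate_level1(net)))
      nets[[length(nets) + 1L]] <- net
  }
  ## identify bubbles regardless of orientation: hash with 2-cycle hybrids
  ## neutralized by dropping the minor parallel edge
  bubble_key <- function(net) {
    hc <- hybrid_cycles(net)
    for (x in hc) if (x$k == 2L) {
      tre <- major_tree(net)
      side <- min(x$ns[1L], net$ntax - x$ns[1L])
      return(paste0("bubble:", sd_hash(tre, labeled = FALSE), ":side", side))
    }
    sd_hash(net, labeled = FALSE)
  }
  keys <- vapply(nets, bubble_key, "")
  nets[!duplicated(keys)]
}

#' Canonical hash of the underlying unrooted topology
#'
#' Ignores the direction of hybrid edges: the minimum of [sd_hash()] over
#' every admissible re-designation of each cycle's hybrid node. Two networks
#' with equal hashes share the underlying undirected (unrooted) topology.
#'
#' @param net a `phynet`
#' @return a character scalar
#' @export
unrooted_hash <- function(net) {
  net <- net_unroot(suppress_degree2(net))
  hcs <- tryCatch(hybrid_cycles(net), error = function(e) NULL)
  if (is.null(hcs) || !length(hcs)) return(sd_hash(net))
  variants <- list(net)
  for (x in hcs) {
    variants <- unlist(lapply(variants, function(v) {
      out <- list()
      for (cand in x$cycle_nodes) {
        v2 <- v
        ce <- x$cycle_edges
        inc <- ce[v2$edge[ce, 1L] == cand | v2$edge[ce, 2L] == cand]
        if (length(inc) != 2L) next
        v2$hybrid[ce] <- FALSE
        v2$gamma[ce] <- NA_real_
        v2$major[ce] <- TRUE
        v2$hybrid[inc] <- TRUE
        v2$major[inc[2L]] <- FALSE
        ## point both hybrid edges at the new hybrid node
        for (e in inc) if (v2$edge[e, 2L] != cand)
          v2$edge[e, ] <- rev(v2$edge[e, ])
        o <- reorient_any(v2)
        if (is.null(o) || length(check_phynet(o))) next
        out[[length(out) + 1L]] <- o
      }
      out
    }), recursive = FALSE)
  }
  if (!length(variants)) return(sd_hash(net))
  min(vapply(variants, sd_hash, ""))
}
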