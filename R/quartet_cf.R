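## ---------------------------------------------------------------------------
## Expected quartet concordance factors under the network multispecies
## coalescent on level-1 semi-directed networks.
##
## Canonical quartet order: the 4 taxa sorted lexicographically (t1<t2<t3<t4);
## q1 = t1t2|t3t4, q2 = t1t3|t2t4, q3 = t1t4|t2t3.
## ---------------------------------------------------------------------------

#' Expected quartet CFs on a species tree
#'
#' For an unrooted 4-taxon species tree with internal edge of length `t`
#' coalescent units, the probability that a gene tree displays the species
#' split is 1 - (2/3) exp(-t) and each discordant split has probability
#' (1/3) exp(-t) (incomplete lineage sorting only).
#'
#' @param t internal branch length in coalescent units (`Inf` allowed)
#' @return numeric vector of 3 probabilities (concordant split first)
#' @export
expected_cf_tree <- function(t) {
  if (is.na(t) || t < 0) stop("branch length must be >= 0")
  m <- exp(-t) / 3
  c(1 - 2 * m, m, m)
}

#' Expected quartet CFs with a single-descendant hybrid
#'
#' Closed form for the 4-taxon network in which one taxon is a hybrid with a
#' single descendant: with probability 1 - gamma its gene lineage descends
#' from the major parent (species tree with internal length `t1`) and with
#' probability gamma from the minor parent (internal length `t1 + t2`).
#'
#' @param t1 internal edge length between the quartet's major-tree join and
#'   the major parent of the hybrid
#' @param t2 length of the cycle tree edge separating the two parents
#' @param gamma minor-edge inheritance probability
#' @return 3 CFs (major split first)
#' @export
expected_cf_hybrid_single <- function(t1, t2, gamma) {
  stopifnot(t1 >= 0, t2 >= 0, gamma >= 0, gamma <= 1)
  minor <- (1 - gamma) * exp(-t1) / 3 + gamma * exp(-t1 - t2) / 3
  c(1 - 2 * minor, minor, minor)
}

#' Expected quartet CFs with a two-descendant hybrid
#'
#' Closed form for the 4-taxon network in which two taxa (a cherry) descend
#' from the hybrid node: the pair may coalesce below the hybrid (length `t1`),
#' otherwise each lineage independently follows the minor parental edge
#' (length `t4`) with probability gamma or the major edge (length `t3`), and
#' the paths rejoin `t2` below the rest of the quartet.
#'
#' @param t1 edge below the hybrid node
#' @param t2 tree edge above the reticulation cycle
#' @param t3 major hybrid edge length
#' @param t4 minor hybrid edge length
#' @param gamma minor-edge inheritance probability
#' @return 3 CFs (major split first); the two minor CFs are exactly equal
#' @export
expected_cf_hybrid_double <- function(t1, t2, t3, t4, gamma) {
  stopifnot(t1 >= 0, t2 >= 0, t3 >= 0, t4 >= 0, gamma >= 0, gamma <= 1)
  g <- gamma
  major <- 1 - exp(-t1) + exp(-t1) *
    ((1 - g)^2 * (1 - 2 / 3 * exp(-t2 - t3)) +
       2 * g * (1 - g) * (1 - 2 / 3 * exp(-t2)) +
       g^2 * (1 - 2 / 3 * exp(-t4 - t2)))
  c(major, (1 - major) / 2, (1 - major) / 2)
}

## closed form for a k=3 cycle whose hybrid subtends the quartet cherry {a,b}
## and whose two parents each subtend one pendant taxon. Derived by the
## first-coalescence argument and verified against the enumeration engine.
##  th: edge below the hybrid; tma/tmi: major/minor hybrid edge; tc: cycle
##  tree edge between the parents. Returns (ab|cd, x|c-pair, x|d-pair) where
##  the second entry pairs the major-parent pendant with `a`.
cf_triangle2 <- function(th, tma, tmi, tc, gamma) {
  g <- gamma
  eh <- exp(-th)
  q1 <- (1 - eh) + eh * ((1 - g)^2 * (1 - 2 / 3 * exp(-tma)) +
                           g^2 * (1 - 2 / 3 * exp(-tmi)) +
                           2 * g * (1 - g) * exp(-tc) / 3)
  qm <- eh * ((1 - g)^2 * exp(-tma) / 3 + g^2 * exp(-tmi) / 3 +
                g * (1 - g) * (1 - exp(-tc) / 3))
  c(q1, qm, qm)
}

## equivalent single-edge length replacing a 2-cycle (parallel hybrid edge
## pair) traversed by at most two lineages:
##  exp(-t') = (1-g)^2 exp(-tmaj) + g^2 exp(-tmin) + 2 g (1-g)
k2_merge_length <- function(tmaj, tmin, gamma) {
  g <- gamma
  -log((1 - g)^2 * exp(-tmaj) + g^2 * exp(-tmin) + 2 * g * (1 - g))
}

#' Reduce an undetectable reticulation in a 4-taxon network
#'
#' Removes one reticulation whose effect on expected quartet CFs can be
#' absorbed exactly into transformed branch lengths: either (a) a hybrid node
#' subtending a single quartet taxon, replaced by the gamma-weighted mixture
#' collapsed onto the major position with the minor alternative encoded in a
#' transformed internal length (only possible when both alternatives display
#' the same quartet, e.g. a k = 3 cycle); or (b) a 2-cycle (parallel hybrid
#' edges) crossed by at most two lineages, replaced by a single edge of
#' length -log((1-g)^2 e^(-t_major) + g^2 e^(-t_minor) + 2g(1-g)).
#'
#' @param net a 4-taxon `phynet` with at least one hybrid
#' @return a `phynet` with one fewer hybrid and identical expected CFs
#' @export
reduce_undetectable_cycle <- function(net) {
  if (net$ntax != 4L) stop("reduction operates on 4-taxon networks")
  if (!any(net$hybrid)) stop("no reticulation to reduce")
  wsn <- wsn_suppress(wsn_from_phynet(net))
  red <- wsn_reduce_once(wsn)
  if (is.null(red)) stop("no reticulation reducible by the transformation rules")
  wsn_to_phynet(red)
}

## ---------------------------------------------------------------------------
## Working subnetworks: a light rooted structure with edge provenance used by
## subnetwork extraction, reduction and plan compilation.
##  fields: taxa (4 sorted labels; leaves 1..4), edge (P,C), hybrid, major,
##          len (numeric, possibly NA), gam, root, nnode,
##          prov (list: original edge ids summed into this edge; may include
##                virtual entries list(k2 = ...) from merges),
##          gref (original edge id carrying this hybrid edge's gamma)
## ---------------------------------------------------------------------------

wsn_new <- function(taxa, edge, hybrid, major, len, gam, root, prov, gref) {
  list(taxa = taxa, edge = edge, hybrid = hybrid, major = major, len = len,
       gam = gam, root = as.integer(root), nnode = max(edge),
       prov = prov, gref = gref)
}

wsn_from_phynet <- function(net) {
  ord <- order(net$labels)
  ## renumber leaves so leaf i is the i-th sorted taxon
  map <- integer(net$nnode); map[ord] <- seq_along(ord)
  rest <- setdiff(seq_len(net$nnode), seq_len(net$ntax))
  map[rest] <- net$ntax + seq_along(rest)
  edge <- net$edge; edge[] <- map[edge]
  wsn_new(sort(net$labels), edge, net$hybrid, net$major, net$length,
          net$gamma, map[net$root],
          prov = as.list(seq_len(nrow(edge))),
          gref = ifelse(net$hybrid, seq_len(nrow(edge)), NA_integer_))
}

wsn_to_phynet <- function(w) {
  new_phynet(w$edge, w$len, w$hybrid, w$major,
             labels = w$taxa, gamma = w$gam, root = w$root)
}

wsn_drop_edges <- function(w, idx) {
  keep <- setdiff(seq_len(nrow(w$edge)), idx)
  w$edge <- w$edge[keep, , drop = FALSE]
  w$hybrid <- w$hybrid[keep]; w$major <- w$major[keep]
  w$len <- w$len[keep]; w$gam <- w$gam[keep]
  w$prov <- w$prov[keep]; w$gref <- w$gref[keep]
  ntax <- length(w$taxa)
  used <- sort(unique(c(as.vector(w$edge), w$root, seq_len(ntax))))
  map <- integer(max(used)); map[used] <- seq_along(used)
  w$edge[] <- map[w$edge]; w$root <- map[w$root]; w$nnode <- length(used)
  w
}

## fuse degree-2 nodes (1 in, 1 out) and degree-1 roots
wsn_suppress <- function(w) {
  ntax <- length(w$taxa)
  repeat {
    indeg <- tabulate(w$edge[, 2L], w$nnode)
    outdeg <- tabulate(w$edge[, 1L], w$nnode)
    if (outdeg[w$root] == 1L && indeg[w$root] == 0L) {
      e <- which(w$edge[, 1L] == w$root)
      w$root <- w$edge[e, 2L]
      w <- wsn_drop_edges(w, e)
      next
    }
    ## fuse a degree-2 root: CFs are invariant to the root position, and a
    ## root subdividing a cycle edge would obscure the cycle's true size
    if (outdeg[w$root] == 2L && indeg[w$root] == 0L) {
      kids <- which(w$edge[, 1L] == w$root)
      if (!all(w$hybrid[kids])) {
        e1 <- kids[1L]; e2 <- kids[2L]
        if (w$hybrid[e1]) { tmp <- e1; e1 <- e2; e2 <- tmp }
        ## e1 is a tree edge; fuse into a single edge parented at e1's child
        x <- w$edge[e1, 2L]; y <- w$edge[e2, 2L]
        if (x <= ntax && !w$hybrid[e2]) { tmp <- e1; e1 <- e2; e2 <- tmp
                                          tmp <- x; x <- y; y <- tmp }
        if (x <= ntax) break  # cannot re-root at a leaf; keep as is
        w$edge[e2, ] <- c(x, y)
        w$len[e2] <- if (is.na(w$len[e1]) || is.na(w$len[e2]))
          NA_real_ else w$len[e1] + w$len[e2]
        w$prov[[e2]] <- c(w$prov[[e2]], w$prov[[e1]])
        w$root <- x
        w <- wsn_drop_edges(w, e1)
        next
      }
    }
    v <- setdiff(which(indeg == 1L & outdeg == 1L), seq_len(ntax))
    if (!length(v)) break
    v <- v[[1L]]
    ein <- which(w$edge[, 2L] == v)
    eout <- which(w$edge[, 1L] == v)
    w$edge[ein, 2L] <- w$edge[eout, 2L]
    w$len[ein] <- if (is.na(w$len[ein]) || is.na(w$len[eout]))
      NA_real_ else w$len[ein] + w$len[eout]
    w$prov[[ein]] <- c(w$prov[[ein]], w$prov[[eout]])
    if (w$hybrid[eout]) {
      w$hybrid[ein] <- TRUE
      w$gam[ein] <- w$gam[eout]; w$major[ein] <- w$major[eout]
      w$gref[ein] <- w$gref[eout]
    }
    w <- wsn_drop_edges(w, eout)
  }
  w
}

## restrict a network to 4 taxa: keep ancestors, drop invisible reticulations,
## fuse chains. Returns a working subnetwork.
extract_subnet <- function(net, taxa4) {
  stopifnot(length(taxa4) == 4L)
  ids <- match(taxa4, net$labels)
  if (anyNA(ids)) stop("taxa not in the network: ",
                       paste(taxa4[is.na(ids)], collapse = ", "))
  ## mark ancestors of the 4 leaves
  keepn <- logical(net$nnode)
  keepn[ids] <- TRUE
  repeat {
    add <- unique(net$edge[net$edge[, 2L] %in% which(keepn), 1L])
    add <- add[!keepn[add]]
    if (!length(add)) break
    keepn[add] <- TRUE
  }
  keepe <- keepn[net$edge[, 1L]] & keepn[net$edge[, 2L]]
  sub <- net
  sub$edge <- net$edge[keepe, , drop = FALSE]
  sub$length <- net$length[keepe]; sub$hybrid <- net$hybrid[keepe]
  sub$gamma <- net$gamma[keepe]; sub$major <- net$major[keepe]
  prov <- as.list(which(keepe))
  gref <- ifelse(sub$hybrid, which(keepe), NA_integer_)
  ## relabel: the 4 leaves (sorted) become 1..4; drop other leaves' ids
  old_leaves <- ids[order(taxa4)]
  used <- sort(unique(c(as.vector(sub$edge), net$root)))
  used <- c(old_leaves, setdiff(used, old_leaves))
  map <- integer(net$nnode); map[used] <- seq_along(used)
  sub$edge[] <- map[sub$edge]
  w <- wsn_new(sort(taxa4), sub$edge, sub$hybrid, sub$major, sub$length,
               sub$gamma, map[net$root], prov, gref)
  w <- wsn_suppress(w)
  ## a root that kept only 2 children but sits mid-path is fine (rooted net)
  w
}

## hybrid nodes and, for each, its cycle data on the rooted working subnet
wsn_hybrids <- function(w) {
  hv <- sort(unique(w$edge[w$hybrid, 2L]))
  lapply(hv, function(v) {
    pe <- which(w$hybrid & w$edge[, 2L] == v)
    p1 <- w$edge[pe[1L], 1L]; p2 <- w$edge[pe[2L], 1L]
    if (p1 == p2) {
      return(list(hybrid = v, k = 2L, parents = c(p1, p2), pedges = pe,
                  top = p1, path_nodes = integer(0)))
    }
    ## undirected path p1 -> p2 avoiding v
    inc <- vector("list", w$nnode)
    for (e in seq_len(nrow(w$edge))) {
      a <- w$edge[e, 1L]; b <- w$edge[e, 2L]
      inc[[a]] <- c(inc[[a]], e); inc[[b]] <- c(inc[[b]], e)
    }
    prev <- integer(w$nnode); prev[p1] <- -1L
    queue <- p1
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      if (u == p2) break
      for (e in inc[[u]]) {
        x <- setdiff(w$edge[e, ], u)
        if (length(x) != 1L) next  # parallel self pair
        if (x == v || prev[x] != 0L) next
        prev[x] <- u; queue <- c(queue, x)
      }
    }
    if (prev[p2] == 0L) stop("could not trace the reticulation cycle path")
    path <- p2
    while (path[[1L]] != p1) path <- c(prev[path[[1L]]], path)
    nodes <- c(v, path)
    ## top: the path node whose parent edge is not a cycle edge
    cyc_edges <- c(pe, vapply(seq_len(length(path) - 1L), function(i) {
      which((w$edge[, 1L] == path[i] & w$edge[, 2L] == path[i + 1L]) |
              (w$edge[, 1L] == path[i + 1L] & w$edge[, 2L] == path[i]))[1L]
    }, 1L))
    top <- NA_integer_
    for (x in path) {
      pe_x <- which(w$edge[, 2L] == x)
      if (!length(pe_x) || !any(pe_x %in% cyc_edges)) { top <- x; break }
    }
    list(hybrid = v, k = length(nodes), parents = c(p1, p2), pedges = pe,
         top = top, path_nodes = path, cyc_edges = cyc_edges)
  })
}

## taxa (1..4 leaf ids) below each node, following all directed paths
wsn_taxa_below <- function(w) {
  ntax <- length(w$taxa)
  below <- rep(list(integer(0)), w$nnode)
  for (i in seq_len(ntax)) below[[i]] <- i
  remaining <- rep(TRUE, w$nnode)
  remaining[seq_len(ntax)] <- FALSE
  while (any(remaining)) {
    progressed <- FALSE
    for (v in which(remaining)) {
      kids <- w$edge[w$edge[, 1L] == v, 2L]
      if (all(!remaining[kids])) {
        below[[v]] <- sort(unique(unlist(below[kids])))
        remaining[v] <- FALSE
        progressed <- TRUE
      }
    }
    if (!progressed) stop("cyclic structure in working subnetwork")
  }
  below
}

## topology index of a coalescing pair among leaves 1..4 (canonical order):
## {1,2}/{3,4} -> 1, {1,3}/{2,4} -> 2, {1,4}/{2,3} -> 3
pair_topology <- function(x, y) {
  if (x > y) { tmp <- x; x <- y; y <- tmp }
  if (x == 1L) y - 1L else 8L - x - y
}

## combine two independent branch states (u, d1, d2, d3)
state_combine <- function(s1, s2) {
  c(s1[1L] * s2[1L],
    s1[-1L] * s2[1L] + s1[1L] * s2[-1L] + s1[-1L] * s2[-1L])
}

## undecided mass crossing an edge of length L with alive set S: first
## coalescence decides the quartet, later ones cannot change it
state_edge <- function(s, S, L) {
  j <- length(S)
  if (j < 2L || L <= 0) return(s)
  r <- j * (j - 1L) / 2
  surv <- exp(-r * L)
  add <- s[1L] * (1 - surv) / r
  for (a in seq_len(j - 1L)) for (b in seq.int(a + 1L, j)) {
    q <- pair_topology(S[a], S[b])
    s[q + 1L] <- s[q + 1L] + add
  }
  s[1L] <- s[1L] * surv
  s
}

## ---------------------------------------------------------------------------
## Coalescent-history enumeration engine: exact quartet CFs on a rooted
## level-1 network with <= 4 sampled lineages. Dynamic program from the leaves
## to the root over (probability undecided, probability each split already
## formed); within each edge carrying j lineages, the first coalescence picks
## a uniform pair at rate choose(j,2); at a hybrid node every remaining
## lineage independently follows the minor parent with probability gamma.
## ---------------------------------------------------------------------------
engine_cf_wsn <- function(w) {
  len <- ifelse(is.na(w$len), 0, w$len)
  hrecs <- wsn_hybrids(w)
  below <- wsn_taxa_below(w)
  top_of <- setNames(hrecs, vapply(hrecs, function(h) h$top, 1L))
  children_edges <- function(v) which(w$edge[, 1L] == v)
  cache <- new.env(parent = emptyenv())

  ## state after crossing child edge e (transition applied)
  edge_state <- function(e) {
    v <- w$edge[e, 2L]
    state_edge(node_state(v), below[[v]], len[e])
  }

  cycle_state <- function(v, h) {
    H <- h$hybrid
    ce_h <- children_edges(H)        # hybrid's child edge
    sH <- edge_state(ce_h)
    SH <- below[[H]]
    pe <- h$pedges
    pe_min <- pe[!w$major[pe]]; pe_maj <- pe[w$major[pe]]
    g <- w$gam[pe_min]
    if (is.na(g)) stop("hybrid edge without gamma in engine")
    ## arms of the cycle from each parent up to the top
    arm_of <- function(parent) {
      if (h$k == 2L) return(list(nodes = integer(0), edges = integer(0)))
      path <- h$path_nodes
      it <- match(h$top, path); ip <- match(parent, path)
      idx <- if (ip < it) seq.int(ip, it) else seq.int(ip, it)
      nodes <- path[idx]
      edges <- vapply(seq_len(length(nodes) - 1L), function(i) {
        which(((w$edge[, 1L] == nodes[i] & w$edge[, 2L] == nodes[i + 1L]) |
                 (w$edge[, 1L] == nodes[i + 1L] & w$edge[, 2L] == nodes[i])) &
                !w$hybrid)[1L]
      }, 1L)
      list(nodes = nodes, edges = edges)
    }
    p_min <- w$edge[pe_min, 1L]; p_maj <- w$edge[pe_maj, 1L]
    arm_min <- arm_of(p_min); arm_maj <- arm_of(p_maj)
    ## cached attachment states for intermediate cycle nodes
    att <- function(x) {
      ce <- setdiff(children_edges(x), c(pe, arm_min$edges, arm_maj$edges))
      if (!length(ce)) return(NULL)
      list(state = edge_state(ce), taxa = below[[w$edge[ce, 2L]]])
    }
    att_cache <- lapply(setNames(nm = as.character(
      setdiff(unique(c(arm_min$nodes, arm_maj$nodes)), v))), function(nm) att(as.integer(nm)))
    prop <- function(T_set, arm, pe_side) {
      st <- c(1, 0, 0, 0)
      alive <- T_set
      st <- state_edge(st, alive, len[pe_side])
      if (length(arm$nodes) > 1L) {
        for (i in seq_len(length(arm$nodes) - 1L)) {
          x <- arm$nodes[i]
          a <- att_cache[[as.character(x)]]
          if (!is.null(a)) {
            st <- state_combine(st, a$state)
            alive <- sort(unique(c(alive, a$taxa)))
          }
          st <- state_edge(st, alive, len[arm$edges[i]])
        }
      }
      list(state = st, taxa = alive)
    }
    m <- length(SH)
    total <- c(0, 0, 0, 0)
    subsets <- lapply(0:(2^m - 1L), function(mask)
      SH[bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) > 0L])
    uH <- sH[1L]
    for (T_set in subsets) {
      wT <- g^length(T_set) * (1 - g)^(m - length(T_set))
      if (wT == 0) next
      a1 <- prop(T_set, arm_min, pe_min)
      a2 <- prop(setdiff(SH, T_set), arm_maj, pe_maj)
      total <- total + uH * wT * state_combine(a1$state, a2$state)
    }
    ## decided mass at the hybrid only needs the attachments' states
    dstate <- c(0, sH[-1L])
    for (a in att_cache) if (!is.null(a)) dstate <- state_combine(dstate, a$state)
    st <- total + dstate
    ## any extra (non-cycle) children of the top node
    extra <- setdiff(children_edges(v), c(pe, arm_min$edges, arm_maj$edges))
    for (e in extra) st <- state_combine(st, edge_state(e))
    st
  }

  node_state <- function(v) {
    key <- as.character(v)
    if (!is.null(cache[[key]])) return(cache[[key]])
    st <- if (v <= 4L) c(1, 0, 0, 0)
    else if (key %in% names(top_of)) cycle_state(v, top_of[[key]])
    else {
      s <- c(1, 0, 0, 0)
      for (e in children_edges(v)) s <- state_combine(s, edge_state(e))
      s
    }
    cache[[key]] <- st
    st
  }

  s <- node_state(w$root)
  ## above the root: remaining lineages coalesce with certainty, uniform pairs
  cf <- s[-1L] + s[1L] / 3
  cf
}

#' Exact quartet CFs by coalescent-history enumeration
#'
#' The general engine behind [expected_cf()]: computes exact expected quartet
#' concordance factors on a rooted 4-taxon level-1 network by dynamic
#' programming over lineage histories (see the methods vignette). Closed-form
#' shortcuts in the package are validated against this engine.
#'
#' @param net a 4-taxon `phynet` (its stored orientation is used; results are
#'   invariant to the choice of valid rooting)
#' @return named numeric vector of 3 CFs in canonical order (taxa sorted;
#'   `q1` joins the two smallest labels)
#' @export
enumerate_histories_cf <- function(net) {
  if (net$ntax != 4L) stop("the enumeration engine runs on 4-taxon networks")
  if (n_hybrids(net) > 0L && any(is.na(net$gamma[net$hybrid])))
    stop("all hybrid edges need gamma values")
  w <- wsn_suppress(wsn_from_phynet(net))
  cf <- engine_cf_wsn(w)
  tx <- w$taxa
  names(cf) <- c(paste0(tx[1], tx[2], "|", tx[3], tx[4]),
                 paste0(tx[1], tx[3], "|", tx[2], tx[4]),
                 paste0(tx[1], tx[4], "|", tx[2], tx[3]))
  cf
}

## ---------------------------------------------------------------------------
## Reductions on working subnetworks
## ---------------------------------------------------------------------------

## clear hybrid bookkeeping on an edge that is no longer a reticulation
wsn_clear_hybrid <- function(w, e) {
  w$hybrid[e] <- FALSE; w$gam[e] <- NA_real_
  w$major[e] <- TRUE; w$gref[e] <- NA_integer_
  w
}

## one reduction step: returns the reduced wsn or NULL if nothing applies.
## numeric = TRUE resolves transformed lengths to numbers (public reduction);
## the plan compiler uses its own symbolic path instead.
wsn_reduce_once <- function(w) {
  hr <- wsn_hybrids(w)
  below <- wsn_taxa_below(w)
  for (h in hr) {
    nh <- length(below[[h$hybrid]])
    if (h$k == 2L && nh <= 2L) {
      pe <- h$pedges
      pmaj <- pe[w$major[pe]]; pmin <- pe[!w$major[pe]]
      g <- w$gam[pmin]
      tmaj <- ifelse(is.na(w$len[pmaj]), 0, w$len[pmaj])
      tmin <- ifelse(is.na(w$len[pmin]), 0, w$len[pmin])
      w$len[pmaj] <- k2_merge_length(tmaj, tmin, g)
      w$prov[[pmaj]] <- list(list(k2 = TRUE, maj = w$prov[[pmaj]],
                                  min = w$prov[[pmin]], gref = w$gref[pmin]))
      w <- wsn_clear_hybrid(w, pmaj)
      w <- wsn_drop_edges(w, pmin)
      return(wsn_suppress(w))
    }
    if (nh == 1L && h$k == 3L) {
      ## single lineage through a triangle: both parental alternatives
      ## display the same quartet. The pendant re-attaches on the cycle tree
      ## edge at distance delta = -log(w + (1-w) e^(-tc)) from the parent
      ## whose side holds the quartet's remaining pair, w being that
      ## parent's hybrid-edge inheritance (delta <= tc; the remainder of the
      ## edge only subtends the other parent's single pendant).
      pe <- h$pedges
      tc_e <- setdiff(h$cyc_edges, pe)
      if (length(tc_e) != 1L) next
      tc <- ifelse(is.na(w$len[tc_e]), 0, w$len[tc_e])
      ## attachment taxa of each parent (off-cycle side)
      att_count <- function(p) {
        ce <- setdiff(which(w$edge[, 1L] == p), h$cyc_edges)
        if (length(ce)) length(below[[w$edge[ce[1L], 2L]]])
        else 4L - length(below[[p]])
      }
      pars <- w$edge[pe, 1L]
      cnts <- vapply(pars, att_count, 1L)
      side <- which(cnts >= 2L)
      if (length(side) != 1L) next
      p_pair <- pars[side]
      wgt <- w$gam[pe[side]]
      delta <- -log(wgt + (1 - wgt) * exp(-tc))
      H <- h$hybrid
      e_pair <- pe[side]   # reuse this row for the pair-side segment
      x <- w$edge[tc_e, 1L]; y <- w$edge[tc_e, 2L]
      if (x == p_pair) {
        w$edge[tc_e, ] <- c(x, H); w$len[tc_e] <- delta
        w$edge[e_pair, ] <- c(H, y); w$len[e_pair] <- tc - delta
      } else {
        w$edge[tc_e, ] <- c(x, H); w$len[tc_e] <- tc - delta
        w$edge[e_pair, ] <- c(H, y); w$len[e_pair] <- delta
      }
      w$prov[[tc_e]] <- list(); w$prov[[e_pair]] <- list()
      w <- wsn_clear_hybrid(w, e_pair)
      w <- wsn_drop_edges(w, setdiff(pe, e_pair))
      return(wsn_suppress(w))
    }
  }
  NULL
}

## ---------------------------------------------------------------------------
## Plan compilation: turn a 4-taxon working subnetwork into a fast closed-form
## evaluator referencing original edge ids, falling back on the engine.
## ---------------------------------------------------------------------------

compile_plan <- function(w) {
  hr <- wsn_hybrids(w)
  below <- wsn_taxa_below(w)
  if (!length(hr)) {
    sizes <- vapply(seq_len(nrow(w$edge)),
                    function(e) length(below[[w$edge[e, 2L]]]), 1L)
    int <- which(sizes == 2L)
    pairq <- pair_topology(below[[w$edge[int[1L], 2L]]][1L],
                           below[[w$edge[int[1L], 2L]]][2L])
    return(list(type = "tree", q = pairq,
                prov = unlist(w$prov[int], recursive = FALSE)))
  }
  ## single-taxon hybrid: gamma mixture over the two parental alternatives
  for (h in hr) {
    if (length(below[[h$hybrid]]) == 1L) {
      pe <- h$pedges
      pmin <- pe[!w$major[pe]]; pmaj <- pe[w$major[pe]]
      gref <- w$gref[pmin]
      drop_one <- function(e_drop, e_keep) {
        w2 <- wsn_clear_hybrid(w, e_keep)
        w2 <- wsn_drop_edges(w2, e_drop)
        wsn_suppress(w2)
      }
      return(list(type = "mix", gref = gref,
                  minor = compile_plan(drop_one(pmaj, pmin)),
                  major = compile_plan(drop_one(pmin, pmaj))))
    }
  }
  ## 2-cycle crossed by two lineages: exact merge into one edge
  for (h in hr) {
    if (h$k == 2L && length(below[[h$hybrid]]) == 2L) {
      pe <- h$pedges
      pmaj <- pe[w$major[pe]]; pmin <- pe[!w$major[pe]]
      w2 <- w
      w2$prov[[pmaj]] <- list(list(k2 = TRUE, maj = w$prov[[pmaj]],
                                   min = w$prov[[pmin]], gref = w$gref[pmin]))
      w2$len[pmaj] <- NA_real_
      w2 <- wsn_clear_hybrid(w2, pmaj)
      w2 <- wsn_drop_edges(w2, pmin)
      return(compile_plan(wsn_suppress(w2)))
    }
  }
  ## lone triangle with the quartet cherry below the hybrid: closed form
  if (length(hr) == 1L) {
    h <- hr[[1L]]
    if (h$k == 3L && length(below[[h$hybrid]]) == 2L) {
      pe <- h$pedges
      pmaj <- pe[w$major[pe]]; pmin <- pe[!w$major[pe]]
      tc_e <- setdiff(h$cyc_edges, pe)
      ce_h <- which(w$edge[, 1L] == h$hybrid)
      SH <- below[[h$hybrid]]
      return(list(type = "tri2", q = pair_topology(SH[1L], SH[2L]),
                  gref = w$gref[pmin],
                  th = w$prov[[ce_h]], tma = w$prov[[pmaj]],
                  tmi = w$prov[[pmin]], tc = w$prov[[tc_e]]))
    }
  }
  list(type = "engine", w = w)
}

## flatten pure-numeric provenance lists into index vectors (fast path)
simplify_plan <- function(plan) {
  sp <- function(prov) {
    if (is.numeric(prov)) return(prov)
    if (all(vapply(prov, is.numeric, TRUE))) return(unlist(prov))
    prov
  }
  switch(plan$type,
    tree = { plan$prov <- sp(plan$prov); plan },
    mix = {
      plan$minor <- simplify_plan(plan$minor)
      plan$major <- simplify_plan(plan$major)
      plan
    },
    tri2 = {
      plan$th <- sp(plan$th); plan$tma <- sp(plan$tma)
      plan$tmi <- sp(plan$tmi); plan$tc <- sp(plan$tc)
      plan
    },
    plan)
}

## resolve a provenance list into a length, given lens/gams by original id
resolve_len <- function(prov, lens, gams) {
  if (is.numeric(prov)) return(sum(lens[prov]))
  s <- 0
  for (p in prov) {
    if (is.numeric(p)) {
      l <- lens[p]
      s <- s + sum(ifelse(is.na(l), 0, l))
    } else if (!is.null(p$k2)) {
      s <- s + k2_merge_length(resolve_len(p$maj, lens, gams),
                               resolve_len(p$min, lens, gams), gams[p$gref])
    } else if (!is.null(p$tri)) {
      g <- gams[p$gref]
      s <- s - log((1 - g) + g * exp(-resolve_len(p$tc, lens, gams)))
    } else stop("unknown provenance token")
  }
  s
}

eval_plan <- function(plan, lens, gams) {
  switch(plan$type,
    tree = {
      m <- exp(-resolve_len(plan$prov, lens, gams)) / 3
      out <- c(m, m, m); out[plan$q] <- 1 - 2 * m
      out
    },
    mix = {
      g <- gams[plan$gref]
      g * eval_plan(plan$minor, lens, gams) +
        (1 - g) * eval_plan(plan$major, lens, gams)
    },
    tri2 = {
      v <- cf_triangle2(resolve_len(plan$th, lens, gams),
                        resolve_len(plan$tma, lens, gams),
                        resolve_len(plan$tmi, lens, gams),
                        resolve_len(plan$tc, lens, gams),
                        gams[plan$gref])
      out <- rep(v[2L], 3L); out[plan$q] <- v[1L]
      out
    },
    engine = {
      w <- plan$w
      w$len <- vapply(w$prov, resolve_len, 1, lens = lens, gams = gams)
      w$gam <- ifelse(is.na(w$gref), NA_real_, gams[w$gref])
      engine_cf_wsn(w)
    },
    stop("unknown plan type"))
}

#' Expected quartet CFs on a network
#'
#' Extracts the 4-taxon subnetwork induced by `taxa` (suppressing other
#' leaves, fusing paths and dropping invisible reticulations), reduces it, and
#' evaluates the expected concordance factors with a closed form or the
#' enumeration engine. The result does not depend on where the network could
#' be rooted.
#'
#' @param net a level-1 `phynet` with branch lengths (coalescent units) and
#'   gamma values on hybrid edges
#' @param taxa 4 leaf labels
#' @param default_length value substituted for missing internal branch
#'   lengths (default 0; external edges never matter)
#' @return named numeric vector of 3 CFs, canonical order (sorted taxa; `q1`
#'   joins the two smallest labels); attribute `"taxa"` carries the sorted
#'   labels
#' @export
expected_cf <- function(net, taxa, default_length = 0) {
  w <- extract_subnet(net, taxa)
  plan <- compile_plan(w)
  lens <- ifelse(is.na(net$length), default_length, net$length)
  cf <- eval_plan(plan, lens, net$gamma)
  tx <- sort(taxa)
  names(cf) <- c(paste0(tx[1], tx[2], "|", tx[3], tx[4]),
                 paste0(tx[1], tx[3], "|", tx[2], tx[4]),
                 paste0(tx[1], tx[4], "|", tx[2], tx[3]))
  attr(cf, "taxa") <- tx
  cf
}
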