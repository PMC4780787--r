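## ---------------------------------------------------------------------------
## Identifiability-aware parameterization of a fixed topology.
##
## Search-space rules: 2-cycles and triangles with any single-taxon subtree
## are excluded entirely. Within the admitted classes:
##  - good triangle: the cycle tree edge joining the two hybrid parents is
##    pinned to 0; the remaining parameters are then identifiable;
##  - bad diamond I: (gamma, t_minor, t_major) of the cycle are replaced by
##    the two identifiable products z1 = gamma (1 - e^(-t_minor)),
##    z2 = (1 - gamma)(1 - e^(-t_major));
##  - bad diamond II: the hybrid node's child edge is pinned to 0.
## External edge lengths are never estimated (one individual per taxon).
## ---------------------------------------------------------------------------

#' Identifiability constraints and free-parameter map
#'
#' Applies the class-specific constraints above to a level-1 network and
#' returns the constrained network together with a map of the free
#' parameters the optimizer may vary.
#'
#' @param net a valid level-1 `phynet` whose cycle classes are all in the
#'   searchable space (no 2-cycles, no triangles with single-taxon subtrees)
#' @param tmax upper bound for branch lengths in coalescent units
#' @return list with `net` (constraints applied) and `map` (list of free
#'   parameters; entries of kind `"length"`, `"gamma"` or `"badI"`)
#' @export
apply_identifiability_constraints <- function(net, tmax = 10) {
  ## a degree-2 root splits one edge into two, of which only the sum is
  ## identifiable: normalize to the fused (unrooted-style) representation
  net <- net_unroot(net)
  hc <- hybrid_cycles(net)
  cls <- vapply(hc, function(x) x$class, "")
  bad <- cls %in% c("cycle2", "triangle_other")
  if (any(bad))
    stop("reticulation class(es) outside the searchable space: ",
         paste(cls[bad], collapse = ", "))
  pinned <- integer(0)
  fixed <- integer(0)
  map <- list()
  for (x in hc) {
    ## hybrid edges above a single-taxon subtree carry at most one lineage:
    ## their lengths fuse into an external edge and are never estimated
    if (x$ns[1L] == 1L) {
      net$length[c(x$major_edge, x$minor_edge)] <- 0
      fixed <- c(fixed, x$major_edge, x$minor_edge)
    }
    if (x$class == "triangle_good") {
      tc <- setdiff(x$cycle_edges, c(x$major_edge, x$minor_edge))
      net$length[tc] <- 0
      pinned <- c(pinned, tc)
    } else if (x$class == "diamond_bad_II") {
      ce <- which(net$edge[, 1L] == x$hybrid)
      net$length[ce] <- 0
      pinned <- c(pinned, ce)
    } else if (x$class == "diamond_bad_I") {
      ## gamma and the two cycle tree edges collapse onto two products:
      ## z1 = gamma (1 - e^-t_minorside), z2 = (1-gamma)(1 - e^-t_majorside)
      tre <- setdiff(x$cycle_edges, c(x$major_edge, x$minor_edge))
      pmin <- net$edge[x$minor_edge, 1L]; pmaj <- net$edge[x$major_edge, 1L]
      tmin_side <- tre[net$edge[tre, 1L] == pmin | net$edge[tre, 2L] == pmin][1L]
      tmaj_side <- tre[net$edge[tre, 1L] == pmaj | net$edge[tre, 2L] == pmaj][1L]
      fixed <- c(fixed, tmin_side, tmaj_side)
      map[[length(map) + 1L]] <-
        list(kind = "badI", minor = x$minor_edge, major = x$major_edge,
             tmin_side = tmin_side, tmaj_side = tmaj_side,
             lower = c(0, 0), upper = c(1, 1))
    }
    if (x$class != "diamond_bad_I") {
      map[[length(map) + 1L]] <-
        list(kind = "gamma", minor = x$minor_edge, major = x$major_edge,
             lower = 0, upper = 1)
    }
  }
  internal <- net$edge[, 2L] > net$ntax
  free_len <- which(internal & !(seq_len(nrow(net$edge)) %in%
                                   c(pinned, fixed)))
  for (e in free_len) {
    map[[length(map) + 1L]] <-
      list(kind = "length", edge = e, lower = 0, upper = tmax)
  }
  list(net = net, map = map)
}

## number of scalar parameters in a map
map_npar <- function(map) sum(vapply(map, function(m)
  if (m$kind == "badI") 2L else 1L, 1L))

## current parameter values from a network (NA lengths become `default`)
map_get <- function(net, map, default = 1) {
  out <- numeric(0)
  for (m in map) {
    out <- c(out, switch(m$kind,
      length = { v <- net$length[m$edge]; if (is.na(v)) default else v },
      gamma = { v <- net$gamma[m$minor]; if (is.na(v)) 0.1 else v },
      badI = {
        g <- net$gamma[m$minor]; if (is.na(g)) g <- 0.1
        t0 <- net$length[m$tmin_side]; if (is.na(t0)) t0 <- default
        t1 <- net$length[m$tmaj_side]; if (is.na(t1)) t1 <- default
        c(g * (1 - exp(-t0)), (1 - g) * (1 - exp(-t1)))
      }))
  }
  out
}

## write parameter vector into lens/gams vectors (indexed by edge);
## returns list(lens, gams)
map_set <- function(lens, gams, map, x) {
  i <- 1L
  for (m in map) {
    if (m$kind == "length") {
      lens[m$edge] <- x[i]; i <- i + 1L
    } else if (m$kind == "gamma") {
      gams[m$minor] <- x[i]; gams[m$major] <- 1 - x[i]; i <- i + 1L
    } else {
      z1 <- x[i]; z2 <- x[i + 1L]; i <- i + 2L
      s <- z1 + z2
      if (s > 1 - 1e-9) { z1 <- z1 * (1 - 1e-9) / s; z2 <- z2 * (1 - 1e-9) / s }
      g <- (z1 + 1 - z2) / 2
      gams[m$minor] <- g; gams[m$major] <- 1 - g
      lens[m$tmin_side] <- -log(1 - z1 / g)
      lens[m$tmaj_side] <- -log(1 - z2 / (1 - g))
    }
  }
  list(lens = lens, gams = gams)
}

map_bounds <- function(map) {
  lo <- unlist(lapply(map, function(m) m$lower))
  hi <- unlist(lapply(map, function(m) m$upper))
  list(lower = lo, upper = hi)
}
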