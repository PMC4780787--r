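## ---------------------------------------------------------------------------
## Network pseudolikelihood: product over 4-taxon sets of multinomial
## likelihoods of the observed quartet counts under the expected CFs.
## ---------------------------------------------------------------------------

## compile evaluation plans for the table's 4-taxon sets on a fixed topology
compile_table_plans <- function(net, table) {
  miss <- setdiff(unique(as.vector(as.matrix(table[, paste0("taxon", 1:4)]))),
                  net$labels)
  if (length(miss))
    stop("table contains taxa absent from the network: ",
         paste(miss, collapse = ", "))
  lapply(seq_len(nrow(table)), function(i) {
    tx <- sort(as.character(table[i, paste0("taxon", 1:4)]))
    simplify_plan(compile_plan(extract_subnet(net, tx)))
  })
}

## quartet count matrix from a cf_table: CF * ngenes rounded to integers
## (fractional CFs kept as weights when ngenes is missing or weighting is
## "fractional")
table_counts <- function(table, weighting = c("counts", "fractional")) {
  weighting <- match.arg(weighting)
  cf <- as.matrix(table[, cf_cols])
  ng <- table$ngenes
  if (weighting == "fractional" || is.null(ng) || all(is.na(ng)))
    return(cf * ifelse(is.na(ng), 1, ng))
  round(cf * ifelse(is.na(ng), 1, ng))
}

eval_table_plans <- function(plans, lens, gams) {
  t(vapply(plans, eval_plan, numeric(3L), lens = lens, gams = gams))
}

## 3 x n variant without the transpose (hot path in the optimizer)
eval_table_plans3 <- function(plans, lens, gams) {
  vapply(plans, eval_plan, numeric(3L), lens = lens, gams = gams)
}

#' Log pseudolikelihood of a network given quartet CFs
#'
#' Sum over 4-taxon sets of the multinomial log likelihood of the observed
#' quartet counts under the network's expected CFs (multinomial coefficient
#' omitted; expected CFs clamped below at 1e-12). Counts are the tabled CFs
#' scaled by `ngenes` and rounded.
#'
#' @param net a level-1 `phynet` with branch lengths and gammas set
#' @param table a `cf_table`
#' @param weighting `"counts"` (CF x ngenes rounded) or `"fractional"`
#' @param default_length value substituted for missing internal lengths
#' @return the log pseudolikelihood; attribute `"by_set"` carries each
#'   4-taxon set's contribution
#' @export
log_pseudolik <- function(net, table, weighting = "counts",
                          default_length = 1) {
  plans <- compile_table_plans(net, table)
  X <- table_counts(table, weighting)
  lens <- ifelse(is.na(net$length), default_length, net$length)
  cf <- eval_table_plans(plans, lens, net$gamma)
  per <- rowSums(X * log(pmax(cf, 1e-12)))
  out <- sum(per)
  attr(out, "by_set") <- per
  out
}

#' Initialize branch lengths from average concordance factors
#'
#' For each internal tree edge, the observed CFs of the quartets that span
#' exactly that edge (one taxon from each of the four subtrees meeting at its
#' endpoints) are averaged and transformed to coalescent units. The default
#' transform is t = -log(1 - 3/2 CF); `formula = "consistent"` uses the exact
#' inversion t = -log(3/2 (1 - CF)) of the species-tree CF formula instead.
#' Results are clamped to [1e-10, tmax]; uncovered edges get 1.
#'
#' @param net a `phynet` (tree or network; hybrid edge lengths and edges
#'   without covering quartets are left at their current values or 1)
#' @param table a `cf_table`
#' @param formula `"printed"` (default) or `"consistent"`
#' @param tmax clamp ceiling
#' @return `net` with initialized internal tree-edge lengths
#' @export
init_branch_lengths <- function(net, table, formula = c("printed", "consistent"),
                                tmax = 10) {
  formula <- match.arg(formula)
  net <- net_unroot(net)
  mt <- major_tree(net)
  key <- apply(as.matrix(table[, paste0("taxon", 1:4)]), 1L, function(r)
    paste(sort(r), collapse = "|"))
  cf <- as.matrix(table[, cf_cols])
  ## subtree taxa hanging at each node of the major tree, per incident edge
  mt_cl <- edge_clusters(mt)
  net_cl <- edge_clusters(net)
  inc <- incident_edges(mt)
  for (e in seq_len(nrow(net$edge))) {
    if (net$hybrid[e] || net$edge[e, 2L] <= net$ntax) next
    ## find matching major-tree edge by child cluster
    me <- which(vapply(mt_cl, identical, TRUE, y = net_cl[[e]]))
    if (!length(me)) next
    me <- me[[1L]]
    u <- mt$edge[me, 1L]; v <- mt$edge[me, 2L]
    sides_u <- lapply(setdiff(inc[[u]], me), function(e2)
      subtree_taxa(mt, setdiff(mt$edge[e2, ], u), e2))
    sides_v <- lapply(setdiff(inc[[v]], me), function(e2)
      subtree_taxa(mt, setdiff(mt$edge[e2, ], v), e2))
    if (length(sides_u) < 2L || length(sides_v) < 2L) next
    vals <- numeric(0)
    ## average observed CF of the split joining the two v-side groups
    for (a in sides_u[[1L]]) for (b in sides_u[[2L]])
      for (cc in sides_v[[1L]]) for (d in sides_v[[2L]]) {
        tx <- sort(mt$labels[c(a, b, cc, d)])
        i <- match(paste(tx, collapse = "|"), key)
        if (is.na(i)) next
        pr <- c(mt$labels[a], mt$labels[b])
        qq <- pair_topology(match(pr[1], tx), match(pr[2], tx))
        vals <- c(vals, cf[i, qq])
      }
    if (!length(vals)) next
    cfbar <- mean(vals)
    t <- if (formula == "printed") {
      if (cfbar >= 2 / 3) tmax else -log(1 - 1.5 * cfbar)
    } else {
      if (cfbar >= 1) tmax else -log(1.5 * (1 - cfbar))
    }
    net$length[e] <- min(max(t, 1e-10), tmax)
  }
  ## remaining missing internal lengths default to 1
  internal <- net$edge[, 2L] > net$ntax
  net$length[internal & is.na(net$length)] <- 1
  net
}

#' Optimize branch lengths and inheritance probabilities
#'
#' Maximizes the log pseudolikelihood over the free parameters of a fixed
#' topology (see [apply_identifiability_constraints()]) with the
#' derivative-free bound-constrained BOBYQA algorithm, restarting from a few
#' jittered points. Parameters sitting at their boundary after optimization
#' (gamma near 0 or 1, branch lengths near 0) are flagged.
#'
#' @param net a searchable level-1 `phynet`
#' @param table a `cf_table`
#' @param weighting see [log_pseudolik()]
#' @param tmax branch-length upper bound (coalescent units)
#' @param gamma_tol boundary tolerance for inheritance probabilities
#' @param t_tol boundary tolerance for branch lengths
#' @param restarts number of additional jittered starts
#' @param rel_tol relative score tolerance passed to the optimizer
#' @param seed optional seed for the jitter
#' @return list with `net` (fitted parameters written back), `score` (log
#'   pseudolikelihood), `par`, `map`, `flags` (list `gamma0`, `gamma1`,
#'   `tzero` of edge indices at boundaries), `convergence`, `evals`
#' @export
optimize_parameters <- function(net, table, weighting = "counts", tmax = 10,
                                gamma_tol = 1e-4, t_tol = 1e-4,
                                restarts = 3, rel_tol = 1e-6, rhoend = 1e-5,
                                seed = NULL) {
  con <- apply_identifiability_constraints(net, tmax = tmax)
  net <- con$net; map <- con$map
  plans <- compile_table_plans(net, table)
  X <- table_counts(table, weighting)
  lens0 <- ifelse(is.na(net$length), 1, net$length)
  gams0 <- ifelse(net$hybrid & is.na(net$gamma), 0.1, net$gamma)
  npar <- map_npar(map)
  Xt <- t(X)
  objective <- function(x) {
    sg <- map_set(lens0, gams0, map, x)
    cf <- eval_table_plans3(plans, sg$lens, sg$gams)
    -sum(Xt * log(pmax(cf, 1e-12)))
  }
  if (npar == 0L) {
    val <- -objective(numeric(0))
    return(list(net = net, score = val, par = numeric(0), map = map,
                flags = list(gamma0 = integer(0), gamma1 = integer(0),
                             tzero = integer(0)),
                convergence = 0L, evals = 1L))
  }
  bb <- map_bounds(map)
  x0 <- pmin(pmax(map_get(net, map), bb$lower), bb$upper)
  if (!is.null(seed)) set.seed(seed)
  starts <- list(x0)
  for (r in seq_len(restarts)) {
    xj <- x0 + stats::rnorm(npar, 0, 0.2 * (bb$upper - bb$lower + 1e-9))
    starts[[r + 1L]] <- pmin(pmax(xj, bb$lower), bb$upper)
  }
  best <- NULL
  evals <- 0L
  for (s in starts) {
    fit <- tryCatch(
      minqa::bobyqa(s, objective, lower = bb$lower, upper = bb$upper,
                    control = list(rhobeg = 0.2, rhoend = rhoend,
                                   maxfun = 2000L * npar)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$fval)) next
    evals <- evals + fit$feval
    if (is.null(best) || fit$fval < best$fval) best <- fit
  }
  if (is.null(best)) stop("pseudolikelihood optimization failed from all starts")
  x <- pmin(pmax(best$par, bb$lower), bb$upper)
  sg <- map_set(lens0, gams0, map, x)
  net$length <- ifelse(is.na(net$length) & net$edge[, 2L] <= net$ntax,
                       NA_real_, sg$lens)
  net$gamma[net$hybrid] <- sg$gams[net$hybrid]
  ## re-designate the major edge where the fitted minor gamma exceeds 0.5
  for (m in map) {
    if (m$kind %in% c("gamma", "badI") && !is.na(net$gamma[m$minor]) &&
        net$gamma[m$minor] > 0.5) {
      net$major[m$minor] <- TRUE
      net$major[m$major] <- FALSE
    }
  }
  ## boundary flags
  g0 <- integer(0); g1 <- integer(0); tz <- integer(0)
  for (m in map) {
    if (m$kind == "gamma" || m$kind == "badI") {
      g <- net$gamma[m$minor]
      if (g < gamma_tol) g0 <- c(g0, m$minor)
      if (g > 1 - gamma_tol) g1 <- c(g1, m$minor)
    } else if (m$kind == "length") {
      if (net$length[m$edge] < t_tol) tz <- c(tz, m$edge)
    }
  }
  list(net = net, score = -best$fval, par = x, map = map,
       flags = list(gamma0 = g0, gamma1 = g1, tzero = tz),
       convergence = best$ierr, evals = evals)
}

#' Expected CF table under a network
#'
#' Tabulates [expected_cf()] for a collection of 4-taxon sets: the table a
#' practitioner would observe from infinitely many error-free genes.
#'
#' @param net a level-1 `phynet` with lengths and gammas
#' @param sets 4-taxon sets (default: all)
#' @param ngenes nominal gene count stored in the table
#' @return a `cf_table`
#' @export
expected_cf_table <- function(net, sets = NULL, ngenes = 10000L) {
  if (is.null(sets)) sets <- quartet_sets(net$labels)
  sets <- t(apply(sets, 1L, sort))
  cf <- t(apply(sets, 1L, function(tx) as.numeric(expected_cf(net, tx))))
  out <- data.frame(taxon1 = sets[, 1L], taxon2 = sets[, 2L],
                    taxon3 = sets[, 3L], taxon4 = sets[, 4L],
                    CF12_34 = cf[, 1L], CF13_24 = cf[, 2L],
                    CF14_23 = cf[, 3L], ngenes = ngenes,
                    stringsAsFactors = FALSE)
  class(out) <- c("cf_table", "data.frame")
  out
}
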