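## ---------------------------------------------------------------------------
## snaq(): the fitting front-end. Returns a classed object with the usual
## modelling verbs (print, summary, coef, logLik, fitted, residuals,
## simulate, plot).
## ---------------------------------------------------------------------------

#' Fit a species network by maximum pseudolikelihood
#'
#' Estimates a semi-directed level-1 phylogenetic network — topology, branch
#' lengths in coalescent units and inheritance probabilities — from a table
#' of quartet concordance factors, by hill-climbing over network space with
#' at most `h_max` reticulations (see [snaq_search()] for the search and
#' [log_pseudolik()] for the criterion).
#'
#' @param cf a `cf_table` (from [count_quartets()], [read_cf_table()] or
#'   [simulate_cf_table()])
#' @param start starting topology: a `phylo` tree, a `phynet`, or a Newick
#'   string
#' @param h_max maximum number of hybridizations (default 0: species tree)
#' @param runs number of independent search runs
#' @param seed integer seed driving all randomness
#' @param ... further arguments passed to [snaq_search()]
#' @return an object of class `"snaq"`: a list with elements `network`
#'   (the `phynet` estimate), `loglik`, `h`, `cf`, `trace`, `runs`, `call`
#' @examples
#' net <- parse_enewick(
#'   "(((a:1,b:1):1,(c:0.5)#H1:1::0.7):1.2,(#H1:1::0.3,d:1):0.8);")
#' tab <- expected_cf_table(net, ngenes = 1000)
#' fit <- snaq(tab, major_tree(net), h_max = 0, runs = 1, seed = 1)
#' fit
#' @export
snaq <- function(cf, start, h_max = 0L, runs = 10L, seed = 42L, ...) {
  cl <- match.call()
  if (is.character(start)) start <- parse_enewick(start)
  res <- snaq_search(cf, start, h_max = h_max, runs = runs, seed = seed, ...)
  structure(list(network = res$net, loglik = res$score, h = res$h,
                 h_max = h_max, cf = cf, trace = res$trace,
                 runs = res$runs, seed = seed, call = cl),
            class = "snaq")
}

#' @export
print.snaq <- function(x, ...) {
  cat("Maximum-pseudolikelihood species network\n")
  cat(sprintf("  taxa: %d   hybridizations: %d (h_max = %d)\n",
              x$network$ntax, x$h, x$h_max))
  cat(sprintf("  log pseudolikelihood: %.3f   (%d run%s)\n", x$loglik,
              length(x$runs), if (length(x$runs) > 1) "s" else ""))
  cat("  ", write_enewick(x$network), "\n", sep = "")
  invisible(x)
}

#' @export
summary.snaq <- function(object, ...) {
  co <- coef(object)
  run_scores <- vapply(object$runs, function(r) r$score, 1)
  out <- list(network = object$network, coef = co, loglik = object$loglik,
              h = object$h, run_scores = run_scores,
              accepted = sum(object$trace$accepted))
  class(out) <- "summary.snaq"
  out
}

#' @export
print.summary.snaq <- function(x, ...) {
  cat("Species network fit (maximum pseudolikelihood)\n\n")
  cat(write_enewick(x$network), "\n\n")
  cat("Parameters:\n")
  print(x$coef, digits = 4)
  cat(sprintf("\nlog pseudolikelihood: %.3f across %d runs (best of %s)\n",
              x$loglik, length(x$run_scores),
              paste(sprintf("%.2f", x$run_scores), collapse = ", ")))
  invisible(x)
}

#' @export
coef.snaq <- function(object, ...) {
  net <- object$network
  cl <- edge_clusters(net)
  data.frame(
    edge = seq_len(nrow(net$edge)),
    cluster = vapply(cl, paste, "", collapse = ","),
    type = ifelse(!net$hybrid, "tree", ifelse(net$major, "hybrid-major",
                                              "hybrid-minor")),
    length = net$length,
    gamma = net$gamma)
}

#' @export
logLik.snaq <- function(object, ...) {
  structure(object$loglik, df = map_npar(
    apply_identifiability_constraints(object$network)$map),
    class = "logLik")
}

#' @export
fitted.snaq <- function(object, ...) {
  tab <- object$cf
  for (i in seq_len(nrow(tab))) {
    tx <- sort(as.character(tab[i, paste0("taxon", 1:4)]))
    tab[i, cf_cols] <- as.numeric(expected_cf(object$network, tx,
                                              default_length = 0))
  }
  tab
}

#' @export
residuals.snaq <- function(object, ...) {
  obs <- as.matrix(object$cf[, cf_cols])
  exp <- as.matrix(fitted(object)[, cf_cols])
  res <- obs - exp
  cbind(object$cf[, paste0("taxon", 1:4)], res)
}

#' @export
simulate.snaq <- function(object, nsim = 1, seed = NULL, ngenes = 1000, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(i)
    simulate_gene_trees(object$network, ngenes))
  if (nsim == 1) out[[1L]] else out
}

#' @export
plot.snaq <- function(x, ...) {
  plot_phynet(x$network, ...)
  invisible(x)
}

#' Plot a semi-directed network
#'
#' Draws the major tree with ape and overlays the minor hybrid edges as
#' dashed arrows annotated with their inheritance probabilities.
#'
#' @param net a `phynet`
#' @param ... passed to [ape::plot.phylo()]
#' @export
plot_phynet <- function(net, ...) {
  mt <- major_tree(net)
  tr <- as_phylo(mt)
  tr$edge.length[is.na(tr$edge.length)] <- 0
  ape::plot.phylo(tr, ...)
  if (!any(net$hybrid)) return(invisible(net))
  last <- graphics::par("usr")
  lp <- ape::node.depth.edgelength(tr)
  yy <- ape::node.height(tr)
  ## locate each minor edge's endpoints by matching clusters to tree nodes
  tr_cl <- lapply(seq_len(ape::Ntip(tr) + tr$Nnode), function(v) {
    if (v <= ape::Ntip(tr)) tr$tip.label[v]
    else sort(ape::extract.clade(tr, v)$tip.label)
  })
  for (e in which(net$hybrid & !net$major)) {
    from_cl <- sort(net$labels[subtree_below(net, net$edge[e, 1L])])
    to_cl <- sort(net$labels[subtree_below(net, net$edge[e, 2L])])
    f <- which(vapply(tr_cl, identical, TRUE, y = from_cl))[1L]
    t <- which(vapply(tr_cl, identical, TRUE, y = to_cl))[1L]
    if (is.na(f) || is.na(t)) next
    graphics::arrows(lp[f], yy[f], lp[t], yy[t], lty = 2, col = "steelblue",
                     length = 0.08)
    graphics::text((lp[f] + lp[t]) / 2, (yy[f] + yy[t]) / 2,
                   sprintf("%.2f", net$gamma[e]), col = "steelblue",
                   cex = 0.8, pos = 3)
  }
  invisible(net)
}
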