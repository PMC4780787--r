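## ---------------------------------------------------------------------------
## Observed quartet concordance factors: 4-taxon set enumeration, counting
## quartets in gene trees, CSV I/O (TICR-compatible columns), the
## concordance-prior helper and credibility-interval bootstrap resampling.
##
## A cf_table is a data frame of class "cf_table" with columns
##   taxon1..taxon4 (sorted within each row), CF12_34, CF13_24, CF14_23,
##   ngenes, and optionally CF*_lo / CF*_hi credibility bounds.
## ---------------------------------------------------------------------------

cf_cols <- c("CF12_34", "CF13_24", "CF14_23")

#' Enumerate or sample 4-taxon sets
#'
#' @param taxa character vector of taxon labels (4 or more)
#' @param mode `"all"` for all choose(n, 4) sets, `"random"` for `m` distinct
#'   sets sampled reproducibly under `seed`
#' @param m number of sets when `mode = "random"`
#' @param seed integer seed for reproducible sampling
#' @return a character matrix with 4 columns, rows sorted canonically; the
#'   attribute `"coverage"` counts how many sets contain each taxon
#' @export
quartet_sets <- function(taxa, mode = c("all", "random"), m = NULL,
                         seed = NULL) {
  mode <- match.arg(mode)
  taxa <- sort(unique(as.character(taxa)))
  n <- length(taxa)
  if (n < 4L) stop("need at least 4 taxa")
  total <- choose(n, 4)
  if (mode == "all") {
    sets <- t(combn(taxa, 4L))
  } else {
    if (is.null(m)) stop("m is required for random mode")
    if (m > total) stop("m exceeds the number of 4-taxon sets (", total, ")")
    if (!is.null(seed)) set.seed(seed)
    idx <- sort(sample.int(total, m))
    ## unrank combinations lazily
    sets <- t(combn(taxa, 4L))[idx, , drop = FALSE]
  }
  cov <- table(factor(as.vector(sets), levels = taxa))
  attr(sets, "coverage") <- setNames(as.integer(cov), taxa)
  sets
}

## bipartitions of a gene tree as a logical matrix over `taxa` (global order);
## returns list(bip = B x n logical, present = logical n, support = numeric B)
tree_bipartitions <- function(tree, taxa) {
  n <- length(taxa)
  idx <- match(tree$tip.label, taxa)
  if (anyNA(idx)) stop("gene tree has labels outside the taxon set: ",
                       paste(tree$tip.label[is.na(idx)], collapse = ", "))
  if (anyDuplicated(tree$tip.label)) stop("gene tree with duplicate labels")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  below <- matrix(FALSE, nnode, n)
  below[cbind(seq_len(ntip), idx)] <- TRUE
  ## accumulate clades in postorder over edges (children before parents)
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    below[p, ] <- below[p, ] | below[ch, ]
  }
  internal <- (ntip + 1L):nnode
  sup <- rep(NA_real_, length(internal))
  if (!is.null(tree$node.label)) {
    sl <- suppressWarnings(as.numeric(tree$node.label))
    sup[seq_along(sl)] <- sl
  }
  list(bip = below[internal, , drop = FALSE], present_taxa = idx,
       support = sup)
}

#' Count displayed quartets in a gene-tree collection
#'
#' For every 4-taxon set, counts the genes whose tree, restricted to those 4
#' taxa, displays each of the three quartets. Genes missing any of the 4 taxa
#' or unresolved on them do not count. When `support_threshold` is given,
#' a gene's vote for a set is kept only if the support of the internal branch
#' displaying the quartet (the maximum over the branches of the inducing
#' path) reaches the threshold; branches without support values always pass.
#'
#' @param genetrees a `multiPhylo` (or list of `phylo`) of possibly
#'   incomplete, possibly rooted gene trees; rooted trees are treated as
#'   unrooted
#' @param sets 4-taxon sets (matrix as from [quartet_sets()]); default: all
#'   sets over the union of tip labels
#' @param support_threshold optional numeric threshold (same scale as the
#'   trees' node labels, e.g. 70 for bootstrap percentages)
#' @return a `cf_table`; sets with no informative gene are omitted
#' @export
count_quartets <- function(genetrees, sets = NULL, support_threshold = NULL) {
  if (inherits(genetrees, "phylo")) genetrees <- list(genetrees)
  if (!length(genetrees)) stop("empty gene-tree list")
  for (tr in genetrees)
    if (anyDuplicated(tr$tip.label)) stop("gene tree with duplicate labels")
  taxa <- sort(unique(unlist(lapply(genetrees, function(t) t$tip.label))))
  if (is.null(sets)) sets <- quartet_sets(taxa)
  sets <- t(apply(sets, 1L, sort))
  m <- nrow(sets)
  sidx <- matrix(match(sets, taxa), m, 4L)
  X <- matrix(0L, m, 3L)
  for (tr in genetrees) {
    tb <- tree_bipartitions(tr, taxa)
    pres <- logical(length(taxa)); pres[tb$present_taxa] <- TRUE
    B <- tb$bip
    if (!nrow(B)) next
    ## membership of each set taxon in each bipartition: B x m logicals
    in1 <- B[, sidx[, 1L], drop = FALSE]; in2 <- B[, sidx[, 2L], drop = FALSE]
    in3 <- B[, sidx[, 3L], drop = FALSE]; in4 <- B[, sidx[, 4L], drop = FALSE]
    cnt <- in1 + in2 + in3 + in4
    patt <- (in1 * 8L + in2 * 4L + in3 * 2L + in4) * (cnt == 2L)
    ## pattern -> split: {12|34}: 12 or 3; {13|24}: 10 or 5; {14|23}: 9 or 6
    ok_set <- pres[sidx[, 1L]] & pres[sidx[, 2L]] & pres[sidx[, 3L]] & pres[sidx[, 4L]]
    for (s in which(ok_set)) {
      p <- patt[, s]
      q <- if (any(p == 12L | p == 3L)) 1L
      else if (any(p == 10L | p == 5L)) 2L
      else if (any(p == 9L | p == 6L)) 3L
      else 0L
      if (q == 0L) next
      if (!is.null(support_threshold)) {
        rows <- which(p %in% switch(q, c(12L, 3L), c(10L, 5L), c(9L, 6L)))
        sup <- tb$support[rows]
        if (!all(is.na(sup)) && max(sup, na.rm = TRUE) < support_threshold)
          next
      }
      X[s, q] <- X[s, q] + 1L
    }
  }
  ng <- rowSums(X)
  keep <- ng > 0L
  out <- data.frame(taxon1 = sets[keep, 1L], taxon2 = sets[keep, 2L],
                    taxon3 = sets[keep, 3L], taxon4 = sets[keep, 4L],
                    CF12_34 = X[keep, 1L] / ng[keep],
                    CF13_24 = X[keep, 2L] / ng[keep],
                    CF14_23 = X[keep, 3L] / ng[keep],
                    ngenes = ng[keep], stringsAsFactors = FALSE)
  class(out) <- c("cf_table", "data.frame")
  out
}

#' Read / write a quartet CF table
#'
#' CSV with columns `taxon1..taxon4`, `CF12_34`, `CF13_24`, `CF14_23`,
#' optionally `ngenes` and per-CF 95% credibility bounds `*_lo`, `*_hi`.
#' CF triples off 1 by at most 1e-6 are renormalized; larger discrepancies
#' are an error.
#'
#' @param path file path
#' @return a `cf_table`
#' @export
read_cf_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(paste0("taxon", 1:4), cf_cols)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  validate_cf_table(df)
}

#' @rdname read_cf_table
#' @param table a `cf_table`
#' @export
write_cf_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

validate_cf_table <- function(df) {
  cf <- as.matrix(df[, cf_cols])
  s <- rowSums(cf)
  bad <- abs(s - 1) > 1e-6
  if (any(bad))
    stop("CFs do not sum to 1 (off by ",
         format(max(abs(s - 1))), ") in row(s) ",
         paste(head(which(bad), 5L), collapse = ", "))
  df[, cf_cols] <- cf / s
  key <- apply(df[, paste0("taxon", 1:4)], 1L, function(r)
    paste(sort(r), collapse = "|"))
  if (anyDuplicated(key)) stop("duplicate 4-taxon sets in table")
  lo <- paste0(cf_cols, "_lo"); hi <- paste0(cf_cols, "_hi")
  if (all(c(lo, hi) %in% names(df))) {
    for (i in 1:3) {
      if (any(df[[lo[i]]] > df[, cf_cols[i]] + 1e-9 |
                df[[hi[i]]] < df[, cf_cols[i]] - 1e-9))
        stop("credibility bounds violate lo <= CF <= hi")
    }
  }
  if (is.null(df$ngenes)) df$ngenes <- NA_real_
  class(df) <- c("cf_table", "data.frame")
  df
}

#' Prior probability that two genes share a quartet tree
#'
#' Under the concordance prior with concentration parameter `alpha`, two
#' genes share the same quartet tree with prior probability
#' (1 + alpha/3) / (1 + alpha): 1 at alpha = 0 (full concordance) and 1/3 as
#' alpha grows (gene trees matching by chance).
#'
#' @param alpha concentration parameter, >= 0 (`Inf` allowed)
#' @return a probability
#' @export
concordance_prior <- function(alpha) {
  if (is.na(alpha) || alpha < 0) stop("alpha must be >= 0")
  if (is.infinite(alpha)) return(1 / 3)
  (1 + alpha / 3) / (1 + alpha)
}

#' Resample a CF table from credibility intervals
#'
#' Draws each CF uniformly and independently from its 95% credibility
#' interval, then renormalizes the three CFs of each set to sum to 1
#' (a conservative parametric bootstrap of the CF estimates).
#'
#' @param table a `cf_table` with `*_lo` / `*_hi` bounds on every row
#' @param seed optional integer seed
#' @return a `cf_table` with the same sets and bounds, resampled CFs
#' @export
resample_cf_table <- function(table, seed = NULL) {
  lo <- paste0(cf_cols, "_lo"); hi <- paste0(cf_cols, "_hi")
  if (!all(c(lo, hi) %in% names(table)))
    stop("credibility bounds (*_lo, *_hi) are required for resampling")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(table)
  draws <- vapply(1:3, function(i)
    stats::runif(n, table[[lo[i]]], table[[hi[i]]]), numeric(n))
  draws <- matrix(draws, n, 3L)
  table[, cf_cols] <- draws / rowSums(draws)
  table
}

## attach uniform half-width bounds to a table (testing / bootstrap helper)
cf_table_with_bounds <- function(table, width) {
  for (i in 1:3) {
    table[[paste0(cf_cols[i], "_lo")]] <- pmax(0, table[[cf_cols[i]]] - width)
    table[[paste0(cf_cols[i], "_hi")]] <- pmin(1, table[[cf_cols[i]]] + width)
  }
  table
}

#' Per-taxon quartet coverage of a CF table
#' @param table a `cf_table`
#' @return named integer vector: number of sampled sets containing each taxon
#' @export
cf_coverage <- function(table) {
  tx <- as.matrix(table[, paste0("taxon", 1:4)])
  tab <- table(factor(as.vector(tx)))
  setNames(as.integer(tab), names(tab))
}
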