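## ---------------------------------------------------------------------------
## Extended Newick I/O
##
## Dialect: "(...)#H<k>:length:support:gamma". Each hybrid node is tagged
## "#H<k>" and appears exactly twice: once carrying its subtree (written under
## the major parent) and once as a bare stub under the minor parent. The
## inheritance probability gamma occupies the third colon field of a hybrid
## edge; when given on only one member of the pair, the partner receives
## 1 - gamma. The edge with gamma >= 0.5 is designated major.
## ---------------------------------------------------------------------------

#' Parse an extended-Newick network
#'
#' Reads a semi-directed level-1 phylogenetic network from extended-Newick
#' text (see the package README for the exact dialect). Plain Newick trees are
#' a special case. Polytomies (other than a trifurcation at the outermost,
#' unrooted-style base) are rejected: the model space is binary.
#'
#' @param text extended-Newick string (a file path is also accepted if the
#'   file exists); one network
#' @return a `phynet` network
#' @export
parse_enewick <- function(text) {
  if (length(text) == 1L && !grepl("(", text, fixed = TRUE) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  text <- paste(text, collapse = "")
  s <- gsub("[[:space:]]", "", text)
  s <- sub(";$", "", s)
  if (!nzchar(s)) stop("empty Newick string")
  pos <- 1L
  n <- nchar(s)
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  ## a parsed node: list(children = list of (node, len, sup, gamma),
  ##                     label, htag)
  parse_label <- function() {
    start <- pos
    while (pos <= n && !(substr(s, pos, pos) %in% c(":", ",", "(", ")", ";")))
      pos <<- pos + 1L
    substr(s, start, pos - 1L)
  }
  parse_fields <- function() {
    f <- c(NA_real_, NA_real_, NA_real_)
    i <- 0L
    while (peek() == ":" && i < 3L) {
      pos <<- pos + 1L; i <- i + 1L
      start <- pos
      while (pos <= n && !(substr(s, pos, pos) %in% c(":", ",", "(", ")")))
        pos <<- pos + 1L
      val <- substr(s, start, pos - 1L)
      if (nzchar(val)) {
        f[i] <- suppressWarnings(as.numeric(val))
        if (is.na(f[i])) stop("malformed numeric field '", val, "'")
      }
    }
    f
  }
  parse_node <- function() {
    children <- list()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        child <- parse_node()
        fields <- parse_fields()
        children[[length(children) + 1L]] <-
          list(node = child, len = fields[1L], sup = fields[2L], gamma = fields[3L])
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("malformed Newick near position ", pos)
      }
    }
    lab <- parse_label()
    htag <- NA_character_
    if (grepl("#", lab, fixed = TRUE)) {
      parts <- strsplit(lab, "#", fixed = TRUE)[[1L]]
      htag <- parts[length(parts)]
      if (!grepl("^(H|LGT|R)?[0-9]+$", htag)) stop("malformed hybrid tag '#", htag, "'")
      lab <- if (length(parts) > 1L) parts[1L] else ""
    }
    list(children = children, label = lab, htag = htag)
  }
  top <- parse_node()
  parse_fields()   # tolerate (and ignore) fields on the outermost node
  if (pos <= n && peek() != "") stop("trailing characters after Newick string")
  if (length(top$children) < 2L) stop("root must have at least 2 children")

  ## flatten into provisional node records
  nodes <- list()   # each: label, htag, children = list of (id, len, sup, gamma)
  build <- function(pn) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(label = pn$label, htag = pn$htag, kids = list())
    for (ch in pn$children) {
      cid <- build(ch$node)
      nodes[[id]]$kids[[length(nodes[[id]]$kids) + 1L]] <<-
        list(id = cid, len = ch$len, sup = ch$sup, gamma = ch$gamma)
    }
    id
  }
  root_pid <- build(top)

  ## merge hybrid occurrences
  htags <- vapply(nodes, function(x) x$htag, "")
  htags[is.na(htags)] <- NA_character_
  for (tg in unique(htags[!is.na(htags)])) {
    occ <- which(htags == tg)
    if (length(occ) != 2L)
      stop("hybrid tag '#", tg, "' appears ", length(occ), " times; expected 2")
  }
  canon <- setNames(seq_along(nodes), seq_along(nodes))
  for (tg in unique(htags[!is.na(htags)])) {
    occ <- which(htags == tg)
    nk <- vapply(occ, function(i) length(nodes[[i]]$kids), 1L)
    if (sum(nk > 0L) != 1L)
      stop("hybrid '#", tg, "' must carry its subtree in exactly one occurrence")
    keepo <- occ[nk > 0L]; dropo <- occ[nk == 0L]
    canon[dropo] <- keepo
  }

  ## assign final ids: leaves first (in order of appearance), then internals
  is_leaf <- vapply(seq_along(nodes), function(i)
    canon[i] == i && length(nodes[[i]]$kids) == 0L && is.na(htags[i]), TRUE)
  leaf_ids <- which(is_leaf)
  labels <- vapply(leaf_ids, function(i) nodes[[i]]$label, "")
  if (any(!nzchar(labels))) stop("unlabeled leaf")
  if (anyDuplicated(labels))
    stop("duplicate leaf labels: ", paste(unique(labels[duplicated(labels)]), collapse = ", "))
  internal_ids <- setdiff(which(canon == seq_along(nodes)), leaf_ids)
  final <- integer(length(nodes))
  final[leaf_ids] <- seq_along(leaf_ids)
  final[internal_ids] <- length(leaf_ids) + seq_along(internal_ids)
  final <- final[canon]  # merged occurrences share the kept node's id

  hyb_final <- final[which(!is.na(htags) &
                             vapply(seq_along(nodes), function(i)
                               length(nodes[[i]]$kids) > 0L, TRUE))]
  parent <- integer(0); child <- integer(0)
  len <- numeric(0); gam <- numeric(0)
  for (i in seq_along(nodes)) {
    if (canon[i] != i && length(nodes[[i]]$kids)) next
    for (k in nodes[[i]]$kids) {
      parent <- c(parent, final[i]); child <- c(child, final[k$id])
      len <- c(len, k$len); gam <- c(gam, k$gamma)
    }
  }
  ## edges into merged (dropped) occurrences point at the kept node: the loop
  ## above already used final[], which maps both occurrences to one id
  hybrid <- child %in% final[which(!is.na(htags))]
  ## per hybrid node: resolve gamma pair and the major flag
  major <- rep(TRUE, length(parent))
  for (v in unique(child[hybrid])) {
    he <- which(hybrid & child == v)
    if (length(he) != 2L) stop("hybrid node must have exactly 2 parent edges")
    g <- gam[he]
    if (all(is.na(g))) {
      major[he[2L]] <- FALSE      # first-encountered edge is major
    } else {
      if (any(!is.na(g) & (g < 0 | g > 1))) stop("gamma outside [0,1]")
      if (sum(!is.na(g)) == 1L) g[is.na(g)] <- 1 - g[!is.na(g)]
      if (abs(sum(g) - 1) > 1e-6)
        stop("gamma pair at hybrid node does not sum to 1 (", g[1L], " + ", g[2L], ")")
      g <- g / sum(g)
      gam[he] <- g
      if (g[1L] >= 0.5) major[he[2L]] <- FALSE else major[he[1L]] <- FALSE
    }
  }
  gam[!hybrid] <- NA_real_
  ## binary check: non-root internal nodes
  outdeg <- tabulate(parent, max(final))
  for (v in setdiff(unique(parent), final[root_pid])) {
    expected <- if (v %in% child[hybrid]) 1L else 2L
    if (outdeg[v] != expected)
      stop("polytomy or malformed node (node with ", outdeg[v],
           " children); input networks must be binary")
  }
  new_phynet(cbind(parent, child), len, hybrid, gam, major, labels,
             final[root_pid])
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Write a network as extended Newick
#'
#' The hybrid subtree is written under the major parent, the minor parent
#' carries a bare `#H` stub; gamma occupies the third colon field on both
#' hybrid edges. The round trip `parse_enewick(write_enewick(net))` preserves
#' topology, branch lengths and inheritance probabilities.
#'
#' @param net a `phynet` network
#' @param file optional path; when given the string is written there
#' @param root_at optional outgroup taxon; the network is re-rooted on that
#'   taxon's external edge before writing (error if invalid, see
#'   [root_with_outgroup()])
#' @param digits significant digits for branch lengths and gamma
#' @return the Newick string, invisibly when `file` is given
#' @export
write_enewick <- function(net, file = NULL, root_at = NULL, digits = 10) {
  if (!is.null(root_at)) net <- root_with_outgroup(net, root_at)
  hyb <- hybrid_node_ids(net)
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  edge_suffix <- function(e) {
    l <- net$length[e]; g <- net$gamma[e]
    if (net$hybrid[e]) {
      paste0(":", if (is.na(l)) "" else fmt(l), "::",
             if (is.na(g)) "" else fmt(g))
    } else if (!is.na(l)) paste0(":", fmt(l)) else ""
  }
  rec <- function(v) {
    if (v <= net$ntax) return(net$labels[v])
    kids <- which(net$edge[, 1L] == v)
    parts <- character(0)
    for (e in kids) {
      w <- net$edge[e, 2L]
      if (w %in% hyb) {
        tag <- paste0("#H", match(w, hyb))
        if (net$major[e]) {
          kid <- which(net$edge[, 1L] == w)
          inner <- rec(net$edge[kid, 2L])
          sub <- paste0("(", inner,
                        { ks <- edge_suffix(kid); ks }, ")", tag, edge_suffix(e))
        } else {
          sub <- paste0(tag, edge_suffix(e))
        }
      } else {
        sub <- paste0(rec(w), edge_suffix(e))
      }
      parts <- c(parts, sub)
    }
    paste0("(", paste(parts, collapse = ","), ")")
  }
  out <- paste0(rec(net$root), ";")
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}
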