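test_that("move proposals respect the legality rules", {
  tr <- as_phynet(ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);"))
  set.seed(1)
  tags <- replicate(40, propose_move(tr, h_max = 1)$move)
  expect_true(all(tags %in% c("nni", "add")))
  tags0 <- replicate(20, propose_move(tr, h_max = 0)$move)
  expect_true(all(tags0 == "nni"))

  net <- fix_diamond6()
  set.seed(2)
  tags1 <- replicate(60, propose_move(net, h_max = 1)$move)
  expect_true(all(tags1 %in% c("origin", "target", "flip", "nni")))
  expect_gte(length(unique(tags1)), 3L)
})

test_that("flip reverses the hybridization direction and re-anchors gamma", {
  net <- fix_diamond6(gamma = 0.3)
  hv0 <- hybrid_cycles(net)[[1L]]$hybrid
  cl0 <- sort(net$labels[qcfnet:::subtree_below(net, hv0)])
  set.seed(3)
  for (i in 1:50) {
    pr <- propose_move(net, h_max = 1)
    if (pr$move != "flip" || is.null(pr$net)) next
    hv1 <- hybrid_cycles(pr$net)[[1L]]$hybrid
    cl1 <- sort(pr$net$labels[qcfnet:::subtree_below(pr$net, hv1)])
    expect_false(identical(cl0, cl1))
    g <- pr$net$gamma[pr$net$hybrid & !pr$net$major]
    expect_true(abs(g - 0.3) < 1e-9 || abs(g - 0.7) < 1e-9)
    break
  }
})

test_that("searchability filters the identifiability-poor classes", {
  expect_false(isTRUE(is_searchable(fix_double(), 1)))     # 2-cycle
  expect_match(attr(is_searchable(fix_double(), 1), "reason"), "cycle2|class")
  expect_false(isTRUE(is_searchable(fix_single(), 1)))     # triangle, n_i = 1
  expect_true(isTRUE(is_searchable(fix_diamond6(), 1)))
  expect_false(isTRUE(is_searchable(fix_diamond6(), 0)))   # h > h_max
  expect_true(isTRUE(is_searchable(fix_bad2(), 1)))
})

test_that("NNI on an internal edge yields a different resolved topology", {
  tr <- as_phynet(ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);"))
  h0 <- sd_hash(tr)
  seen <- character(0)
  set.seed(4)
  for (i in 1:30) {
    cand <- propose_move(tr, h_max = 0)$net
    if (is.null(cand)) next
    seen <- c(seen, sd_hash(cand))
  }
  expect_true(all(seen != h0))
  ## classical NNI neighborhood: 2 alternatives per internal edge
  expect_gte(length(unique(seen)), 2L)
})

test_that("random move application explores most of the 5-taxon h=1 space", {
  ## enumerate the searchable 5-taxon h = 1 networks by brute force
  base <- as_phynet(ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);"))
  trees <- list(base)
  set.seed(5)
  for (i in 1:200) {
    cand <- propose_move(trees[[sample(length(trees), 1)]], h_max = 0)$net
    if (!is.null(cand)) trees <- c(trees, list(cand))
  }
  keys <- vapply(trees, sd_hash, "")
  trees <- trees[!duplicated(keys)]
  expect_equal(length(trees), 15L)  # all unrooted 5-taxon topologies
  space <- new.env(parent = emptyenv())
  for (tr in trees) {
    E <- nrow(tr$edge)
    for (de in seq_len(E)) for (re in seq_len(E)) {
      if (de == re) next
      cand <- add_hybridization(tr, de, re, gamma = 0.3, length = 0.5)
      if (is.null(cand) || !isTRUE(is_searchable(cand, 1))) next
      assign(sd_hash(cand), TRUE, envir = space)
    }
  }
  total <- length(ls(space))
  expect_gt(total, 10L)
  ## random walk with moves origin/target/nni from a few random starts
  reached <- new.env(parent = emptyenv())
  starts <- 0L
  set.seed(6)
  while (starts < 8L) {
    tr <- trees[[sample(length(trees), 1)]]
    E <- nrow(tr$edge)
    net <- add_hybridization(tr, sample(E, 1), sample(E, 1), gamma = 0.3,
                             length = 0.5)
    if (is.null(net) || !isTRUE(is_searchable(net, 1))) next
    starts <- starts + 1L
    for (step in 1:400) {
      assign(sd_hash(net), TRUE, envir = reached)
      pr <- propose_move(net, h_max = 1)
      if (!is.null(pr$net) && isTRUE(is_searchable(pr$net, 1)) &&
            pr$move %in% c("origin", "target", "nni"))
        net <- pr$net
    }
  }
  coverage <- mean(ls(space) %in% ls(reached))
  expect_gte(coverage, 0.9)
})

test_that("accepted scores are non-decreasing along each run", {
  net <- fix_diamond6()
  tab <- simulate_cf_table(net, 1000, seed = 41)
  res <- snaq_search(tab, start_tree_nj(tab), h_max = 1, runs = 2, seed = 5,
                     max_failures = 10)
  for (r in unique(res$trace$run)) {
    sc <- res$trace$score[res$trace$run == r]
    expect_true(all(diff(sc) >= -1e-9))
  }
  expect_true(all(res$trace$move %in%
                    c("origin", "target", "flip", "nni", "nni0", "add",
                      "none")))
})

test_that("exact tree CFs with h_max = 1 exercise the gamma-zero deletion", {
  tr <- parse_enewick("(((a:1,b:1):0.4,(c:1,d:1):0.5):0.3,(e:1,f:1):0.6);")
  tab <- expected_cf_table(tr)
  res <- snaq_search(tab, as_phylo(tr), h_max = 1, runs = 1, seed = 3,
                     max_failures = 12, weighting = "fractional")
  ok <- res$h == 0L ||
    all(res$net$gamma[res$net$hybrid & !res$net$major] <= 1e-4)
  expect_true(ok)
  expect_equal(sd_hash(major_tree(res$net)), sd_hash(tr))
})

test_that("search recovers the generating network from exact CFs", {
  net <- fix_diamond6()
  tab <- expected_cf_table(net)
  res <- snaq_search(tab, as_phylo(major_tree(net)), h_max = 1, runs = 3,
                     seed = 11, max_failures = 25, weighting = "fractional")
  expect_equal(res$h, 1L)
  expect_equal(sd_hash(res$net), sd_hash(net))
})

test_that("snaq returns a classed fit with working methods", {
  net <- fix_diamond6()
  tab <- simulate_cf_table(net, 2000, seed = 51)
  fit <- snaq(tab, start_tree_nj(tab), h_max = 1, runs = 1, seed = 2,
              max_failures = 10)
  expect_s3_class(fit, "snaq")
  expect_output(print(fit), "pseudolikelihood")
  expect_s3_class(summary(fit), "summary.snaq")
  co <- coef(fit)
  expect_true(all(c("type", "length", "gamma") %in% names(co)))
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(as.numeric(ll), fit$loglik)
  ft <- fitted(fit)
  expect_equal(dim(ft), dim(tab))
  rs <- residuals(fit)
  expect_lt(max(abs(rs$CF12_34)), 0.5)
  sims <- simulate(fit, seed = 1, ngenes = 10)
  expect_length(sims, 10L)
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})
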