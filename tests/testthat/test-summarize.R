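test_that("slope heuristic picks the breakpoint of two-segment fits", {
  ## oracle: exhaustive breakpoint SSE comparison with lm()
  oracle <- function(scores) {
    n <- length(scores); h <- 0:(n - 1)
    sse <- function(i) if (length(i) < 2) 0 else
      sum(resid(lm(scores[i] ~ h[i]))^2)
    tot <- sapply(2:(n - 1), function(b) sse(1:b) + sse(b:n))
    (2:(n - 1))[which.min(tot)] - 1
  }
  s <- c(1000, 500, 100, 95, 90, 85)
  expect_equal(slope_heuristic(s), 2L)
  expect_equal(slope_heuristic(s), oracle(s))
  s2 <- c(400, 150, 60, 55, 52, 50, 49)
  expect_equal(slope_heuristic(s2), oracle(s2))

  ## exactly linear profiles resolve to h = 0
  expect_equal(slope_heuristic(c(100, 80, 60, 40, 20)), 0L)
  expect_error(slope_heuristic(c(10, 5)), "3")

  ## affine invariance
  expect_equal(slope_heuristic(3 * s + 17), slope_heuristic(s))
  expect_equal(slope_heuristic(s / 1000), slope_heuristic(s))
})

test_that("Robinson-Foulds distances match split arithmetic", {
  t1 <- ape::read.tree(text = "((a,b),c,(d,e));")
  expect_equal(robinson_foulds(t1, t1), 0L)
  t2 <- ape::read.tree(text = "((a,c),b,(d,e));")
  expect_equal(robinson_foulds(t1, t2), 2L)
  ## NNI neighbors are at distance 2
  tr <- ape::read.tree(text = "(((a,b),c),(d,e),f);")
  nn <- as_phylo(qcfnet:::nni_move(as_phynet(tr),
    which(as_phynet(tr)$edge[, 2] > 6)[2]))
  expect_equal(robinson_foulds(tr, nn), 2L)
  expect_error(robinson_foulds(t1, ape::read.tree(text = "((a,b),c,(d,f));")),
               "differ")
})

test_that("hardwired cluster distance behaves like a pseudometric", {
  net <- fix_diamond6()
  r1 <- root_with_outgroup(net, "e")
  expect_equal(hardwired_cluster_distance(r1, r1), 0L)

  ## on trees it reduces to the rooted-cluster symmetric difference
  ta <- root_with_outgroup(parse_enewick("((a,b),(c,d),e);"), "e")
  tb <- root_with_outgroup(parse_enewick("((a,c),(b,d),e);"), "e")
  expect_equal(hardwired_cluster_distance(ta, tb), 4L)

  ## the direction-experiment pair differs when rooted identically
  p <- fix_dir_pair()
  d <- hardwired_cluster_distance(root_with_outgroup(p$good, "c"),
                                  root_with_outgroup(p$bad1, "c"))
  expect_gt(d, 0L)

  ## symmetry and triangle inequality on random rooted trees
  set.seed(77)
  for (i in 1:10) {
    ns <- lapply(1:3, function(j) root_with_outgroup(
      as_phynet(ape::rtree(6, tip.label = paste0("t", 1:6))), "t1"))
    d12 <- hardwired_cluster_distance(ns[[1]], ns[[2]])
    d21 <- hardwired_cluster_distance(ns[[2]], ns[[1]])
    d13 <- hardwired_cluster_distance(ns[[1]], ns[[3]])
    d23 <- hardwired_cluster_distance(ns[[2]], ns[[3]])
    expect_equal(d12, d21)
    expect_lte(d13, d12 + d23)
  }
})

test_that("hybridization matching detects identical and reversed placements", {
  net <- fix_diamond6()
  expect_true(hybridization_match(net, net, outgroup = "e"))
  p <- fix_dir_pair()
  expect_false(hybridization_match(p$good, p$bad1, outgroup = "c"))
  ## a second, unrelated reticulation does not affect the tested hybrid:
  ## build a 2-hybrid network whose first reticulation matches net's
  set.seed(12)
  net2 <- NULL
  ee <- which(!net$hybrid & net$edge[, 2] <= net$ntax)
  for (i in seq_along(ee)) for (j in seq_along(ee)) {
    if (i == j || !is.null(net2)) next
    cand <- add_hybridization(net, ee[i], ee[j], gamma = 0.1, length = 0.2)
    if (!is.null(cand) && !length(validate_level1(cand))) net2 <- cand
  }
  expect_false(is.null(net2))
  hv_main <- hybrid_cycles(net)[[1]]$hybrid
  idx2 <- which(vapply(hybrid_cycles(net2), function(x)
    setequal(qcfnet:::subtree_below(net2, x$hybrid), 1L), TRUE))
  ## locate the original hybrid in net2 by its single descendant "a"
  idx2 <- which(vapply(hybrid_cycles(net2), function(x)
    identical(sort(net2$labels[qcfnet:::subtree_below(net2, x$hybrid)]), "a"),
    TRUE))
  if (length(idx2) == 1L)
    expect_true(hybridization_match(net, net2, c(1L, idx2), outgroup = "e"))
})

test_that("bootstrap summaries count equivalent edges and placements", {
  ref <- fix_diamond6()
  ## all replicates identical to the reference: 100% everywhere
  s <- summarize_bootstrap(rep(list(ref), 4L), ref)
  expect_true(all(s$edge_support$support == 100))
  expect_true(all(s$hybrid_support$support == 100))

  ## reference hybrid absent from all replicates: 0%
  alt <- major_tree(ref)
  s0 <- summarize_bootstrap(rep(list(alt), 4L), ref)
  expect_true(all(s0$hybrid_support$support == 0))

  ## a 75/25 split of placements is reported as such
  p <- fix_dir_pair()
  boots <- c(rep(list(p$good), 3L), list(p$bad1))
  sg <- summarize_bootstrap(boots, p$good)
  expect_equal(sg$hybrid_support$support, 75)
  expect_setequal(sg$hybrid_alternatives$frequency, c(75, 25))
  ## all supports are multiples of 100/B
  expect_true(all(sg$hybrid_alternatives$frequency %% 25 == 0))
})

test_that("bootstrap networks are reproducible and respect degenerate bounds", {
  net <- fix_diamond6()
  tab <- qcfnet:::cf_table_with_bounds(expected_cf_table(net, ngenes = 1000),
                                       0)
  expect_error(bootstrap_networks(tab, as_phylo(major_tree(net)), B = 0),
               "B")
  b1 <- bootstrap_networks(tab, as_phylo(major_tree(net)), B = 1, h_max = 1,
                           runs = 1, seed = 9, max_failures = 8,
                           weighting = "fractional")
  expect_length(b1, 1L)
  ## the replicate is exactly the documented composition: resample (here an
  ## identity up to renormalization) followed by the seeded search
  rt <- resample_cf_table(tab, seed = attr(b1[[1]], "seed"))
  expect_equal(as.matrix(rt[, c("CF12_34", "CF13_24", "CF14_23")]),
               as.matrix(tab[, c("CF12_34", "CF13_24", "CF14_23")]),
               tolerance = 1e-12)
  direct <- snaq_search(rt, as_phylo(major_tree(net)), h_max = 1, runs = 1,
                        seed = attr(b1[[1]], "seed"), max_failures = 8,
                        weighting = "fractional")
  expect_equal(sd_hash(b1[[1]]), sd_hash(direct$net))
})
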