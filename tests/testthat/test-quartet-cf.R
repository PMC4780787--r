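test_that("species-tree CFs follow the coalescent closed form", {
  expect_equal(expected_cf_tree(0), rep(1 / 3, 3))
  expect_equal(expected_cf_tree(Inf), c(1, 0, 0))
  expect_equal(expected_cf_tree(log(2)), c(2 / 3, 1 / 6, 1 / 6))
  for (t in c(0.1, 1, 4)) {
    cf <- expected_cf_tree(t)
    expect_equal(sum(cf), 1)
    expect_equal(cf[1], 1 - 2 / 3 * exp(-t))
  }
  expect_error(expected_cf_tree(-1))
})

test_that("single-descendant hybrid CFs mix the two parental species trees", {
  expect_equal(expected_cf_hybrid_single(1, 2, 0), expected_cf_tree(1))
  expect_equal(expected_cf_hybrid_single(1, 2, 1), expected_cf_tree(3))
  cf <- expected_cf_hybrid_single(1, 2, 0.3)
  direct <- 0.7 * (1 - 2 / 3 * exp(-1)) + 0.3 * (1 - 2 / 3 * exp(-3))
  expect_equal(cf[1], direct)
  expect_equal(round(cf, 5), c(0.81837, 0.09082, 0.09082))
})

test_that("two-descendant hybrid CFs follow the four-tree average", {
  expect_equal(expected_cf_hybrid_double(Inf, 1, 1, 1, 0.2), c(1, 0, 0))
  expect_equal(expected_cf_hybrid_double(0, 2, 1, 1, 0),
               expected_cf_tree(3))
  cf <- expected_cf_hybrid_double(1, 1, 1, 1, 0.2)
  direct <- 1 - exp(-1) + exp(-1) *
    (0.8^2 * (1 - 2 / 3 * exp(-2)) + 2 * 0.2 * 0.8 * (1 - 2 / 3 * exp(-1)) +
       0.2^2 * (1 - 2 / 3 * exp(-2)))
  expect_equal(cf[1], direct)
  expect_equal(cf[1], 0.9485583, tolerance = 1e-6)
})

test_that("closed forms agree with the enumeration engine", {
  for (g in c(0.1, 0.3, 0.5, 0.9)) for (tt in c(0.2, 1, 2.5)) {
    eng <- enumerate_histories_cf(fix_single(t1 = tt, t2 = 2 * tt, gamma = g))
    expect_equal(as.numeric(eng), expected_cf_hybrid_single(tt, 2 * tt, g),
                 tolerance = 1e-9)
    eng2 <- enumerate_histories_cf(
      fix_double(t1 = tt, t2 = 1.3, t3 = tt, t4 = 0.5, gamma = g))
    expect_equal(as.numeric(eng2),
                 expected_cf_hybrid_double(tt, 1.3, tt, 0.5, g),
                 tolerance = 1e-9)
  }
})

test_that("the engine confirms the two minor CFs of the cherry-hybrid case", {
  cf <- enumerate_histories_cf(fix_double(0.4, 0.8, 1.2, 0.3, 0.35))
  expect_equal(cf[[2]], cf[[3]], tolerance = 1e-12)
})

test_that("reducing an undetectable cycle preserves expected CFs", {
  ## triangle reduction: transformed internal length matches the closed form
  net <- fix_single(t1 = 1, t2 = 2, gamma = 0.3)
  red <- reduce_undetectable_cycle(net)
  expect_equal(n_hybrids(red), 0L)
  ## equivalent species tree has internal length -log(0.7 e^-1 + 0.3 e^-3)
  t3 <- -log(0.7 * exp(-1) + 0.3 * exp(-3))
  expect_equal(t3, 1.300294, tolerance = 1e-6)
  expect_equal(as.numeric(expected_cf(red, c("a", "b", "c", "d"))),
               expected_cf_tree(t3), tolerance = 1e-9)
  ## CFs unchanged on a parameter grid, for triangles and 2-cycles
  for (g in c(0.2, 0.5, 0.8)) for (tt in c(0.3, 1.2)) {
    n1 <- fix_single(t1 = tt, t2 = 2 * tt, gamma = g)
    r1 <- reduce_undetectable_cycle(n1)
    expect_equal(as.numeric(enumerate_histories_cf(r1)),
                 as.numeric(enumerate_histories_cf(n1)), tolerance = 1e-9)
    n2 <- fix_double(t1 = tt, t2 = 0.9, t3 = tt, t4 = 0.4, gamma = g)
    r2 <- reduce_undetectable_cycle(n2)
    expect_equal(as.numeric(enumerate_histories_cf(r2)),
                 as.numeric(enumerate_histories_cf(n2)), tolerance = 1e-9)
  }
  expect_error(reduce_undetectable_cycle(parse_enewick("(a,(b,(c,d)));")),
               "reduce")
})

test_that("expected_cf extracts subnetworks and is rooting-invariant", {
  ## 6-taxon tree: any quartet equals the tree CF of the summed path
  tr <- parse_enewick("(((a:1,b:1):0.4,(c:1,d:1):0.5):0.3,(e:1,f:1):0.6);")
  cf <- expected_cf(tr, c("a", "b", "e", "f"))
  expect_equal(as.numeric(cf), expected_cf_tree(0.4 + 0.3 + 0.6),
               tolerance = 1e-12)
  cf2 <- expected_cf(tr, c("a", "c", "e", "f"))
  expect_equal(as.numeric(cf2), expected_cf_tree(0.3 + 0.6), tolerance = 1e-12)

  ## network quartet equals the engine on the extracted subnetwork under
  ## every valid rooting
  net <- fix_diamond6()
  sets <- quartet_sets(net$labels)
  roots <- qcfnet:::valid_root_nodes(net)
  for (i in seq_len(nrow(sets))) {
    ref <- as.numeric(expected_cf(net, sets[i, ]))
    expect_equal(sum(ref), 1, tolerance = 1e-9)
    for (p in roots) {
      eng <- engine_cf_at_root(net, sets[i, ], p)
      expect_equal(eng, ref, tolerance = 1e-12)
    }
  }
})

test_that("gamma symmetry: exchanging the hybrid-edge roles leaves CFs fixed", {
  ## swapping which edge is called minor while replacing gamma by 1 - gamma
  ## keeps each edge's physical inheritance, so expected CFs cannot change
  for (build in list(function(g) fix_single(gamma = g),
                     function(g) fix_double(gamma = g),
                     function(g) fix_diamond6(gamma = g))) {
    for (g in c(0.2, 0.45)) {
      n1 <- build(g)
      n3 <- n1
      n3$major[n3$hybrid] <- !n3$major[n3$hybrid]
      sets <- quartet_sets(n1$labels)
      for (i in seq_len(nrow(sets))) {
        expect_equal(as.numeric(expected_cf(n1, sets[i, ])),
                     as.numeric(expected_cf(n3, sets[i, ])),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("there are exactly five canonical quartet networks, all level-1", {
  nets <- canonical_quartet_networks()
  expect_length(nets, 5L)
  for (net in nets) {
    expect_length(validate_level1(net), 0L)
    expect_equal(net$ntax, 4L)
    expect_equal(n_hybrids(net), 1L)
  }
  ks <- sort(vapply(nets, function(n) hybrid_cycles(n)[[1L]]$k, 1L))
  expect_equal(ks, c(2L, 2L, 3L, 3L, 4L))
})

test_that("k = 2 and k = 3 canonical networks are tree-equivalent", {
  nets <- canonical_quartet_networks()
  for (net in nets) {
    k <- hybrid_cycles(net)[[1L]]$k
    if (k >= 4L) next
    for (g in c(0.15, 0.5, 0.85)) {
      n2 <- net
      n2$gamma[n2$hybrid & !n2$major] <- g
      n2$gamma[n2$hybrid & n2$major] <- 1 - g
      cf <- as.numeric(expected_cf(n2, n2$labels, default_length = 0.7))
      ## some tree reproduces these CFs: minors equal and major >= 1/3
      m <- sort(cf)
      expect_equal(m[1], m[2], tolerance = 1e-9)
      expect_gte(m[3], 1 / 3 - 1e-9)
    }
  }
})

test_that("k = 4 reticulations are detectable: CFs differ from any tree", {
  nets <- canonical_quartet_networks()
  k4 <- nets[[which(vapply(nets, function(n) hybrid_cycles(n)[[1L]]$k, 1L)
                    == 4L)]]
  cf <- as.numeric(expected_cf(k4, k4$labels))
  m <- sort(cf, decreasing = TRUE)
  ## a species tree always has its two smallest CFs equal
  expect_gt(abs(m[2] - m[3]), 1e-3)
})

test_that("hybrid direction is unidentifiable at n = 4 but identifiable at n = 5", {
  p <- fix_dir_pair(gamma = 0.3)
  q4 <- c("a", "b", "c", "d1")
  target <- as.numeric(expected_cf(p$bad1, q4))

  ## on 4 taxa: the good diamond can match the bad-I CFs exactly
  match4 <- function(x) {
    net <- p$good
    con <- apply_identifiability_constraints(net)
    sg <- qcfnet:::map_set(ifelse(is.na(con$net$length), 1, con$net$length),
                           con$net$gamma, con$map,
                           pmin(pmax(x, 0), c(1, rep(10, length(x) - 1))))
    net2 <- con$net; net2$length <- sg$lens; net2$gamma <- sg$gams
    sum((as.numeric(expected_cf(net2, q4)) - target)^2)
  }
  con <- apply_identifiability_constraints(p$good)
  x0 <- qcfnet:::map_get(con$net, con$map)
  fit <- optim(x0, match4, method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-14))
  expect_lt(fit$value, 1e-10)

  ## on all 5 taxa: no parameter choice of the good diamond reproduces the
  ## bad-I CF table
  sets5 <- quartet_sets(p$bad1$labels)
  target5 <- t(apply(sets5, 1, function(tx)
    as.numeric(expected_cf(p$bad1, tx))))
  match5 <- function(x) {
    sg <- qcfnet:::map_set(ifelse(is.na(con$net$length), 1, con$net$length),
                           con$net$gamma, con$map,
                           pmin(pmax(x, 0), c(1, rep(10, length(x) - 1))))
    net2 <- con$net; net2$length <- sg$lens; net2$gamma <- sg$gams
    got <- t(apply(sets5, 1, function(tx) as.numeric(expected_cf(net2, tx))))
    sum((got - target5)^2)
  }
  fit5 <- optim(fit$par, match5, method = "Nelder-Mead",
                control = list(maxit = 6000, reltol = 1e-14))
  expect_gt(fit5$value, 1e-6)
})
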