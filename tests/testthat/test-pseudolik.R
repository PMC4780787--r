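test_that("log pseudolikelihood matches direct multinomial arithmetic", {
  ## single quartet with expected CFs (0.9, 0.05, 0.05) and X = (90, 5, 5):
  ## 90 log 0.9 + 10 log 0.05
  tr <- parse_enewick(sprintf("((a:1,b:1):%g,(c:1,d:1):0);",
                              -log(1.5 * (1 - 0.9))))
  tab <- data.frame(taxon1 = "a", taxon2 = "b", taxon3 = "c", taxon4 = "d",
                    CF12_34 = 0.9, CF13_24 = 0.05, CF14_23 = 0.05,
                    ngenes = 100)
  class(tab) <- c("cf_table", "data.frame")
  val <- log_pseudolik(tr, tab)
  expect_equal(as.numeric(val), 90 * log(0.9) + 10 * log(0.05),
               tolerance = 1e-9)
  expect_equal(round(as.numeric(val), 3), -39.440)

  ## zero counts give zero log likelihood
  tab0 <- tab; tab0$ngenes <- 0
  expect_equal(as.numeric(log_pseudolik(tr, tab0)), 0)

  ## star expectation: total X * log(1/3)
  star <- parse_enewick("((a:1,b:1):0,(c:1,d:1):0);")
  tab3 <- tab; tab3$ngenes <- 300
  expect_equal(as.numeric(log_pseudolik(star, tab3)), 300 * log(1 / 3),
               tolerance = 1e-9)
})

test_that("log pseudolikelihood is invariant to the stored rooting", {
  net <- fix_diamond6()
  tab <- simulate_cf_table(net, 500, seed = 31)
  v0 <- as.numeric(log_pseudolik(net, tab))
  for (p in qcfnet:::valid_root_nodes(net)) {
    vp <- as.numeric(log_pseudolik(qcfnet:::orient_network(net, p), tab))
    expect_equal(vp, v0, tolerance = 1e-9)
  }
})

test_that("branch length initialization inverts average CFs as printed", {
  tr <- parse_enewick("((a:1,b:1):1,(c:1,d:1):1);")
  mk <- function(cf1) {
    tab <- data.frame(taxon1 = "a", taxon2 = "b", taxon3 = "c", taxon4 = "d",
                      CF12_34 = cf1, CF13_24 = (1 - cf1) / 2,
                      CF14_23 = (1 - cf1) / 2, ngenes = 100)
    class(tab) <- c("cf_table", "data.frame")
    tab
  }
  internal_len <- function(net) {
    nu <- qcfnet:::net_unroot(net)
    sum(nu$length[nu$edge[, 2L] > nu$ntax])
  }
  expect_equal(internal_len(init_branch_lengths(tr, mk(1 / 3))), log(2),
               tolerance = 1e-9)
  ## CF >= 2/3 clamps at the ceiling
  expect_equal(internal_len(init_branch_lengths(tr, mk(0.9))), 10)
  ## CF ~ 0 clamps at the floor
  expect_equal(internal_len(init_branch_lengths(tr, mk(0))), 1e-10)
  ## consistent inversion: t = -log(3/2 (1 - CF))
  expect_equal(internal_len(init_branch_lengths(tr, mk(0.9),
                                                formula = "consistent")),
               -log(1.5 * 0.1), tolerance = 1e-9)
})

test_that("exact CFs on the true topology recover all free parameters", {
  ## good diamond (6 taxa)
  net <- fix_diamond6()
  tab <- expected_cf_table(net)
  scr <- net
  scr$length[scr$edge[, 2L] > scr$ntax] <- 0.5
  scr$gamma[scr$hybrid & !scr$major] <- 0.15
  scr$gamma[scr$hybrid & scr$major] <- 0.85
  opt <- optimize_parameters(scr, tab, weighting = "fractional", seed = 1,
                             rhoend = 1e-7)
  con <- apply_identifiability_constraints(net)
  expect_lt(max(abs(qcfnet:::map_get(con$net, con$map) - opt$par)), 1e-3)

  ## bad diamond II (5 taxa, child edge 0 in truth)
  nb <- fix_bad2()
  tabb <- expected_cf_table(nb)
  scb <- nb
  scb$length[scb$edge[, 2L] > scb$ntax] <- 0.4
  scb$gamma[scb$hybrid & !scb$major] <- 0.15
  scb$gamma[scb$hybrid & scb$major] <- 0.85
  optb <- optimize_parameters(scb, tabb, weighting = "fractional", seed = 2,
                              rhoend = 1e-7)
  conb <- apply_identifiability_constraints(nb)
  expect_lt(max(abs(qcfnet:::map_get(conb$net, conb$map) - optb$par)), 1e-3)
})

test_that("tree data on a network topology drives gamma to the boundary", {
  tr <- parse_enewick("(((a:1,b:1):0.4,(c:1,d:1):0.5):0.3,(e:1,f:1):0.6);")
  tab <- expected_cf_table(tr)
  ## add a spurious hybridization to the true tree
  set.seed(8)
  net <- NULL
  while (is.null(net) || !isTRUE(is_searchable(net, 1))) {
    ee <- sample(which(!tr$hybrid), 2)
    net <- add_hybridization(tr, ee[1], ee[2], gamma = 0.2, length = 0.3)
  }
  opt <- optimize_parameters(net, tab, weighting = "fractional", seed = 3)
  expect_true(length(c(opt$flags$gamma0, opt$flags$gamma1)) >= 1L ||
                min(opt$net$gamma[opt$net$hybrid]) < 1e-3)
})

test_that("star-tree data drives internal branch lengths to zero", {
  tr <- parse_enewick("(((a:1,b:1):0.4,(c:1,d:1):0.5):0.3,(e:1,f:1):0.6);")
  star_tab <- expected_cf_table(parse_enewick(
    "(((a:1,b:1):1e-9,(c:1,d:1):1e-9):1e-9,(e:1,f:1):1e-9);"))
  opt <- optimize_parameters(tr, star_tab, weighting = "fractional", seed = 4)
  expect_true(all(opt$net$length[opt$net$edge[, 2] > opt$net$ntax] < 1e-3))
  expect_true(length(opt$flags$tzero) >= 1L)
})

test_that("adding a hybrid edge never decreases the optimized score", {
  for (s in 1:6) {
    set.seed(s * 13)
    net <- rnetwork(6, 0)
    tab <- simulate_cf_table(net, 300, seed = s)
    base <- optimize_parameters(net, tab, seed = s)
    cand <- NULL
    tries <- 0
    while (tries < 50 && (is.null(cand) || !isTRUE(is_searchable(cand, 1)))) {
      tries <- tries + 1
      ee <- sample(which(!net$hybrid), 2)
      cand <- add_hybridization(net, ee[1], ee[2], gamma = 0.1, length = 0.2)
    }
    if (is.null(cand) || !isTRUE(is_searchable(cand, 1))) next
    withh <- optimize_parameters(cand, tab, seed = s)
    expect_gte(withh$score, base$score - 0.05)
  }
})

test_that("parameters are recovered from finite-sample CF tables", {
  ## simulated tables from a fixed 6-taxon single-hybridization network:
  ## median absolute errors of gamma-hat and of the identifiable branch
  ## lengths stay small (desk-scale version of the module's recovery check)
  net <- fix_diamond6(gamma = 0.3)
  con <- apply_identifiability_constraints(net)
  truth <- qcfnet:::map_get(con$net, con$map)
  kinds <- vapply(con$map, function(m) m$kind, "")
  scr <- net
  scr$length[scr$edge[, 2L] > scr$ntax] <- 0.5
  scr$gamma[scr$hybrid & !scr$major] <- 0.15
  scr$gamma[scr$hybrid & scr$major] <- 0.85
  gerr <- terr <- numeric(0)
  for (r in 1:10) {
    tab <- simulate_cf_table(net, 10000L, seed = 700L + r)
    opt <- optimize_parameters(scr, tab, seed = r, restarts = 1,
                               rhoend = 1e-6)
    gerr <- c(gerr, abs(opt$par[kinds == "gamma"] -
                          truth[kinds == "gamma"]))
    terr <- c(terr, abs(opt$par[kinds == "length"] -
                          truth[kinds == "length"]))
  }
  expect_lte(median(gerr), 0.05)
  expect_lte(median(terr), 0.2)
})
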