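test_that("trees and valid networks pass level-1 validation", {
  expect_length(validate_level1(parse_enewick("(A,(B,(C,D)));")), 0L)
  expect_length(validate_level1(fix_single()), 0L)
  expect_length(validate_level1(fix_double()), 0L)
  ## 7 taxa, two reticulations in separate cycles
  net7 <- parse_enewick(paste0(
    "(A,((B,((C:0.5,D:0.5):0.3)#H1:0.2::0.9),(#H1:1::0.1,",
    "((E,(F)#H2:1::0.5),(#H2:1::0.5,G)))));"))
  expect_length(validate_level1(net7), 0L)
  expect_equal(n_hybrids(net7), 2L)

  ## 7 taxa with one 3-cycle (hybridization between adjacent lineages) and
  ## one 4-cycle: cycle sizes {3, 4}
  net7b <- parse_enewick(paste0(
    "(A,((B,((C:0.5,D:0.5):0.3)#H1:0.2::0.9),(#H1:1::0.1,",
    "(E,((F:0.5)#H2:0.3::0.5,(#H2:0.4::0.5,G:0.8):0.3):0.5))));"))
  expect_length(validate_level1(net7b), 0L)
  expect_setequal(vapply(hybrid_cycles(net7b), function(x) x$k, 1L),
                  c(3L, 4L))
})

test_that("overlapping cycles violate level-1 and are reported", {
  ## two hybridizations targeting the same edge region so cycles share edges
  base <- parse_enewick("((a:1,b:1):1,(c:1,d:1):1,e:1);")
  n1 <- add_hybridization(base, 1, 3, gamma = 0.2, length = 0.1)
  ## second hybridization with donor inside the first cycle's tree path
  hit <- FALSE
  for (de in seq_len(nrow(n1$edge))) for (re in seq_len(nrow(n1$edge))) {
    if (n1$hybrid[de] || n1$hybrid[re] || de == re) next
    n2 <- add_hybridization(n1, de, re, gamma = 0.2, length = 0.1)
    if (is.null(n2)) next
    v <- validate_level1(n2)
    if (length(v)) {
      hit <- TRUE
      expect_match(paste(v, collapse = " "), "cycle")
    }
  }
  expect_true(hit)
})

test_that("hybrid cycles are measured and classified correctly", {
  hc <- hybrid_cycles(fix_single())
  expect_equal(hc[[1L]]$k, 3L)
  expect_equal(sort(hc[[1L]]$ns), c(1L, 1L, 2L))

  hc2 <- hybrid_cycles(fix_double())
  expect_equal(hc2[[1L]]$k, 2L)
  expect_equal(hc2[[1L]]$class, "cycle2")

  expect_equal(hybrid_cycles(fix_diamond6())[[1L]]$class, "diamond_good")
  expect_equal(hybrid_cycles(fix_bad2())[[1L]]$class, "diamond_bad_II")
  p <- fix_dir_pair()
  expect_equal(hybrid_cycles(p$bad1)[[1L]]$class, "diamond_bad_I")
  expect_equal(hybrid_cycles(p$good)[[1L]]$class, "diamond_good")
})

test_that("each hybrid gets exactly one class over many random networks", {
  for (s in 1:20) {
    net <- rnet_seeded(s, sample(5:8, 1L), sample(1:2, 1L))
    hcs <- hybrid_cycles(net)
    expect_length(hcs, n_hybrids(net))
    for (x in hcs) {
      expect_true(x$class %in% c("cycle2", "triangle_good", "triangle_other",
                                 "diamond_good", "diamond_bad_I",
                                 "diamond_bad_II", "k5plus"))
      expect_equal(sum(x$ns), net$ntax)
      expect_gte(x$k, 2L)
    }
  }
})

test_that("rooting with an outgroup respects hybrid edge directions", {
  net <- fix_single()   # c is the hybrid taxon
  expect_s3_class(root_with_outgroup(net, "a"), "phynet")
  expect_error(root_with_outgroup(net, "c"), "outgroup|invalid")
  tr <- parse_enewick("(A,(B,(C,D)));")
  for (tx in c("A", "B", "C", "D"))
    expect_s3_class(root_with_outgroup(tr, tx), "phynet")
})

test_that("major tree suppresses minor edges and keeps all taxa", {
  tr <- parse_enewick("(A,(B,(C,D)));")
  expect_true(phynet_equal(major_tree(tr), tr, check_numeric = FALSE))

  mt <- major_tree(fix_single())
  expect_equal(n_hybrids(mt), 0L)
  ## gamma = 0.3 on the minor edge: major tree is ab|cd
  ph <- as_phylo(mt)
  expect_equal(robinson_foulds(ph, ape::read.tree(text = "((a,b),(c,d));")),
               0L)

  big <- rnet_seeded(11, 15, 3)
  mb <- major_tree(big)
  expect_equal(mb$ntax, 15L)
  expect_equal(n_hybrids(mb), 0L)
  ## binary n-taxon tree: n - 3 internal edges after unrooting
  mbu <- qcfnet:::net_unroot(mb)
  internal <- sum(mbu$edge[, 2L] > mbu$ntax)
  expect_equal(internal, mbu$ntax - 3L)
})

test_that("identifiability constraints pin and reparameterize as designed", {
  ## good diamond: all cycle parameters free (map covers gamma + lengths)
  con <- apply_identifiability_constraints(fix_diamond6())
  kinds <- vapply(con$map, function(m) m$kind, "")
  expect_true("gamma" %in% kinds)
  expect_false("badI" %in% kinds)

  ## bad diamond I: two free products replace gamma and cycle tree edges
  p <- fix_dir_pair(gamma = 0.2)
  net <- qcfnet:::net_unroot(p$bad1)
  ## set the two cycle tree edges to 1 and 2 for the frozen arithmetic
  hc <- hybrid_cycles(net)[[1L]]
  tre <- setdiff(hc$cycle_edges, c(hc$major_edge, hc$minor_edge))
  pmin <- net$edge[hc$minor_edge, 1L]
  tmin_side <- tre[net$edge[tre, 1L] == pmin | net$edge[tre, 2L] == pmin][1L]
  tmaj_side <- setdiff(tre, tmin_side)[1L]
  net$length[tmin_side] <- 1; net$length[tmaj_side] <- 2
  con1 <- apply_identifiability_constraints(net)
  m <- con1$map[[which(vapply(con1$map, function(m) m$kind, "") == "badI")]]
  z <- qcfnet:::map_get(con1$net, list(m))
  expect_equal(z, c(0.2 * (1 - exp(-1)), 0.8 * (1 - exp(-2))),
               tolerance = 1e-10)
  expect_equal(round(z, 5), c(0.12642, 0.69173))

  ## bad diamond II: the hybrid's child edge is pinned to 0
  netb <- fix_bad2()
  conb <- apply_identifiability_constraints(netb)
  hcb <- hybrid_cycles(conb$net)[[1L]]
  ce <- which(conb$net$edge[, 1L] == hcb$hybrid)
  expect_equal(conb$net$length[ce], 0)

  ## 2-cycles are rejected from the search parameterization
  expect_error(apply_identifiability_constraints(fix_double()),
               "search")
})

test_that("bad diamond I representatives with equal products give equal CFs", {
  p <- fix_dir_pair(gamma = 0.25)
  net <- p$bad1
  con <- apply_identifiability_constraints(net)
  m <- con$map[[which(vapply(con$map, function(mm) mm$kind, "") == "badI")]]
  z <- c(0.11, 0.47)
  sets <- quartet_sets(net$labels)
  cfs <- list()
  for (gshift in c(0, 0.1)) {
    ## two different representatives of the same (z1, z2)
    g <- (z[1] + 1 - z[2]) / 2 + gshift
    lens <- ifelse(is.na(con$net$length), 1, con$net$length)
    gams <- con$net$gamma
    lens[m$tmin_side] <- -log(1 - z[1] / g)
    lens[m$tmaj_side] <- -log(1 - z[2] / (1 - g))
    gams[m$minor] <- g; gams[m$major] <- 1 - g
    net2 <- con$net
    net2$length <- lens; net2$gamma <- gams
    cfs[[length(cfs) + 1L]] <- t(apply(sets, 1L, function(tx)
      as.numeric(expected_cf(net2, tx))))
  }
  expect_equal(cfs[[1L]], cfs[[2L]], tolerance = 1e-10)
})

test_that("semi-directed hashes are invariant to rooting and representation", {
  net <- fix_diamond6()
  h0 <- sd_hash(net)
  r <- root_with_outgroup(net, "e")
  expect_equal(sd_hash(r), h0)
  back <- parse_enewick(write_enewick(net, root_at = "f"))
  expect_equal(sd_hash(back), h0)
  expect_false(sd_hash(fix_single()) == sd_hash(fix_double()))
})
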