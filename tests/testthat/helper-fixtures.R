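## Shared fixtures, all built in code.

## single-descendant hybrid (triangle k=3): taxon c is the hybrid;
## t1 = 1 (internal), t2 = 2 (cycle tree edge), gamma = 0.3
fix_single <- function(t1 = 1, t2 = 2, gamma = 0.3) {
  parse_enewick(sprintf(
    "(((a:1,b:1):%g,(c:0.5)#H1:1::%g):%g,(#H1:1::%g,d:1):%g);",
    t1, 1 - gamma, t2 * 0.6, gamma, t2 * 0.4))
}

## two-descendant hybrid (2-cycle on the internal edge): cherry (a,b) below
fix_double <- function(t1 = 0.9, t2 = 1.3, t3 = 1.1, t4 = 0.7, gamma = 0.2) {
  parse_enewick(sprintf(
    "((((a:1,b:1):%g)#H1:%g::%g,#H1:%g::%g):%g,c:1,d:1);",
    t1, t3, 1 - gamma, t4, gamma, t2))
}

## 6-taxon good diamond (hybrid above a; major parent subtends the bc cherry)
fix_diamond6 <- function(gamma = 0.3) {
  parse_enewick(sprintf(
    "((((a:0.5)#H1:0.3::%g,(b:1,c:1):0.6):0.5,(#H1:0.4::%g,d:1):0.7):0.4,(e:1,f:1):0.3);",
    1 - gamma, gamma))
}

## 5-taxon bad diamond II (cherry below the hybrid, child edge 0)
fix_bad2 <- function(gamma = 0.3) {
  parse_enewick(sprintf(
    "((((a:1,b:1):0.0)#H1:0.6::%g,c:1):0.8,(#H1:0.9::%g,d:1):0.5,e:1);",
    1 - gamma, gamma))
}

## the two 5-taxon diamonds of the direction-identifiability experiment:
## identical underlying unrooted topology (4-cycle with subtrees {a}, {b},
## {c}, {d1,d2} in the same cyclic order a-b-dd-c), differing only in which
## cycle node is the hybrid. In `bad1` the hybrid subtends {a} with the
## cherry opposite it (bad diamond I); in `good` the hybrid subtends {b}
## with the cherry on one of its parents (good diamond).
fix_dir_pair <- function(gamma = 0.3) {
  bad1 <- parse_enewick(sprintf(
    "((b:1,(a:0.4)#H1:0.4::%g):0.3,((d1:1,d2:1):0.5,(c:1,#H1:0.3::%g):0.8):0.2);",
    1 - gamma, gamma))
  good <- parse_enewick(sprintf(
    "((a:1,(b:0.4)#H1:0.4::%g):0.25,(c:1,((d1:1,d2:1):0.5,#H1:0.3::%g):0.35):0.45);",
    1 - gamma, gamma))
  list(good = good, bad1 = bad1)
}

## random level-1 network with reproducible seed
rnet_seeded <- function(seed, n, h, gamma = 0.3) {
  set.seed(seed)
  rnetwork(n, h, gamma = gamma)
}

## expected CFs recomputed by the enumeration engine under a given rooting
engine_cf_at_root <- function(net, taxa, root_node) {
  o <- qcfnet:::orient_network(net, root_node)
  w <- qcfnet:::wsn_suppress(qcfnet:::wsn_from_phynet(o))
  ## restrict to the 4 taxa first
  sub <- qcfnet:::extract_subnet(o, taxa)
  lens <- ifelse(is.na(o$length), 0, o$length)
  sub$len <- vapply(sub$prov, qcfnet:::resolve_len, 1,
                    lens = lens, gams = o$gamma)
  sub$gam <- ifelse(is.na(sub$gref), NA_real_, o$gamma[sub$gref])
  qcfnet:::engine_cf_wsn(sub)
}
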