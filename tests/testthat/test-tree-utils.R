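# Newick canonical serialization, Robinson-Foulds, rooting, consensus,
# bootstrap support, monophyly.

test_that("canonical Newick round-trips and is a fixed point", {
  txt <- "((A:1,B:2):1,(C:3,D:4):0);"
  tr <- parse_newick(txt)
  out <- write_newick(tr)
  expect_identical(write_newick(parse_newick(out)), out)
  star <- parse_newick("(A,B,C);")
  expect_identical(ape::Ntip(star), 3L)
  expect_identical(star$Nnode, 1L)
  set.seed(91)
  for (i in 1:40) {
    tr <- rand_unrooted(sample(4:10, 1))
    s1 <- write_newick(tr)
    expect_identical(write_newick(parse_newick(s1)), s1)
  }
  # children ordered by smallest descendant label
  expect_identical(write_newick(parse_newick("((D:4,C:3):0,(B:2,A:1):1);")),
                   write_newick(parse_newick(txt)))
})

test_that("Robinson-Foulds matches brute bipartition sets and phangorn", {
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,C),(B,D));")
  expect_identical(robinson_foulds(t1, t1), 0L)
  expect_identical(robinson_foulds(t1, t2), 2L)
  expect_error(robinson_foulds(t1, parse_newick("((A,B),(C,E));")),
               class = "cpcapture_input_error")
  set.seed(92)
  for (i in 1:50) {
    n <- sample(4:6, 1)
    a <- rand_unrooted(n)
    b <- rand_unrooted(n)
    b$tip.label <- a$tip.label[match(b$tip.label, sort(b$tip.label))]
    expect_identical(robinson_foulds(a, b),
                     as.integer(phangorn::RF.dist(a, b)))
    expect_identical(robinson_foulds(a, b), robinson_foulds(b, a))
  }
})

test_that("outgroup rooting halves the pendant edge and round-trips", {
  tr <- parse_newick("((A:1,B:2):1,(C:3,O:4):0.5);")
  rooted <- root_on_outgroup(tr, "O")
  expect_true(ape::is.rooted(rooted))
  kids <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1, 2]
  og_edge <- rooted$edge.length[rooted$edge[, 2] ==
                                  which(rooted$tip.label == "O")]
  expect_equal(og_edge, 2)          # midpoint of the 4-unit pendant edge
  expect_identical(robinson_foulds(ape::unroot(rooted), tr), 0L)
  set.seed(93)
  for (i in 1:20) {
    t0 <- rand_unrooted(7)
    og <- sample(t0$tip.label, 1)
    rr <- root_on_outgroup(t0, og)
    expect_identical(robinson_foulds(rr, t0), 0L)
  }
})

test_that("majority-rule consensus retains splits above threshold", {
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,C),(B,D));")
  cons <- majority_rule_consensus(c(rep(list(t1), 3), rep(list(t2), 2)))
  expect_identical(robinson_foulds(cons, t1), 0L)
  expect_equal(unname(attr(cons, "split_freq")), 0.6)
  same <- majority_rule_consensus(rep(list(t1), 4))
  expect_identical(robinson_foulds(same, t1), 0L)
  expect_true(all(attr(same, "split_freq") == 1))
  single <- majority_rule_consensus(list(t1))
  expect_identical(robinson_foulds(single, t1), 0L)
  # agreement with ape's consensus topology on random tree sets
  set.seed(94)
  trees <- lapply(1:9, function(i) rand_unrooted(6))
  base <- sort(trees[[1]]$tip.label)
  trees <- lapply(trees, function(tr) {
    tr$tip.label <- base[match(tr$tip.label, sort(tr$tip.label))]
    tr
  })
  mine <- majority_rule_consensus(trees)
  theirs <- ape::consensus(trees, p = 0.5)
  expect_identical(robinson_foulds(mine, theirs), 0L)
})

test_that("bootstrap support is deterministic and saturates on clean signal", {
  set.seed(95)
  anc <- rand_dna(300)
  nodeA <- evolve_sequence(anc, 0.2)
  nodeB <- evolve_sequence(anc, 0.2)
  aln <- c(A = evolve_sequence(nodeA, 0.02), B = evolve_sequence(nodeA, 0.02),
           C = evolve_sequence(nodeB, 0.02), D = evolve_sequence(nodeB, 0.02))
  tr1 <- bootstrap_support(aln, "nj", B = 100, seed = 7)
  tr2 <- bootstrap_support(aln, "nj", B = 100, seed = 7)
  expect_identical(write_newick(tr1), write_newick(tr2))
  expect_equal(split_support(tr1, c("A", "B")), 100)
  supp <- suppressWarnings(as.numeric(tr1$node.label))
  supp <- supp[!is.na(supp)]
  expect_true(all(supp >= 0 & supp <= 100))
})

test_that("monophyly is read from unrooted bipartitions", {
  sp <- c(a1 = "a", a2 = "a", b1 = "b", b2 = "b")
  good <- parse_newick("((a1,a2),(b1,b2));")
  expect_identical(monophyly_check(good, sp), c(a = TRUE, b = TRUE))
  bad <- parse_newick("((a1,b1),(a2,b2));")
  expect_identical(monophyly_check(bad, sp), c(a = FALSE, b = FALSE))
  single <- parse_newick("((a1,a2),(b1,c1));")
  sp2 <- c(a1 = "a", a2 = "a", b1 = "b", c1 = "c")
  expect_true(all(monophyly_check(single, sp2)))
  expect_error(monophyly_check(good, sp[1:3]),
               class = "cpcapture_input_error")
})
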