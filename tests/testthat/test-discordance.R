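# Fitch parsimony, capture flagging, Mantel test, clade composition,
# haplotype summaries.

test_that("Fitch parsimony counts minimum transitions", {
  sp <- c(a1 = "a", a2 = "a", b1 = "b", b2 = "b")
  expect_identical(fitch_parsimony(parse_newick("((a1,a2),(b1,b2));"), sp), 1L)
  expect_identical(fitch_parsimony(parse_newick("((a1,b1),(a2,b2));"), sp), 2L)
  expect_error(fitch_parsimony(parse_newick("((a1,a2),(b1,b2));"), sp[1:3]),
               class = "cpcapture_input_error")
})

test_that("Fitch equals brute force over internal assignments (random trees)", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(5:8, 1)
    tr <- rand_unrooted(n)
    char <- setNames(sample(letters[1:sample(2:4, 1)], n, replace = TRUE),
                     tr$tip.label)
    expect_identical(fitch_parsimony(tr, char),
                     as.integer(brute_fitch(tr, char)))
  }
})

test_that("Fitch score is invariant to re-rooting", {
  set.seed(102)
  tr <- rand_unrooted(8)
  char <- setNames(sample(c("a", "b", "c"), 8, replace = TRUE), tr$tip.label)
  ref <- fitch_parsimony(tr, char)
  for (tip in tr$tip.label) {
    expect_identical(fitch_parsimony(root_on_outgroup(tr, tip), char), ref)
  }
})

test_that("zero excess is equivalent to all-species monophyly", {
  set.seed(103)
  for (i in 1:60) {
    n <- sample(5:9, 1)
    tr <- rand_unrooted(n)
    char <- setNames(sample(c("a", "b"), n, replace = TRUE), tr$tip.label)
    if (length(unique(char)) < 2) next
    ex <- parsimony_excess(tr, char)
    expect_gte(ex, 0L)
    expect_identical(ex == 0L, all(monophyly_check(tr, char)))
  }
})

test_that("capture flagging hits a grafted foreign accession and nothing else", {
  # species-sorted plastome tree: no flags
  clean <- parse_newick(
    "(((a1:.1,a2:.1):1,(a3:.1,a4:.1):1):5,((b1:.1,b2:.1):1,(b3:.1,b4:.1):1):5);")
  sp <- setNames(rep(c("A", "B"), each = 4), c(paste0("a", 1:4),
                                               paste0("b", 1:4)))
  rep0 <- capture_candidates(clean, sp, k = 3)
  expect_false(any(rep0$flagged))
  expect_identical(attr(rep0, "excess"), 0L)
  # graft one B accession inside the A clade
  grafted <- parse_newick(
    "((((a1:.1,b4:.1):1,a2:.1):1,(a3:.1,a4:.1):1):5,((b1:.1,b2:.1):1,b3:1):5);")
  rep1 <- capture_candidates(grafted, sp, k = 3)
  expect_identical(rep1$id[rep1$flagged], "b4")
  expect_identical(attr(rep1, "excess"), 1L)
  expect_error(capture_candidates(clean, sp, k = 8),
               class = "cpcapture_input_error")
  # tidy/glance accessors
  expect_identical(nrow(tidy(rep1)), 8L)
  expect_identical(glance(rep1)$n_flagged, 1L)
})

test_that("Mantel statistic and p behave at the extremes and reproduce", {
  set.seed(104)
  xy <- cbind(runif(15), runif(15))
  D1 <- as.matrix(dist(xy))
  dimnames(D1) <- list(letters[1:15], letters[1:15])
  m <- mantel_test(D1, D1, n_perm = 99, seed = 5)
  expect_equal(m$r, 1.0)
  expect_equal(m$p, 1 / 100)
  m2 <- mantel_test(D1, D1, n_perm = 99, seed = 5)
  expect_identical(m, m2)
  expect_error(mantel_test(D1, D1[1:10, 1:10]),
               class = "cpcapture_input_error")
  expect_error(mantel_test(D1, D1, n_perm = 10),
               class = "cpcapture_input_error")
})

test_that("Mantel r agrees with vegan and permutation order is respected", {
  set.seed(105)
  D1 <- as.matrix(dist(cbind(runif(12), runif(12))))
  D2 <- as.matrix(dist(cbind(runif(12), runif(12))))
  dimnames(D1) <- dimnames(D2) <- list(letters[1:12], letters[1:12])
  mine <- mantel_test(D1, D2, n_perm = 199, seed = 1)
  veg <- vegan::mantel(D1, D2, permutations = 199)
  expect_equal(mine$r, unname(veg$statistic), tolerance = 1e-12)
  # label alignment: shuffling D2's storage order must not change r
  perm <- sample(12)
  D2s <- D2[perm, perm]
  expect_equal(mantel_test(D1, D2s, n_perm = 99, seed = 1)$r, mine$r)
})

test_that("clade composition tallies are conserved and mixed clades marked", {
  tr <- parse_newick("(((a1,a2),(a3,b3)),(b1,b2));")
  sp <- c(a1 = "A", a2 = "A", a3 = "A", b3 = "B", b1 = "B", b2 = "B")
  comp <- clade_species_composition(tr, sp)
  expect_gt(nrow(comp), 0)
  sums <- comp$n_in + comp$n_out
  totals <- table(sp)
  expect_true(all(sums == totals[comp$species]))
  mixed_edges <- unique(comp$edge_key[comp$mixed])
  # the (a3,b3) cherry is a mixed clade
  key_a3b3 <- comp$edge_key[comp$clade_size == 2 &
                              comp$species == "A" & comp$n_in == 1][1]
  expect_true(key_a3b3 %in% mixed_edges)
})

test_that("haplotype summary reproduces the one-divergent-accession pattern", {
  base <- strrep("ACGT", 25)
  seqs <- setNames(rep(base, 23), sprintf("m%02d", 1:23))
  odd <- base
  substr(odd, 7, 7) <- "T"
  substr(odd, 50, 50) <- "A"
  seqs["m23"] <- odd
  hs <- haplotype_summary(seqs)
  expect_identical(hs$n_haplotypes, 2L)
  expect_true(all(hs$differences["m23", -23] == 2))
  expect_identical(max(hs$differences), 2L)
  expect_identical(haplotype_summary(seqs[1:22])$n_haplotypes, 1L)
  distinct <- setNames(c("AAAA", "AAAC", "AACC", "ACCC"), letters[1:4])
  expect_identical(haplotype_summary(distinct)$n_haplotypes, 4L)
})
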