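# Translated search, single-hit selection, cross-database intersection,
# tabular import.

test_that("self-hit scores the BLOSUM62 diagonal sum with identity 1", {
  set.seed(31)
  cds <- rand_dna(60)
  prot <- translate_cds(cds)
  hits <- translated_search(c(q1 = prot), c(s1 = cds), min_score = 10)
  expect_identical(nrow(hits), 1L)
  S <- get_blosum62()
  aa <- strsplit(prot, "")[[1]]
  expect_equal(hits$score, sum(S[cbind(aa, aa)]))
  expect_equal(hits$identity, 1.0)
  expect_identical(hits$aln_length, nchar(prot))
})

test_that("internal aligner agrees with an independent Gotoh implementation", {
  set.seed(32)
  for (i in 1:12) {
    a <- rand_aa(sample(4:8, 1))
    b <- rand_aa(sample(4:8, 1))
    got <- sw_gotoh(a, b)
    bs <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    # Biostrings reports the (possibly negative) best single-pair score;
    # the local optimum over substrings is max(0, .)
    expect_equal(max(0, bs), got, info = paste(a, b))
  }
})

test_that("duplicated subjects yield two equal-score hits; misses yield none", {
  set.seed(33)
  cds <- rand_dna(90)
  prot <- translate_cds(cds)
  hits <- translated_search(c(q1 = prot), c(copy1 = cds, copy2 = cds),
                            min_score = 10)
  expect_identical(nrow(hits), 2L)
  expect_equal(hits$score[1], hits$score[2])
  # an unrelated query scoring below threshold produces no hits
  none <- translated_search(c(q2 = rand_aa(25)), c(s = cds),
                            min_score = 1e6)
  expect_identical(nrow(none), 0L)
  # empty database is not an error
  empty <- translated_search(c(q1 = prot), character(0))
  expect_identical(nrow(empty), 0L)
  expect_error(translated_search(c(q = "MK!"), c(s = cds)),
               class = "cpcapture_input_error")
})

test_that("single-hit selection counts distinct subjects, order-invariantly", {
  hits <- tibble::tibble(
    query_id = c("q1", "q2", "q2", "q3", "q3"),
    subject_id = c("s1", "s2", "s3", "s4", "s4"),
    score = c(100, 90, 80, 70, 60))
  expect_identical(select_single_hit_queries(hits), c("q1", "q3"))
  shuffled <- hits[c(4, 2, 5, 1, 3), ]
  expect_identical(select_single_hit_queries(shuffled), c("q1", "q3"))
  expect_identical(select_single_hit_queries(hits[0, ]), character(0))
})

test_that("intersection across references keeps panel order and errors when empty", {
  panel <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                          sequence = rep("ATG", 4))
  out <- intersect_across_references(list(c("a", "b", "c"), c("c", "b", "d")),
                                     panel)
  expect_identical(out$gene_id, c("b", "c"))
  one <- intersect_across_references(list(c("d", "a")), panel)
  expect_identical(one$gene_id, c("a", "d"))
  expect_error(
    intersect_across_references(list("a", "b"), panel),
    regexp = "no shared single-copy genes",
    class = "cpcapture_selection_error")
})

test_that("a gene duplicated in one of several reference genomes is excluded", {
  cfg <- simulation_config(seed = 41, n_genes = 8, gene_length = 120,
                           cp_length = 1500, n_accessions_per_species = 2,
                           n_duplicate_genes = 2)
  d <- simulate_dataset(cfg)
  sel <- select_gene_panel(d$panel, d$reference_dbs, min_score = 40)
  expect_identical(sel$gene_id, d$truth$single_copy_genes)
})

test_that("12-column tabular hits round-trip and malformed rows are located", {
  set.seed(34)
  hits <- tibble::tibble(
    query_id = sprintf("q%03d", 1:100),
    subject_id = sprintf("s%03d", sample(100)),
    identity = round(runif(100), 4),
    aln_length = sample.int(500, 100),
    score = round(runif(100, 30, 400), 4))
  f <- tempfile(fileext = ".tsv")
  write_tabular_hits(hits, f)
  back <- import_tabular_hits(f)
  expect_equal(back, hits)

  empty <- tempfile()
  file.create(empty)
  expect_identical(nrow(import_tabular_hits(empty)), 0L)

  bad <- tempfile()
  writeLines(c(readLines(f)[1], "q1\ts1\tnot_enough_columns"), bad)
  expect_error(import_tabular_hits(bad), regexp = "line 2",
               class = "cpcapture_format_error")
})
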