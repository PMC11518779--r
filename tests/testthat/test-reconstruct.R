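# IUPAC reconstruction and supermatrix assembly.

test_that("apply_variants substitutes alleles and IUPAC codes", {
  het <- tibble::tibble(gene_id = "g", pos = 2L, ref = "T", alleles = "A/G",
                        freqs = "0.5/0.5", zygosity = "heterozygous",
                        depth = 10)
  expect_identical(apply_variants("ATG", het, gene_id = "g"), "ARG")
  hom <- tibble::tibble(gene_id = "g", pos = 2L, ref = "T", alleles = "C",
                        freqs = "1", zygosity = "homozygous", depth = 10)
  expect_identical(apply_variants("ATG", hom, gene_id = "g"), "ACG")
  # empty table is the identity
  expect_identical(apply_variants("ATG", het[0, ], gene_id = "g"), "ATG")
  # reference mismatch is a consistency error naming the position
  bad <- dplyr::mutate(het, ref = "C")
  expect_error(apply_variants("ATG", bad, gene_id = "g"), regexp = "pos 2",
               class = "cpcapture_consistency_error")
  # major-allele haploidization picks the higher-frequency allele
  skew <- dplyr::mutate(het, freqs = "0.3/0.7")
  expect_identical(apply_variants("ATG", skew, gene_id = "g",
                                  haploidize = "major"), "AGG")
})

test_that("concatenation follows panel order regardless of input order", {
  set.seed(61)
  panel <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                          sequence = c(rand_dna(300), rand_dna(450),
                                       rand_dna(750)))
  per_gene <- setNames(panel$sequence, panel$gene_id)
  cc <- concatenate_genes(per_gene, panel)
  expect_identical(nchar(cc$sequence), 1500L)
  expect_identical(cc$blocks$start, c(0L, 300L, 750L))
  expect_identical(cc$blocks$end, c(300L, 750L, 1500L))
  for (i in 1:5) {
    perm <- sample(per_gene)
    expect_identical(concatenate_genes(perm, panel)$sequence, cc$sequence)
  }
  one <- concatenate_genes(per_gene["g2"], panel[2, ])
  expect_identical(one$sequence, per_gene[["g2"]])
  expect_error(concatenate_genes(per_gene[1:2], panel),
               regexp = "g3", class = "cpcapture_completeness_error")
})

test_that("supermatrix dimensions and ambiguity counts are conserved", {
  set.seed(62)
  panel <- tibble::tibble(gene_id = c("g1", "g2"),
                          sequence = c(rand_dna(120), rand_dna(90)))
  empty <- call_gene(tibble::tibble(gene_id = character(0), pos = integer(0),
                                    ref = character(0), nA = integer(0),
                                    nC = integer(0), nG = integer(0),
                                    nT = integer(0)))
  het <- tibble::tibble(gene_id = "g1", pos = 5L,
                        ref = substr(panel$sequence[1], 5, 5),
                        alleles = "A/C", freqs = "0.5/0.5",
                        zygosity = "heterozygous", depth = 12)
  # keep the call reference-consistent
  substr(panel$sequence[1], 5, 5) <- "A"
  het$ref <- "A"
  sm <- build_supermatrix(c("acc1", "acc2"), panel,
                          list(acc1 = empty, acc2 = het))
  expect_identical(unname(nchar(sm$sequences)), c(210L, 210L))
  ref_row <- paste(panel$sequence, collapse = "")
  expect_identical(unname(sm$sequences["acc1"]), ref_row)
  diff <- which(strsplit(sm$sequences[["acc2"]], "")[[1]] !=
                  strsplit(ref_row, "")[[1]])
  expect_identical(diff, 5L)
  expect_identical(substr(sm$sequences[["acc2"]], 5, 5), "M")
})

test_that("ambiguity columns correspond one-to-one to heterozygous calls", {
  set.seed(63)
  panel <- tibble::tibble(gene_id = "g1", sequence = rand_dna(600))
  refchars <- strsplit(panel$sequence, "")[[1]]
  pos <- sort(sample.int(600, 25))
  zyg <- sample(c("heterozygous", "homozygous"), 25, replace = TRUE)
  other <- vapply(refchars[pos], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  calls <- tibble::tibble(
    gene_id = "g1", pos = pos, ref = refchars[pos],
    alleles = ifelse(zyg == "heterozygous",
                     paste(pmin(refchars[pos], other), "/",
                           pmax(refchars[pos], other), sep = ""),
                     other),
    freqs = ifelse(zyg == "heterozygous", "0.5/0.5", "1"),
    zygosity = zyg, depth = 20)
  rec <- apply_variants(panel$sequence, calls, gene_id = "g1")
  n_ambig <- sum(!strsplit(rec, "")[[1]] %in% c("A", "C", "G", "T"))
  expect_identical(n_ambig, sum(zyg == "heterozygous"))
})

test_that("diploid consensus encodes het sites as ambiguity codes", {
  expect_identical(diploid_consensus("ATGC", "ATGC"), "ATGC")
  expect_identical(diploid_consensus("ATGC", "GTGT"), "RTGY")
  expect_error(diploid_consensus("AT", "A"), class = "cpcapture_input_error")
})

test_that("error-free round-trip misses are exactly band-tail het sites", {
  set.seed(65)
  cfg <- caller_config()
  for (g in 1:100) {
    L <- 300
    ref <- rand_dna(L)
    h1 <- evolve_sequence(ref, 0.002)
    h2v <- strsplit(h1, "")[[1]]
    het <- which(runif(L) < 0.01)
    for (i in het) h2v[i] <- sample(setdiff(c("A", "C", "G", "T"), h2v[i]), 1)
    h2 <- paste(h2v, collapse = "")
    pu <- simulate_gene_pileup(h1, h2, ref, mean_depth = 25, error_rate = 0)
    rec <- strsplit(apply_variants(ref, call_gene(pu, cfg),
                                   gene_id = "g001"), "")[[1]]
    tv <- strsplit(diploid_consensus(h1, h2), "")[[1]]
    depth <- pu$nA + pu$nC + pu$nG + pu$nT
    cm <- cbind(pu$nA, pu$nC, pu$nG, pu$nT)
    hom_bad <- 0L
    het_unexplained <- 0L
    for (i in which(depth >= 10)) {
      if (tv[i] %in% c("A", "C", "G", "T")) {
        # homozygous truth (ref or substituted) is always recovered
        hom_bad <- hom_bad + (rec[i] != tv[i])
      } else if (rec[i] != tv[i]) {
        # a missed het must be a site whose sampled frequencies fail the
        # caller's own band/count filter — never any other cause
        cnt <- sort(cm[i, ], decreasing = TRUE)[1:2]
        f <- cnt / depth[i]
        het_unexplained <- het_unexplained +
          !(cnt[2] < 3 || f[2] < 0.25 || f[1] > 0.75)
      }
    }
    expect_identical(hom_bad, 0L)
    expect_identical(het_unexplained, 0L)
  }
})

test_that("default-scale supermatrix arithmetic holds", {
  cfg <- simulation_config(seed = 64, n_genes = 5, gene_length = 120,
                           cp_length = 1500, n_accessions_per_species = 3)
  d <- simulate_dataset(cfg)
  sm <- build_supermatrix(
    d$accessions$id, d$panel,
    setNames(rep(list(call_gene(tibble::tibble(
      gene_id = character(0), pos = integer(0), ref = character(0),
      nA = integer(0), nC = integer(0), nG = integer(0), nT = integer(0)))),
      nrow(d$accessions)), d$accessions$id),
    extra_rows = setNames(list(d$outgroup_nuclear), "OUT"))
  expect_identical(length(sm$sequences), 13L)   # 12 ingroup + outgroup
  expect_identical(unique(nchar(sm$sequences)), 600L)
  expect_identical(sum(sm$blocks$end - sm$blocks$start), 600L)
})
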