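# Synthetic data generator: substitution engine, determinism, capture
# bookkeeping, geography, pileup sampling.

test_that("evolve_sequence follows the JC69 expected-change curve", {
  set.seed(11)
  anc <- rand_dna(10000)
  expect_identical(evolve_sequence(anc, 0), anc)

  # saturation: difference fraction -> 3/4
  der <- evolve_sequence(anc, 50)
  pdiff <- mean(strsplit(anc, "")[[1]] != strsplit(der, "")[[1]])
  se <- sqrt(0.75 * 0.25 / 10000)
  expect_lt(abs(pdiff - 0.75), 3 * se)

  # mid-branch closed form at t = 0.1 over 100 kb
  anc2 <- rand_dna(1e5)
  der2 <- evolve_sequence(anc2, 0.1)
  p_exp <- 0.75 * (1 - exp(-0.4 / 3))
  p_obs <- mean(strsplit(anc2, "")[[1]] != strsplit(der2, "")[[1]])
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 1e5))

  expect_error(evolve_sequence(anc, -0.1), class = "cpcapture_input_error")
})

test_that("simulation is deterministic and validates its configuration", {
  cfg <- simulation_config(seed = 3, n_genes = 4, gene_length = 120,
                           cp_length = 1500, n_accessions_per_species = 4)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1, d2)

  expect_error(simulation_config(het_rate = 1.2),
               regexp = "het_rate", class = "cpcapture_config_error")
  expect_error(simulation_config(gene_length = 100),
               regexp = "gene_length", class = "cpcapture_config_error")
  expect_error(simulation_config(n_capture_events = 1000),
               regexp = "n_capture_events", class = "cpcapture_config_error")
})

test_that("capture injection is conserved and cross-consistent", {
  cfg0 <- simulation_config(seed = 1, n_genes = 3, gene_length = 120,
                            cp_length = 1500)
  d0 <- simulate_dataset(cfg0)
  expect_false(any(d0$truth$capture_flags))
  expect_true(all(is.na(d0$accessions$captured_from)))

  cfg5 <- simulation_config(seed = 7, n_capture_events = 5, n_genes = 3,
                            gene_length = 120, cp_length = 1500)
  d5 <- simulate_dataset(cfg5)
  expect_identical(sum(d5$truth$capture_flags), 5L)
  hap <- d5$truth$haplotypes
  cap <- hap[!is.na(hap$captured_from), ]
  expect_identical(nrow(cap), 5L)
  # captured accessions carry a haplotype lineage of the donor, never their own
  expect_true(all(cap$captured_from != cap$species))
  expect_true(all(startsWith(cap$haplotype_lineage, cap$captured_from)))
  # flags agree with the haplotype table
  expect_setequal(hap$id[!is.na(hap$captured_from)],
                  names(which(d5$truth$capture_flags)))
})

test_that("between-species plastome distance grows with the divergence knob", {
  means <- vapply(c(0.002, 0.01, 0.05), function(db) {
    cfg <- simulation_config(seed = 5, n_genes = 2, gene_length = 120,
                             cp_length = 4000, n_accessions_per_species = 4,
                             cp_divergence_between_species = db)
    d <- simulate_dataset(cfg)
    sp <- species_map_of(d)
    D <- seq_dist(d$cp[names(sp)], model = "p")
    between <- outer(sp, sp, "!=")
    mean(D[between])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("a fully captured species is plastome-indistinguishable from the donor", {
  ids <- sprintf("S1_%02d", 1:4)
  cfg <- simulation_config(seed = 9, n_accessions_per_species = 4,
                           n_genes = 2, gene_length = 120, cp_length = 3000,
                           n_capture_events = 4, capture_accessions = ids,
                           capture_donor_species = "S2")
  d <- simulate_dataset(cfg)
  hap <- d$truth$haplotypes
  expect_true(all(hap$captured_from[hap$id %in% ids] == "S2"))
  # every S1 plastome now sits inside the S2 haplotype radiation
  sp <- species_map_of(d)
  D <- seq_dist(d$cp[names(sp)], model = "p")
  d_s1_s2 <- mean(D[ids, setdiff(names(sp)[sp == "S2"], ids)])
  d_s2_s3 <- mean(D[names(sp)[sp == "S2"], names(sp)[sp == "S3"]])
  expect_lt(d_s1_s2, d_s2_s3 / 3)
})

test_that("pileup sampling matches its Poisson/binomial model", {
  set.seed(21)
  # heterozygous A/G site replicated: allele balance ~ Binomial(depth, 1/2)
  L <- 20000
  h1 <- paste(rep("A", L), collapse = "")
  h2 <- paste(rep("G", L), collapse = "")
  pu <- simulate_gene_pileup(h1, h2, h1, mean_depth = 10, error_rate = 0)
  expect_true(all(pu$nC == 0 & pu$nT == 0))
  fA <- sum(pu$nA) / sum(pu$nA + pu$nG)
  expect_lt(abs(fA - 0.5), 3 * sqrt(0.25 / sum(pu$nA + pu$nG)))
  # mean depth ~ Poisson(10)
  depth <- pu$nA + pu$nG
  expect_lt(abs(mean(depth) - 10), 3 * sqrt(10 / L))

  # homozygous error-free site: all reads carry the base
  pu2 <- simulate_gene_pileup(h1, h1, h2, mean_depth = 8, error_rate = 0)
  expect_true(all(pu2$nG + pu2$nC + pu2$nT == 0))

  # error reads land on other bases at the configured rate
  pu3 <- simulate_gene_pileup(h1, h1, h1, mean_depth = 20, error_rate = 0.05)
  tot <- sum(pu3$nA + pu3$nC + pu3$nG + pu3$nT)
  err <- sum(pu3$nC + pu3$nG + pu3$nT)
  expect_lt(abs(err / tot - 0.05), 3 * sqrt(0.05 * 0.95 / tot))
})

test_that("dataset-level pileups are deterministic and per-species referenced", {
  cfg <- simulation_config(seed = 13, n_genes = 2, gene_length = 90,
                           cp_length = 1500, n_accessions_per_species = 3)
  d <- simulate_dataset(cfg)
  p1 <- simulate_pileups(d)
  p2 <- simulate_pileups(d)
  expect_identical(p1, p2)
  expect_setequal(names(p1), d$accessions$id)
  # the ref column is the accession's own-species reference
  id <- d$accessions$id[1]
  s <- d$accessions$species[1]
  expect_identical(paste(p1[[id]]$ref[p1[[id]]$gene_id == "g001"],
                         collapse = ""),
                   d$species_seqs[["g001"]][[s]])
})
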