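# Synthetic four-species + outgroup data generator with known ground truth:
# diploid nuclear genes on a fixed species topology, geographically
# structured chloroplast haplotypes, injected capture events, and per-site
# read-count pileups.

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate a wild four-species tree-crop system: four ingroup
#' species on the fixed topology ((S1,S2),(S3,S4)) plus an outgroup, tens of
#' accessions per species, a panel of 53 single-copy nuclear coding genes,
#' diploid heterozygosity, uniparental (haploid) plastomes whose haplotypes
#' cluster by species and by geography, and sequencing depth around 25x.
#'
#' @param seed integer seed; the whole dataset is a deterministic function of
#'   the configuration.
#' @param n_accessions_per_species sampled trees per ingroup species.
#' @param species_names five labels: four ingroup species then the outgroup.
#' @param branch_lengths list with elements `internal`, `species_tip`,
#'   `outgroup`, `within_species` (substitutions/site) for the nuclear genes.
#' @param n_genes number of nuclear genes in the reference panel.
#' @param gene_length gene length in bp (multiple of 3).
#' @param het_rate probability that a site is heterozygous within an
#'   accession.
#' @param cp_length plastome proxy length in bp (scaled stand-in for the
#'   ~159.5 kb plastome).
#' @param cp_divergence_between_species,cp_divergence_within_species plastome
#'   divergence scales (subs/site): species-level branch scale and
#'   haplotype-founder depth within species. Accessions additionally carry
#'   private plastome mutations at one fifth of the within-species scale.
#' @param n_capture_events number of ingroup accessions whose plastome is
#'   replaced by a lineage captured from the geographically nearest other
#'   species.
#' @param capture_accessions optional explicit accession ids to capture
#'   (length must equal `n_capture_events`); default: a seeded random sample.
#' @param capture_donor_species optional fixed donor species label overriding
#'   the nearest-species rule (useful for degenerate scenarios).
#' @param mean_depth expected per-site sequencing coverage (Poisson mean).
#' @param depth_range optional length-2 vector; when set, each accession gets
#'   its own mean depth drawn uniformly from this range (e.g. the 16.47-43.98x
#'   per-sample spread seen in real short-read data).
#' @param error_rate per-base miscall probability in the pileups.
#' @param geography list with `centers` (4 x 2 matrix of ingroup region
#'   centers), `site_sigma` (spread of population sites around the region
#'   center), `dispersal_sigma` (spread of accessions around their site) and
#'   `n_sites_per_species`.
#' @param cp_spatial_autocorrelation assign haplotype founders to spatially
#'   contiguous blocks of sites (`TRUE`) or at random (`FALSE`).
#' @param n_cp_haplotypes haplotype founders per species.
#' @param n_duplicate_genes how many panel genes get a diverged second copy
#'   planted into one per-species reference CDS database (cycling across
#'   species); these genes are not single-copy and must be excluded by
#'   ortholog selection.
#' @return a `cpcapture_config` list.
#' @export
simulation_config <- function(seed = 1,
                              n_accessions_per_species = 10,
                              species_names = c("S1", "S2", "S3", "S4", "OUT"),
                              branch_lengths = list(internal = 0.005,
                                                    species_tip = 0.01,
                                                    outgroup = 0.06,
                                                    within_species = 0.001),
                              n_genes = 53,
                              gene_length = 501,
                              het_rate = 0.002,
                              cp_length = 20000,
                              cp_divergence_between_species = 0.01,
                              cp_divergence_within_species = 0.001,
                              n_capture_events = 0,
                              capture_accessions = NULL,
                              capture_donor_species = NULL,
                              mean_depth = 25,
                              depth_range = NULL,
                              error_rate = 0.001,
                              geography = list(
                                centers = matrix(c(0, 0, 20, 0, 0, 20, 20, 20),
                                                 ncol = 2, byrow = TRUE),
                                site_sigma = 3,
                                dispersal_sigma = 0.5,
                                n_sites_per_species = 4),
                              cp_spatial_autocorrelation = TRUE,
                              n_cp_haplotypes = 3,
                              n_duplicate_genes = 0) {
  cfg <- list(seed = seed,
              n_accessions_per_species = n_accessions_per_species,
              species_names = species_names,
              branch_lengths = branch_lengths,
              n_genes = n_genes, gene_length = gene_length,
              het_rate = het_rate, cp_length = cp_length,
              cp_divergence_between_species = cp_divergence_between_species,
              cp_divergence_within_species = cp_divergence_within_species,
              n_capture_events = n_capture_events,
              capture_accessions = capture_accessions,
              capture_donor_species = capture_donor_species,
              mean_depth = mean_depth, depth_range = depth_range,
              error_rate = error_rate, geography = geography,
              cp_spatial_autocorrelation = cp_spatial_autocorrelation,
              n_cp_haplotypes = n_cp_haplotypes,
              n_duplicate_genes = n_duplicate_genes)
  validate_config(cfg)
  structure(cfg, class = "cpcapture_config")
}

validate_config <- function(cfg) {
  bad <- function(field, why) {
    abort(sprintf("invalid configuration field '%s': %s", field, why),
          class = "cpcapture_config_error")
  }
  chk_rate <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || v < 0 || v >= 1) bad(field, "must be in [0, 1)")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) bad("seed", "one integer")
  if (length(cfg$species_names) != 5 || anyDuplicated(cfg$species_names)) {
    bad("species_names", "needs 5 distinct labels (4 ingroup + outgroup)")
  }
  if (cfg$n_genes < 1) bad("n_genes", "must be >= 1")
  if (cfg$gene_length %% 3 != 0 || cfg$gene_length < 3) {
    bad("gene_length", "must be a positive multiple of 3")
  }
  for (f in c("het_rate", "error_rate", "cp_divergence_between_species",
              "cp_divergence_within_species")) chk_rate(f)
  for (f in names(cfg$branch_lengths)) {
    if (cfg$branch_lengths[[f]] < 0) {
      bad(paste0("branch_lengths$", f), "must be >= 0")
    }
  }
  total <- 4 * cfg$n_accessions_per_species
  if (cfg$n_capture_events < 0 || cfg$n_capture_events > total) {
    bad("n_capture_events", "must be between 0 and the ingroup size")
  }
  if (!is.null(cfg$capture_accessions) &&
      length(cfg$capture_accessions) != cfg$n_capture_events) {
    bad("capture_accessions", "length must equal n_capture_events")
  }
  if (!is.null(cfg$capture_donor_species) &&
      !cfg$capture_donor_species %in% cfg$species_names[1:4]) {
    bad("capture_donor_species", "must be an ingroup species label")
  }
  if (cfg$mean_depth <= 0) bad("mean_depth", "must be > 0")
  if (!is.null(cfg$depth_range) &&
      (length(cfg$depth_range) != 2 || any(cfg$depth_range <= 0))) {
    bad("depth_range", "needs two positive values")
  }
  if (cfg$n_cp_haplotypes < 1) bad("n_cp_haplotypes", "must be >= 1")
  if (cfg$n_duplicate_genes < 0 || cfg$n_duplicate_genes > cfg$n_genes) {
    bad("n_duplicate_genes", "must be between 0 and n_genes")
  }
  invisible(cfg)
}

random_dna <- function(length) {
  decode_seq(sample.int(4L, length, replace = TRUE))
}

#' Evolve a sequence along a branch
#'
#' Jukes-Cantor substitution: each site changes with probability
#' (3/4)(1 - exp(-4t/3)), uniformly to one of the other three bases. Uses the
#' current RNG state.
#'
#' @param ancestor IUPAC-free nucleotide string (A/C/G/T only).
#' @param branch_length expected substitutions per site (>= 0).
#' @param model substitution model; only `"JC69"` is implemented.
#' @return the descendant sequence (same length).
#' @export
evolve_sequence <- function(ancestor, branch_length, model = "JC69") {
  model <- match.arg(model, "JC69")
  if (branch_length < 0) {
    abort("branch_length must be >= 0", class = "cpcapture_input_error")
  }
  x <- encode_seq(ancestor)
  if (any(x > 4)) {
    abort("ancestor must be unambiguous A/C/G/T",
          class = "cpcapture_input_error")
  }
  p <- 0.75 * (1 - exp(-4 * branch_length / 3))
  hit <- which(runif(length(x)) < p)
  if (length(hit) > 0) {
    # new base: one of the 3 others, uniformly
    x[hit] <- ((x[hit] - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
  }
  decode_seq(x)
}

# mutate exactly the given sites to a different random base (het injection)
mutate_sites <- function(seq_int, sites) {
  if (length(sites) > 0) {
    seq_int[sites] <- ((seq_int[sites] - 1L +
                          sample.int(3L, length(sites), replace = TRUE)) %% 4L) + 1L
  }
  seq_int
}

#' Generate the synthetic dataset
#'
#' Deterministic given the configuration (which includes the seed). Nuclear
#' genes evolve on the fixed species topology ((S1,S2),(S3,S4)) with the
#' outgroup attached at the root; each accession adds a short private branch
#' plus Bernoulli heterozygous sites. Plastomes are haploid: each species has
#' `n_cp_haplotypes` founder lineages assigned to geographically contiguous
#' blocks of accessions; captured accessions instead descend from a founder of
#' the nearest other species.
#'
#' @param config a [simulation_config()].
#' @return a `cpcapture_dataset` list with elements `accessions` (metadata
#'   tibble), `panel` (reference CDS tibble), `reference_dbs` (per-species CDS
#'   databases), `nuclear` (per-gene diploid haplotypes), `outgroup_nuclear`,
#'   `cp` (per-accession plastome sequences incl. outgroup), `truth`
#'   (species tree, per-gene trees, capture flags, haplotype table) and
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  validate_config(config)
  with_local_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  sp <- cfg$species_names[1:4]
  og <- cfg$species_names[5]
  bl <- cfg$branch_lengths
  n_acc <- cfg$n_accessions_per_species
  acc_ids <- unlist(lapply(sp, function(s) sprintf("%s_%02d", s, seq_len(n_acc))))
  acc_species <- rep(sp, each = n_acc)
  names(acc_species) <- acc_ids
  gene_ids <- sprintf("g%03d", seq_len(cfg$n_genes))

  # ---- geography ----
  geo <- cfg$geography
  centers <- geo$centers
  rownames(centers) <- sp
  n_sites <- geo$n_sites_per_species
  site_xy <- list()
  for (s in seq_along(sp)) {
    site_xy[[sp[s]]] <- cbind(
      rnorm(n_sites, centers[s, 1], geo$site_sigma),
      rnorm(n_sites, centers[s, 2], geo$site_sigma))
  }
  site_of <- integer(length(acc_ids))
  xy <- matrix(0, length(acc_ids), 2)
  for (i in seq_along(acc_ids)) {
    s <- acc_species[i]
    k <- ((match(acc_ids[i], acc_ids[acc_species == s]) - 1) %% n_sites) + 1
    site_of[i] <- (match(s, sp) - 1) * n_sites + k
    xy[i, ] <- site_xy[[s]][k, ] + rnorm(2, 0, geo$dispersal_sigma)
  }

  # ---- nuclear genes on the fixed topology ----
  species_seqs <- vector("list", cfg$n_genes)
  nuclear <- vector("list", cfg$n_genes)
  outgroup_nuclear <- character(cfg$n_genes)
  names(species_seqs) <- names(nuclear) <- names(outgroup_nuclear) <- gene_ids
  for (g in seq_len(cfg$n_genes)) {
    anc <- random_dna(cfg$gene_length)
    nodeA <- evolve_sequence(anc, bl$internal)
    nodeB <- evolve_sequence(anc, bl$internal)
    sseq <- c(evolve_sequence(nodeA, bl$species_tip),
              evolve_sequence(nodeA, bl$species_tip),
              evolve_sequence(nodeB, bl$species_tip),
              evolve_sequence(nodeB, bl$species_tip))
    names(sseq) <- sp
    ogseq <- evolve_sequence(anc, bl$outgroup)
    species_seqs[[g]] <- c(sseq, setNames(ogseq, og))
    outgroup_nuclear[g] <- ogseq
    hap1 <- hap2 <- character(length(acc_ids))
    for (i in seq_along(acc_ids)) {
      base <- encode_seq(evolve_sequence(sseq[[acc_species[i]]],
                                         bl$within_species))
      het <- which(runif(cfg$gene_length) < cfg$het_rate)
      hap1[i] <- decode_seq(base)
      hap2[i] <- decode_seq(mutate_sites(base, het))
    }
    nuclear[[g]] <- list(hap1 = setNames(hap1, acc_ids),
                         hap2 = setNames(hap2, acc_ids))
  }

  # ---- per-species reference CDS databases (+ planted duplicates) ----
  dup_genes <- if (cfg$n_duplicate_genes > 0) {
    gene_ids[seq(cfg$n_genes - cfg$n_duplicate_genes + 1, cfg$n_genes)]
  } else {
    character(0)
  }
  reference_dbs <- lapply(seq_along(sp), function(s) {
    db <- vapply(species_seqs, `[[`, character(1), sp[s])
    names(db) <- gene_ids
    extra <- dup_genes[(match(dup_genes, gene_ids) - 1) %% 4 + 1 == s]
    for (g in extra) {
      db[paste0(g, "_dup")] <- evolve_sequence(db[[g]], 0.03)
    }
    db
  })
  names(reference_dbs) <- sp

  # ---- plastomes ----
  cp_anc <- random_dna(cfg$cp_length)
  d_bt <- cfg$cp_divergence_between_species
  d_in <- cfg$cp_divergence_within_species
  cpA <- evolve_sequence(cp_anc, d_bt / 2)
  cpB <- evolve_sequence(cp_anc, d_bt / 2)
  cp_species <- c(evolve_sequence(cpA, d_bt), evolve_sequence(cpA, d_bt),
                  evolve_sequence(cpB, d_bt), evolve_sequence(cpB, d_bt))
  names(cp_species) <- sp
  cp_outgroup <- evolve_sequence(cp_anc, 3 * d_bt)
  founders <- list()
  for (s in sp) {
    founders[[s]] <- vapply(seq_len(cfg$n_cp_haplotypes), function(j) {
      evolve_sequence(cp_species[[s]], d_in)
    }, character(1))
  }
  # founder assignment: contiguous in x within species (spatial
  # autocorrelation) or random
  founder_of <- integer(length(acc_ids))
  for (s in sp) {
    idx <- which(acc_species == s)
    grp <- if (cfg$cp_spatial_autocorrelation) {
      ceiling(rank(xy[idx, 1], ties.method = "first") /
                (length(idx) / cfg$n_cp_haplotypes))
    } else {
      sample.int(cfg$n_cp_haplotypes, length(idx), replace = TRUE)
    }
    founder_of[idx] <- pmin(pmax(grp, 1), cfg$n_cp_haplotypes)
  }

  # pre-capture plastomes: founder lineage + private mutations
  cp_base <- vapply(seq_along(acc_ids), function(i) {
    evolve_sequence(founders[[acc_species[i]]][founder_of[i]], d_in / 5)
  }, character(1))
  names(cp_base) <- acc_ids
  cp_seqs <- cp_base

  # ---- capture events ----
  # Each event is an independent historical hybridization: the recipient's
  # plastome is replaced by a descendant of the (pre-capture) plastome of a
  # specific donor accession — the geographically nearest one, with distinct
  # source accessions across events — and then accumulates post-capture
  # divergence (3x the within-species founder depth: the transfer predates
  # the sampled donor generation).
  captured_from <- rep(NA_character_, length(acc_ids))
  names(captured_from) <- acc_ids
  if (cfg$n_capture_events > 0) {
    chosen <- if (!is.null(cfg$capture_accessions)) {
      if (!all(cfg$capture_accessions %in% acc_ids)) {
        abort("capture_accessions contains unknown accession ids",
              class = "cpcapture_config_error")
      }
      cfg$capture_accessions
    } else {
      sample(acc_ids, cfg$n_capture_events)
    }
    used_sources <- character(0)
    for (id in chosen) {
      i <- match(id, acc_ids)
      donor <- if (!is.null(cfg$capture_donor_species)) {
        cfg$capture_donor_species
      } else {
        others <- which(acc_species != acc_species[i])
        dd <- sqrt((xy[others, 1] - xy[i, 1])^2 + (xy[others, 2] - xy[i, 2])^2)
        acc_species[others[which.min(dd)]]
      }
      if (donor == acc_species[i]) {
        abort("capture donor equals the accession's own species",
              class = "cpcapture_config_error")
      }
      didx <- which(acc_species == donor)
      dd <- sqrt((xy[didx, 1] - xy[i, 1])^2 + (xy[didx, 2] - xy[i, 2])^2)
      ord <- didx[order(dd, acc_ids[didx], method = "radix")]
      free <- ord[!acc_ids[ord] %in% used_sources]
      src <- if (length(free) > 0) free[1] else ord[1]
      used_sources <- c(used_sources, acc_ids[src])
      founder_of[i] <- founder_of[src]
      captured_from[i] <- donor
      cp_seqs[i] <- evolve_sequence(cp_base[[src]], 3 * d_in)
    }
  }

  hap_species <- ifelse(is.na(captured_from), acc_species, captured_from)
  names(cp_seqs) <- acc_ids
  hap_label <- sprintf("%s_h%d", hap_species, founder_of)
  cp_hap_id <- match(hap_label, sort(unique(
    as.vector(outer(sp, seq_len(cfg$n_cp_haplotypes),
                    function(a, b) sprintf("%s_h%d", a, b))))))

  # ---- truth ----
  to2 <- bl$outgroup / 2
  species_tree <- parse_newick(sprintf(
    "(((%s:%g,%s:%g):%g,(%s:%g,%s:%g):%g):%g,%s:%g);",
    sp[1], bl$species_tip, sp[2], bl$species_tip, bl$internal,
    sp[3], bl$species_tip, sp[4], bl$species_tip, bl$internal,
    to2, og, to2))
  # truth accession tree: species polytomies on the species topology
  clade <- function(s) {
    paste0("(", paste(sprintf("%s:%g", acc_ids[acc_species == s],
                              bl$within_species), collapse = ","),
           "):", bl$species_tip)
  }
  acc_tree <- parse_newick(sprintf("(((%s,%s):%g,(%s,%s):%g):%g,%s:%g);",
                                   clade(sp[1]), clade(sp[2]), bl$internal,
                                   clade(sp[3]), clade(sp[4]), bl$internal,
                                   to2, og, to2))
  truth <- list(
    species_tree = species_tree,
    accession_tree = acc_tree,
    gene_trees = rep(list(acc_tree), cfg$n_genes),
    capture_flags = setNames(!is.na(captured_from), acc_ids),
    haplotypes = tibble(id = acc_ids, species = unname(acc_species),
                        haplotype_lineage = hap_label,
                        founder = founder_of,
                        captured_from = unname(captured_from)),
    duplicated_genes = dup_genes,
    single_copy_genes = setdiff(gene_ids, dup_genes)
  )

  accessions <- tibble(
    id = acc_ids, species = unname(acc_species), site_id = site_of,
    x = xy[, 1], y = xy[, 2], cp_haplotype = cp_hap_id,
    captured_from = unname(captured_from))

  structure(list(
    accessions = accessions,
    panel = tibble(gene_id = gene_ids,
                   sequence = vapply(species_seqs, `[[`, character(1), sp[1])),
    species_seqs = species_seqs,
    reference_dbs = reference_dbs,
    nuclear = nuclear,
    outgroup_nuclear = outgroup_nuclear,
    cp = c(cp_seqs, setNames(cp_outgroup, og)),
    truth = truth,
    config = cfg
  ), class = "cpcapture_dataset")
}

#' Simulate per-site read-count pileups for diploid accessions
#'
#' Per site, depth is Poisson with the accession's mean depth; each read comes
#' from one of the two haplotypes with probability 1/2 and is miscalled to a
#' uniformly chosen other base with probability `error_rate`. The reference
#' column is the accession's own-species reference CDS (mirroring per-species
#' read mapping). Deterministic given the configuration seed.
#'
#' @param dataset a `cpcapture_dataset`.
#' @param config defaults to `dataset$config`.
#' @return named list (one per ingroup accession) of tibbles with columns
#'   `gene_id`, `pos` (1-based), `ref`, `nA`, `nC`, `nG`, `nT`.
#' @export
simulate_pileups <- function(dataset, config = dataset$config) {
  cfg <- config
  sp <- cfg$species_names[1:4]
  acc <- dataset$accessions
  gene_ids <- names(dataset$nuclear)
  with_local_seed(cfg$seed + 1L, {
    depth_mean <- if (is.null(cfg$depth_range)) {
      rep(cfg$mean_depth, nrow(acc))
    } else {
      runif(nrow(acc), cfg$depth_range[1], cfg$depth_range[2])
    }
    out <- vector("list", nrow(acc))
    names(out) <- acc$id
    for (i in seq_len(nrow(acc))) {
      h1 <- unlist(lapply(gene_ids, function(g) {
        encode_seq(dataset$nuclear[[g]]$hap1[[acc$id[i]]])
      }))
      h2 <- unlist(lapply(gene_ids, function(g) {
        encode_seq(dataset$nuclear[[g]]$hap2[[acc$id[i]]])
      }))
      refs <- unlist(lapply(gene_ids, function(g) {
        encode_seq(dataset$species_seqs[[g]][[acc$species[i]]])
      }))
      cm <- sample_site_counts(h1, h2, depth_mean[i], cfg$error_rate)
      gl <- vapply(gene_ids, function(g) {
        nchar(dataset$nuclear[[g]]$hap1[[1]])
      }, integer(1))
      out[[i]] <- tibble(
        gene_id = rep(gene_ids, gl),
        pos = unlist(lapply(gl, seq_len)),
        ref = c("A", "C", "G", "T")[refs],
        nA = cm[, 1], nC = cm[, 2], nG = cm[, 3], nT = cm[, 4])
    }
    out
  })
}

#' Simulate the pileup of a single diploid gene
#'
#' Low-level counterpart of [simulate_pileups()] for one haplotype pair,
#' using the current RNG state (seed it with `set.seed()` for
#' reproducibility).
#'
#' @param hap1,hap2 the two haplotype sequences (A/C/G/T strings of equal
#'   length).
#' @param ref reference CDS string of the same length (the pileup's `ref`
#'   column).
#' @param mean_depth Poisson mean per-site depth.
#' @param error_rate per-base miscall probability.
#' @param gene_id value for the `gene_id` column.
#' @return pileup tibble (`gene_id`, `pos`, `ref`, `nA`, `nC`, `nG`, `nT`).
#' @export
simulate_gene_pileup <- function(hap1, hap2, ref, mean_depth = 25,
                                 error_rate = 0.001, gene_id = "g001") {
  h1 <- encode_seq(hap1)
  h2 <- encode_seq(hap2)
  r <- encode_seq(ref)
  if (length(h1) != length(h2) || length(h1) != length(r)) {
    abort("hap1, hap2 and ref must have equal lengths",
          class = "cpcapture_input_error")
  }
  if (any(h1 > 4) || any(h2 > 4)) {
    abort("haplotypes must be unambiguous A/C/G/T",
          class = "cpcapture_input_error")
  }
  cm <- sample_site_counts(h1, h2, mean_depth, error_rate)
  tibble(gene_id = gene_id, pos = seq_along(h1),
         ref = c("A", "C", "G", "T")[r],
         nA = cm[, 1], nC = cm[, 2], nG = cm[, 3], nT = cm[, 4])
}

# vectorised diploid pileup sampler over integer-coded haplotypes (1..4);
# returns an L x 4 count matrix
sample_site_counts <- function(h1, h2, mean_depth, error_rate) {
  L <- length(h1)
  depth <- rpois(L, mean_depth)
  n1 <- rbinom(L, depth, 0.5)
  n2 <- depth - n1
  counts <- matrix(0L, L, 4)
  # error-free reads
  e1 <- rbinom(L, n1, error_rate)
  e2 <- rbinom(L, n2, error_rate)
  idx <- cbind(seq_len(L), h1)
  counts[idx] <- counts[idx] + (n1 - e1)
  idx <- cbind(seq_len(L), h2)
  counts[idx] <- counts[idx] + (n2 - e2)
  # miscalled reads land uniformly on one of the 3 other bases
  err <- function(src, ne) {
    sites <- rep(seq_len(L), ne)
    if (length(sites) == 0) return(invisible(NULL))
    # rep(src, ne) aligns with sites: both expand element i by ne[i], in order
    tgt <- ((rep(src, ne) - 1L +
               sample.int(3L, length(sites), replace = TRUE)) %% 4L) + 1L
    for (k in seq_along(sites)) {
      counts[sites[k], tgt[k]] <<- counts[sites[k], tgt[k]] + 1L
    }
  }
  err(h1, e1)
  err(h2, e2)
  counts
}
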