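# End-to-end orchestration: simulate -> select genes -> call variants ->
# reconstruct -> trees -> species tree -> discordance, from one validated
# configuration, with a reproducible run manifest.

#' Full-run configuration
#'
#' Unknown arguments are rejected (R's named-argument matching), so typos
#' cannot silently change a run.
#'
#' @param sim a [simulation_config()].
#' @param caller a [caller_config()].
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate","select","call","reconstruct","trees","species_tree",
#'   "discordance")`; later stages require earlier ones.
#' @param out_dir output directory (created if needed).
#' @param bootstrap_B bootstrap replicates for the nuclear concatenation tree.
#' @param min_score ortholog-selection raw-score threshold.
#' @param k capture-scan neighbour count.
#' @param n_perm Mantel permutations.
#' @param write_pileups also write the (large) per-accession pileup TSVs.
#' @return a `cpcapture_run_config` list.
#' @export
run_config <- function(sim = simulation_config(),
                       caller = caller_config(),
                       stages = c("simulate", "select", "call", "reconstruct",
                                  "trees", "species_tree", "discordance"),
                       out_dir = tempfile("cpcapture_run_"),
                       bootstrap_B = 100,
                       min_score = 70,
                       k = 3,
                       n_perm = 999,
                       write_pileups = FALSE) {
  all_stages <- c("simulate", "select", "call", "reconstruct", "trees",
                  "species_tree", "discordance")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) {
    abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
          class = "cpcapture_config_error")
  }
  structure(list(sim = sim, caller = caller,
                 stages = intersect(all_stages, stages), out_dir = out_dir,
                 bootstrap_B = bootstrap_B, min_score = min_score, k = k,
                 n_perm = n_perm, write_pileups = write_pileups),
            class = "cpcapture_run_config")
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full workflow
#'
#' Executes the enabled stages in order; each stage consumes only earlier
#' stages' outputs. All randomness derives from `config$sim$seed`, so a rerun
#' with the same configuration reproduces identical file contents (the
#' manifest's timestamp aside).
#'
#' @param config a [run_config()].
#' @return a `cpcapture_run` list: `manifest`, `summary`, `paths`, and the key
#'   in-memory results (`dataset`, trees, reports).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  out <- list()
  stage_on <- function(s) s %in% cfg$stages
  og <- cfg$sim$species_names[5]
  sp <- cfg$sim$species_names[1:4]

  # ---- simulate ----
  dataset <- simulate_dataset(cfg$sim)
  out$dataset <- dataset
  pipeline_log("simulate", "%d accessions, %d genes, seed %d",
               nrow(dataset$accessions), cfg$sim$n_genes, cfg$sim$seed)
  paths$metadata <- file.path(cfg$out_dir, "accessions.tsv")
  readr::write_tsv(dataset$accessions, paths$metadata)
  paths$cp_fasta <- file.path(cfg$out_dir, "cp_sequences.fasta")
  write_fasta(dataset$cp, paths$cp_fasta)
  paths$truth_tree <- file.path(cfg$out_dir, "truth_species_tree.nwk")
  writeLines(write_newick(dataset$truth$species_tree), paths$truth_tree)

  species_map <- setNames(dataset$accessions$species, dataset$accessions$id)

  # ---- select ----
  panel <- dataset$panel
  if (stage_on("select")) {
    panel <- select_gene_panel(dataset$panel, dataset$reference_dbs,
                               min_score = cfg$min_score)
    pipeline_log("select", "%d of %d genes single-copy in all databases",
                 nrow(panel), nrow(dataset$panel))
    paths$panel_fasta <- file.path(cfg$out_dir, "panel.fasta")
    write_fasta(setNames(panel$sequence, panel$gene_id), paths$panel_fasta)
    paths$panel_tsv <- file.path(cfg$out_dir, "panel_genes.tsv")
    readr::write_tsv(tibble(order = seq_len(nrow(panel)),
                            gene_id = panel$gene_id), paths$panel_tsv)
  }
  out$panel <- panel

  # ---- call ----
  calls <- NULL
  if (stage_on("call")) {
    pileups <- simulate_pileups(dataset)
    if (cfg$write_pileups) {
      pdir <- file.path(cfg$out_dir, "pileups")
      dir.create(pdir, showWarnings = FALSE)
      for (id in names(pileups)) {
        readr::write_tsv(pileups[[id]], file.path(pdir, paste0(id, ".tsv")))
      }
    }
    calls <- call_pileups(pileups, cfg$caller)
    vdir <- file.path(cfg$out_dir, "variants")
    dir.create(vdir, showWarnings = FALSE)
    for (id in names(calls)) {
      write_variant_csv(calls[[id]], file.path(vdir, paste0(id, ".csv")))
    }
    paths$variants_dir <- vdir
    pipeline_log("call", "%d variant calls across %d accessions",
                 sum(vapply(calls, nrow, integer(1))), length(calls))
    out$calls <- calls
  }

  # ---- reconstruct ----
  sm <- NULL
  if (stage_on("reconstruct")) {
    if (is.null(calls)) {
      abort("reconstruct stage requires the call stage",
            class = "cpcapture_config_error")
    }
    refs <- lapply(setNames(dataset$accessions$id, dataset$accessions$id),
                   function(id) {
      s <- species_map[[id]]
      setNames(vapply(dataset$species_seqs[panel$gene_id], `[[`,
                      character(1), s), panel$gene_id)
    })
    sm <- build_supermatrix(
      dataset$accessions$id, panel, calls, references = refs,
      extra_rows = setNames(list(dataset$outgroup_nuclear[panel$gene_id]), og))
    paths$supermatrix <- file.path(cfg$out_dir, "supermatrix.fasta")
    paths$partitions <- file.path(cfg$out_dir, "partitions.tsv")
    write_supermatrix(sm, paths$supermatrix, paths$partitions)
    pipeline_log("reconstruct", "supermatrix %d x %d", length(sm$sequences),
                 nchar(sm$sequences[[1]]))
    out$supermatrix <- sm
  }

  # ---- trees ----
  gene_trees <- NULL
  if (stage_on("trees")) {
    if (is.null(sm)) {
      abort("trees stage requires the reconstruct stage",
            class = "cpcapture_config_error")
    }
    gene_trees <- lapply(seq_len(nrow(sm$blocks)), function(i) {
      seqs <- substr(sm$sequences, sm$blocks$start[i] + 1, sm$blocks$end[i])
      nj_tree(seqs)
    })
    names(gene_trees) <- sm$blocks$gene_id
    paths$gene_trees <- file.path(cfg$out_dir, "gene_trees.nwk")
    writeLines(vapply(gene_trees, write_newick, character(1)),
               paths$gene_trees)
    nuclear_tree <- bootstrap_support(sm$sequences, builder = "nj",
                                      B = cfg$bootstrap_B,
                                      seed = cfg$sim$seed + 2L)
    paths$nuclear_tree <- file.path(cfg$out_dir, "nuclear_tree.nwk")
    writeLines(write_newick(nuclear_tree), paths$nuclear_tree)
    cp_tree <- nj_tree(dataset$cp)
    paths$cp_tree <- file.path(cfg$out_dir, "cp_tree.nwk")
    writeLines(write_newick(cp_tree), paths$cp_tree)
    pipeline_log("trees", "%d gene trees + nuclear (B=%d) + plastome tree",
                 length(gene_trees), cfg$bootstrap_B)
    out$gene_trees <- gene_trees
    out$nuclear_tree <- nuclear_tree
    out$cp_tree <- cp_tree
  }

  # ---- species tree ----
  if (stage_on("species_tree")) {
    if (is.null(gene_trees)) {
      abort("species_tree stage requires the trees stage",
            class = "cpcapture_config_error")
    }
    st <- quartet_species_tree(gene_trees, species_map,
                               seed = cfg$sim$seed + 3L)
    paths$species_tree <- file.path(cfg$out_dir, "species_tree.nwk")
    writeLines(write_newick(st$tree), paths$species_tree)
    pipeline_log("species_tree", "%s (quartet support %.3f)",
                 st$topology, st$support)
    out$species_tree <- st
  }

  # ---- discordance ----
  if (stage_on("discordance")) {
    if (is.null(out$cp_tree) || is.null(out$nuclear_tree)) {
      abort("discordance stage requires the trees stage",
            class = "cpcapture_config_error")
    }
    report <- capture_candidates(out$cp_tree, species_map, k = cfg$k,
                                 outgroup = og)
    paths$capture_report <- file.path(cfg$out_dir, "capture_report.tsv")
    readr::write_tsv(as_tibble(report), paths$capture_report)
    nuc_rooted <- root_on_outgroup(out$nuclear_tree, og)
    char_all <- c(species_map, setNames(og, og))
    nuc_fitch <- fitch_parsimony(nuc_rooted, char_all)
    n_states <- length(unique(char_all))
    comp <- clade_species_composition(out$cp_tree, char_all)
    paths$composition <- file.path(cfg$out_dir, "clade_composition.tsv")
    readr::write_tsv(comp, paths$composition)
    mt <- mantel_test(patristic_dist(out$cp_tree, drop = og),
                      geographic_dist(dataset$accessions),
                      n_perm = cfg$n_perm, seed = cfg$sim$seed + 4L)
    hap <- lapply(setNames(sp, sp), function(s) {
      ids <- dataset$accessions$id[dataset$accessions$species == s]
      haplotype_summary(dataset$cp[ids])
    })
    summary <- list(
      parsimony_cp = attr(report, "parsimony"),
      excess_cp = attr(report, "excess"),
      parsimony_nuclear = nuc_fitch,
      excess_nuclear = nuc_fitch - (n_states - 1L),
      mantel_r = mt$r, mantel_p = mt$p,
      n_flagged = sum(report$flagged),
      flagged = report$id[report$flagged],
      n_haplotypes = vapply(hap, `[[`, integer(1), "n_haplotypes"),
      species_topology = out$species_tree$topology %||% NA_character_,
      quartet_support = out$species_tree$support %||% NA_real_,
      monophyly_nuclear = as.list(monophyly_check(
        ape::drop.tip(out$nuclear_tree, og), species_map)))
    paths$summary <- file.path(cfg$out_dir, "summary.json")
    jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    pipeline_log("discordance",
                 "flags=%d excess_cp=%d excess_nuclear=%d mantel_p=%.4g",
                 sum(report$flagged), summary$excess_cp,
                 summary$excess_nuclear, mt$p)
    out$capture_report <- report
    out$mantel <- mt
    out$summary <- summary
  }

  # ---- manifest ----
  files <- unlist(paths[!vapply(paths, is.null, logical(1))])
  isdir <- dir.exists(files)
  files <- c(files[!isdir],
             unlist(lapply(files[isdir], list.files, full.names = TRUE,
                           recursive = TRUE)))
  files <- files[file.exists(files)]
  hashes <- tools::md5sum(files)
  names(hashes) <- basename(names(hashes))
  manifest <- list(
    tool = as.character(utils::packageVersion("cpcapture")),
    config_hash = config_hash(cfg),
    seed = cfg$sim$seed,
    stages = cfg$stages,
    files = as.list(hashes),
    timestamp = format(Sys.time(), tz = "UTC"))
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  out$manifest <- manifest
  out$paths <- paths
  structure(out, class = "cpcapture_run")
}

# stable hash of a configuration (structure + values, not environments)
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg[setdiff(names(cfg), "out_dir")]), collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}
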