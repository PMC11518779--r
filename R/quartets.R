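# Species-tree estimation for four ingroup species by exhaustive quartet
# concordance over gene trees (quartet-based species-tree principle, with the
# species-topology search made exhaustive because there are only 3 candidates).

# topological (edge-count) leaf distance matrix of a tree
topo_dist <- function(tree) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(tree$edge))
  ape::cophenetic.phylo(t2)
}

#' Quartet topology votes from gene trees
#'
#' For every gene tree, samples one-accession-per-species quartets (all
#' combinations when their number is at most `max_combos`, otherwise a seeded
#' uniform sample of `max_combos`), restricts the gene tree to each quartet by
#' the four-point condition on topological distances, and records which of the
#' three species topologies it displays. Unresolved restrictions are skipped.
#' Leaves without a species assignment (e.g. the outgroup) are ignored; a tree
#' missing all accessions of some species contributes no votes.
#'
#' @param gene_trees list of `phylo` objects over accession leaves.
#' @param species named character vector: accession -> species (exactly 4
#'   ingroup species).
#' @param max_combos cap on quartets per gene tree.
#' @param seed integer seed for the (possible) quartet sampling.
#' @return a `cpcapture_quartet_votes` tibble: `topology`, `votes`,
#'   `fraction` (of resolved quartets); attributes `n_resolved`, `n_sampled`,
#'   `species`.
#' @export
quartet_votes <- function(gene_trees, species, max_combos = 1000,
                          seed = NULL) {
  sp <- sort(unique(species))
  if (length(sp) != 4) {
    abort("quartet concordance needs exactly 4 ingroup species",
          class = "cpcapture_input_error")
  }
  topo_names <- c(
    paste0(sp[1], ",", sp[2], "|", sp[3], ",", sp[4]),
    paste0(sp[1], ",", sp[3], "|", sp[2], ",", sp[4]),
    paste0(sp[1], ",", sp[4], "|", sp[2], ",", sp[3]))
  votes <- setNames(numeric(3), topo_names)
  n_sampled <- 0L
  with_local_seed(seed, {
    for (tr in gene_trees) {
      tips <- intersect(tr$tip.label, names(species))
      members <- lapply(sp, function(s) tips[species[tips] == s])
      if (any(lengths(members) == 0)) {
        warn("gene tree missing a species entirely; it contributes no votes")
        next
      }
      total <- prod(lengths(members))
      if (total <= max_combos) {
        combos <- as.matrix(expand.grid(members, stringsAsFactors = FALSE))
      } else {
        combos <- vapply(members, function(m) {
          m[sample.int(length(m), max_combos, replace = TRUE)]
        }, character(max_combos))
      }
      D <- topo_dist(tr)
      a <- combos[, 1]; b <- combos[, 2]; c_ <- combos[, 3]; d <- combos[, 4]
      s12 <- D[cbind(a, b)] + D[cbind(c_, d)]
      s13 <- D[cbind(a, c_)] + D[cbind(b, d)]
      s14 <- D[cbind(a, d)] + D[cbind(b, c_)]
      S <- cbind(s12, s13, s14)
      mins <- pmin(s12, s13, s14)
      is_min <- S == mins
      resolved <- rowSums(is_min) == 1
      pick <- max.col(is_min[resolved, , drop = FALSE], ties.method = "first")
      tb <- tabulate(pick, nbins = 3)
      votes <- votes + tb
      n_sampled <- n_sampled + nrow(S)
    }
  })
  n_resolved <- sum(votes)
  out <- tibble(topology = topo_names, votes = as.numeric(votes),
                fraction = if (n_resolved > 0) as.numeric(votes) / n_resolved
                           else rep(NA_real_, 3))
  structure(out, class = c("cpcapture_quartet_votes", class(out)),
            n_resolved = n_resolved, n_sampled = n_sampled, species = sp)
}

#' Select the species topology from quartet votes
#'
#' Argmax over the three candidate topologies; the reported support is the
#' winning vote fraction (a normalized quartet fraction, not a posterior
#' probability). An exact tie is an error naming the tied topologies.
#'
#' @param votes a `cpcapture_quartet_votes` tibble.
#' @return list with `tree` (a `phylo` over the 4 species labels),
#'   `topology`, `support`, `n_quartets`.
#' @export
select_species_topology <- function(votes) {
  if (sum(votes$votes) == 0) {
    abort("no resolved quartets", class = "cpcapture_input_error")
  }
  top <- which(votes$votes == max(votes$votes))
  if (length(top) > 1) {
    abort(sprintf("unresolved: tied topologies %s",
                  paste(votes$topology[top], collapse = " and ")),
          class = "cpcapture_unresolved_error")
  }
  lab <- votes$topology[top]
  halves <- strsplit(lab, "|", fixed = TRUE)[[1]]
  nwk <- sprintf("((%s),(%s));", halves[1], halves[2])
  list(tree = parse_newick(nwk), topology = lab,
       support = votes$fraction[top],
       n_quartets = attr(votes, "n_resolved"))
}

#' Estimate the species tree from gene trees by quartet concordance
#'
#' @inheritParams quartet_votes
#' @return as [select_species_topology()], plus `votes`.
#' @export
quartet_species_tree <- function(gene_trees, species, max_combos = 1000,
                                 seed = NULL) {
  v <- quartet_votes(gene_trees, species, max_combos = max_combos, seed = seed)
  out <- select_species_topology(v)
  out$votes <- v
  out
}
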