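# Cyto-nuclear discordance and phylogeography: Fitch parsimony of the species
# character, k-nearest-neighbour capture flagging, permutation Mantel test,
# clade species composition, haplotype diversity.

#' Fitch parsimony score of a species character on a tree
#'
#' Minimum number of state changes by the Fitch bottom-up pass
#' (intersection/union of state sets). The tree must be binary; an unrooted
#' (trifurcating-basal) tree is rooted internally on its first tip's pendant
#' edge — the score is invariant to root placement.
#'
#' @param tree a binary `phylo` object.
#' @param character named character vector mapping every tip label to a state
#'   (species).
#' @return integer: minimum number of transitions.
#' @export
fitch_parsimony <- function(tree, character) {
  miss <- setdiff(tree$tip.label, names(character))
  if (length(miss) > 0) {
    abort(sprintf("unlabeled leaf: %s", miss[1]),
          class = "cpcapture_input_error")
  }
  if (!ape::is.binary(tree)) {
    # a trifurcating basal node (unrooted storage) is fine once rooted
    rooted <- root_on_outgroup(tree, tree$tip.label[1])
    if (!ape::is.binary(rooted)) {
      abort("Fitch parsimony needs a binary tree",
            class = "cpcapture_input_error")
    }
    tree <- rooted
  }
  states <- sort(unique(character[tree$tip.label]))
  n <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- matrix(FALSE, n + tree$Nnode, length(states))
  for (i in seq_len(n)) {
    sets[i, match(character[[tree$tip.label[i]]], states)] <- TRUE
  }
  changes <- 0L
  for (node in unique(po$edge[, 1])) {
    kids <- po$edge[po$edge[, 1] == node, 2]
    acc <- sets[kids[1], ]
    for (k in kids[-1]) {
      inter <- acc & sets[k, ]
      if (any(inter)) {
        acc <- inter
      } else {
        acc <- acc | sets[k, ]
        changes <- changes + 1L
      }
    }
    sets[node, ] <- acc
  }
  changes
}

#' Parsimony excess of the species character
#'
#' Fitch score minus (number of species - 1): zero when every species is
#' monophyletic on the tree, positive when reticulation (or other conflict)
#' forces extra transitions.
#'
#' @inheritParams fitch_parsimony
#' @return non-negative integer.
#' @export
parsimony_excess <- function(tree, character) {
  k <- length(unique(character[tree$tip.label]))
  fitch_parsimony(tree, character) - (k - 1L)
}

#' Flag chloroplast-capture candidates on a plastome tree
#'
#' For each ingroup accession, takes its `k` nearest other ingroup leaves by
#' patristic distance (ties: smaller distance, then lexicographic id) and the
#' majority species among them. The accession is flagged when the majority
#' species differs from its own; majority ties are recorded as ambiguous and
#' left unflagged. The margin is the patristic distance to the nearest
#' same-species leaf minus the distance to the nearest other-species leaf
#' (positive = another species is closer).
#'
#' @param cp_tree plastome tree (`phylo`, with branch lengths).
#' @param species named character vector: leaf -> species.
#' @param k number of neighbours (default 3).
#' @param outgroup optional label excluded from the scan.
#' @return a `cpcapture_capture_report`: tibble with columns `id`, `species`,
#'   `neighbor_species` (majority), `margin`, `ambiguous`, `flagged`;
#'   attributes `parsimony` and `excess` (computed on the ingroup tree rooted
#'   on its first leaf, or on `outgroup` when given).
#' @export
capture_candidates <- function(cp_tree, species, k = 3, outgroup = NULL) {
  tree <- cp_tree
  if (!is.null(outgroup) && outgroup %in% tree$tip.label) {
    rooted <- root_on_outgroup(tree, outgroup)
    ingroup_tree <- ape::drop.tip(tree, outgroup)
  } else {
    rooted <- tree
    ingroup_tree <- tree
  }
  tips <- ingroup_tree$tip.label
  if (k < 1 || k >= length(tips)) {
    abort("k must be in [1, number of ingroup leaves)",
          class = "cpcapture_input_error")
  }
  miss <- setdiff(tips, names(species))
  if (length(miss) > 0) {
    abort(sprintf("leaf without species label: %s", miss[1]),
          class = "cpcapture_input_error")
  }
  D <- ape::cophenetic.phylo(ingroup_tree)
  ord_tips <- sort(tips, method = "radix")
  D <- D[ord_tips, ord_tips]
  res <- lapply(ord_tips, function(id) {
    d <- D[id, setdiff(ord_tips, id)]
    ord <- order(d, names(d), method = "radix")
    nn <- names(d)[ord[seq_len(k)]]
    tab <- sort(table(species[nn]), decreasing = TRUE)
    ambiguous <- length(tab) > 1 && tab[1] == tab[2]
    maj <- if (ambiguous) NA_character_ else names(tab)[1]
    own <- species[[id]]
    same <- d[species[names(d)] == own]
    other <- d[species[names(d)] != own]
    margin <- if (length(same) == 0 || length(other) == 0) {
      NA_real_
    } else {
      min(same) - min(other)
    }
    flag <- !ambiguous && maj != own
    tibble(id = id, species = own, neighbor_species = maj,
           margin = margin, ambiguous = ambiguous, flagged = flag)
  })
  out <- dplyr::bind_rows(res)
  char_full <- species
  if (!is.null(outgroup)) char_full[outgroup] <- outgroup
  fp <- fitch_parsimony(rooted, char_full)
  n_sp <- length(unique(char_full[rooted$tip.label]))
  structure(out, class = c("cpcapture_capture_report", class(out)),
            parsimony = fp, excess = fp - (n_sp - 1L))
}

#' Permutation Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries; significance by jointly
#' permuting rows and columns of `D2`. One-sided p-value
#' `(1 + #{r_perm >= r_obs}) / (n_perm + 1)`.
#'
#' @param D1,D2 symmetric labelled distance matrices over the same labels
#'   (`D2` is reordered to `D1`'s labels).
#' @param n_perm number of permutations (>= 99).
#' @param seed optional integer seed (deterministic result).
#' @return a `cpcapture_mantel` list: `r`, `p`, `n_perm`, `n`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999, seed = NULL) {
  if (n_perm < 99) {
    abort("n_perm must be >= 99", class = "cpcapture_input_error")
  }
  l1 <- dimnames(D1)[[1]]
  l2 <- dimnames(D2)[[1]]
  if (is.null(l1) || is.null(l2) || !setequal(l1, l2)) {
    abort("distance matrices must share the same labels",
          class = "cpcapture_input_error")
  }
  D2 <- D2[l1, l1]
  ut <- upper.tri(D1)
  v1 <- D1[ut]
  r_obs <- cor(v1, D2[ut])
  n <- nrow(D1)
  with_local_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      pm <- sample.int(n)
      if (cor(v1, D2[pm, pm][ut]) >= r_obs) hits <- hits + 1L
    }
    structure(list(r = r_obs, p = (1 + hits) / (n_perm + 1),
                   n_perm = n_perm, n = n),
              class = "cpcapture_mantel")
  })
}

#' Species composition of supported clades
#'
#' For each internal edge with support at least `support_min`, tallies the
#' species on the clade (child) side and the rest of the tree; clades
#' containing more than one species are marked mixed.
#'
#' @param tree a `phylo`; internal node labels are read as supports (edges
#'   without a numeric label are kept only when `support_min` is 0).
#' @param species named character vector: leaf -> species.
#' @param support_min minimum support to report an edge.
#' @return tibble with one row per (edge, species): `edge_key`, `support`,
#'   `clade_size`, `species`, `n_in`, `n_out`, `mixed`.
#' @export
clade_species_composition <- function(tree, species, support_min = 0) {
  miss <- setdiff(tree$tip.label, names(species))
  if (length(miss) > 0) {
    abort(sprintf("leaf without species label: %s", miss[1]),
          class = "cpcapture_input_error")
  }
  n <- ape::Ntip(tree)
  es <- edge_splits(tree)
  es <- es[es$size >= 2 & es$size <= n - 2, , drop = FALSE]
  keep <- is.na(es$support) & support_min <= 0 |
    (!is.na(es$support) & es$support >= support_min)
  es <- es[keep, , drop = FALSE]
  total <- table(species[tree$tip.label])
  rows <- lapply(seq_len(nrow(es)), function(i) {
    inside <- table(factor(species[es$tips[[i]]], levels = names(total)))
    tibble(edge_key = es$key[i],
           support = es$support[i],
           clade_size = es$size[i],
           species = names(total),
           n_in = as.integer(inside),
           n_out = as.integer(total - inside),
           mixed = sum(inside > 0) > 1)
  })
  dplyr::bind_rows(rows)
}

#' Haplotype diversity summary of aligned sequences
#'
#' Counts exactly distinct sequences and returns the pairwise Hamming
#' difference matrix (any character mismatch counts, including differing
#' ambiguity codes).
#'
#' @param seqs named character vector of equal-length sequences.
#' @return list with `n_haplotypes`, `haplotype` (named integer assignment,
#'   numbered by first appearance), and `differences` (labelled matrix).
#' @export
haplotype_summary <- function(seqs) {
  if (length(unique(nchar(seqs))) > 1) {
    abort("sequences have unequal lengths", class = "cpcapture_input_error")
  }
  uniq <- unique(seqs)
  hap <- setNames(match(seqs, uniq), names(seqs))
  M <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  n <- length(seqs)
  D <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq(i + 1, n)) {
      d <- sum(M[i, ] != M[j, ])
      D[i, j] <- D[j, i] <- d
    }
  }
  list(n_haplotypes = length(uniq), haplotype = hap, differences = D)
}

#' Euclidean geographic distance matrix from accession metadata
#'
#' @param accessions tibble with columns `id`, `x`, `y`.
#' @return labelled symmetric matrix.
#' @export
geographic_dist <- function(accessions) {
  D <- as.matrix(stats::dist(cbind(accessions$x, accessions$y)))
  dimnames(D) <- list(accessions$id, accessions$id)
  D
}

#' Patristic (path-length) distance matrix of a tree
#'
#' @param tree a `phylo` with branch lengths.
#' @param drop optional tip labels to exclude (e.g. the outgroup).
#' @return labelled symmetric matrix.
#' @export
patristic_dist <- function(tree, drop = NULL) {
  if (!is.null(drop)) tree <- ape::drop.tip(tree, intersect(drop, tree$tip.label))
  ape::cophenetic.phylo(tree)
}
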