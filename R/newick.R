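# Tree plumbing: Newick parse/serialize, bipartitions, Robinson-Foulds,
# outgroup rooting, majority-rule consensus, monophyly.
#
# Trees are ape "phylo" objects throughout. Serialization is canonical:
# children are ordered by their smallest descendant tip label, so
# write_newick(parse_newick(x)) is a fixed point.

#' Parse a Newick string into a phylogenetic tree
#'
#' Supports branch lengths, internal node labels (e.g. bootstrap support) and
#' quoted labels.
#'
#' @param text a Newick string (must end with `;`).
#' @return an object of class `phylo`.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(tr)) {
    abort("could not parse Newick string", class = "cpcapture_format_error")
  }
  tr
}

#' Serialize a tree to canonical Newick
#'
#' Children of every node are ordered by their smallest descendant tip label,
#' which makes the output deterministic for a given unrooted/rooted topology.
#' Internal node labels (support values) and branch lengths are preserved.
#'
#' @param tree a `phylo` object.
#' @return a single Newick string.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- ape::Ntip(tree)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  paste0(nwk_subtree(tree, root, parent = 0L)$str, ";")
}

nwk_quote <- function(lab) {
  if (grepl("[ (),:;\\[\\]']", lab)) {
    paste0("'", gsub("'", "''", lab), "'")
  } else {
    lab
  }
}

nwk_label <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n) {
    tree$tip.label[node]
  } else if (!is.null(tree$node.label)) {
    tree$node.label[node - n]
  } else {
    ""
  }
}

# recursive canonical writer; returns list(str=, min=) where min is the
# smallest descendant tip label (used to order siblings)
nwk_subtree <- function(tree, node, parent) {
  n <- ape::Ntip(tree)
  if (node <= n) {
    lab <- tree$tip.label[node]
    return(list(str = nwk_quote(lab), min = lab))
  }
  rows <- which(tree$edge[, 1] == node)
  parts <- lapply(rows, function(k) {
    child <- tree$edge[k, 2]
    sub <- nwk_subtree(tree, child, node)
    s <- sub$str
    if (child > n) {
      lab <- nwk_label(tree, child)
      if (!is.null(lab) && !is.na(lab) && nzchar(lab)) s <- paste0(s, lab)
    }
    if (!is.null(tree$edge.length)) {
      s <- paste0(s, ":", sprintf("%.10g", tree$edge.length[k]))
    }
    list(str = s, min = sub$min)
  })
  ord <- order(vapply(parts, `[[`, character(1), "min"), method = "radix")
  inner <- paste(vapply(parts[ord], `[[`, character(1), "str"),
                 collapse = ",")
  list(str = paste0("(", inner, ")"),
       min = min(vapply(parts, `[[`, character(1), "min")))
}

# ---- bipartitions ------------------------------------------------------

# canonical key for the bipartition separating `tipset` from the rest:
# the side not containing the overall smallest label, sorted and joined
split_key <- function(tipset, all_tips_sorted) {
  ref <- all_tips_sorted[1]
  side <- if (ref %in% tipset) setdiff(all_tips_sorted, tipset) else tipset
  paste(sort(side, method = "radix"), collapse = "\t")
}

# per-edge clade (child-side) tip sets, sizes, canonical keys and supports
edge_splits <- function(tree) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n + m)
  sets[seq_len(n)] <- as.list(tree$tip.label)
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]
    ch <- po$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  all_sorted <- sort(tree$tip.label, method = "radix")
  child <- tree$edge[, 2]
  tibble(
    node = child,
    size = lengths(sets)[child],
    tips = lapply(child, function(x) sets[[x]]),
    key = vapply(child, function(x) split_key(sets[[x]], all_sorted),
                 character(1)),
    support = vapply(child, function(x) {
      if (x > n && !is.null(tree$node.label)) {
        suppressWarnings(as.numeric(tree$node.label[x - n]))
      } else {
        NA_real_
      }
    }, numeric(1))
  )
}

# canonical keys of the non-trivial bipartitions of the unrooted topology
nontrivial_splits <- function(tree) {
  n <- ape::Ntip(tree)
  es <- edge_splits(tree)
  unique(es$key[es$size >= 2 & es$size <= n - 2])
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the non-trivial bipartition sets of the unrooted
#' topologies.
#'
#' @param t1,t2 `phylo` objects over the same leaf set.
#' @return a non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    abort("trees have different leaf sets", class = "cpcapture_input_error")
  }
  b1 <- nontrivial_splits(t1)
  b2 <- nontrivial_splits(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# ---- rooting -----------------------------------------------------------

# adjacency view of a phylo: per undirected edge, length and support
# (support = internal child's node label in the stored orientation)
tree_adjacency <- function(tree) {
  n <- ape::Ntip(tree)
  e <- tree$edge
  len <- tree$edge.length
  sup <- vapply(seq_len(nrow(e)), function(k) {
    ch <- e[k, 2]
    if (ch > n && !is.null(tree$node.label)) tree$node.label[ch - n] else ""
  }, character(1))
  nb <- vector("list", n + tree$Nnode)
  for (k in seq_len(nrow(e))) {
    a <- e[k, 1]
    b <- e[k, 2]
    nb[[a]] <- rbind(nb[[a]], c(b, k))
    nb[[b]] <- rbind(nb[[b]], c(a, k))
  }
  list(nb = nb, len = len, sup = sup, n = n, tips = tree$tip.label)
}

# write a newick subtree from `node` entered via edge `from_edge`
# (0 = virtual root), over the adjacency view
nwk_adj <- function(adj, node, from_edge) {
  if (node <= adj$n) {
    return(list(str = nwk_quote(adj$tips[node]), min = adj$tips[node]))
  }
  nbr <- adj$nb[[node]]
  keep <- nbr[nbr[, 2] != from_edge, , drop = FALSE]
  parts <- lapply(seq_len(nrow(keep)), function(i) {
    child <- keep[i, 1]
    ek <- keep[i, 2]
    sub <- nwk_adj(adj, child, ek)
    s <- sub$str
    if (child > adj$n && nzchar(adj$sup[ek])) s <- paste0(s, adj$sup[ek])
    if (!is.null(adj$len)) s <- paste0(s, ":", sprintf("%.10g", adj$len[ek]))
    list(str = s, min = sub$min)
  })
  ord <- order(vapply(parts, `[[`, character(1), "min"), method = "radix")
  list(str = paste0("(", paste(vapply(parts[ord], `[[`, character(1), "str"),
                               collapse = ","), ")"),
       min = min(vapply(parts, `[[`, character(1), "min")))
}

#' Root a tree on an outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant edge, so the
#' first split of the rooted tree separates the outgroup from everything else.
#'
#' @param tree a `phylo` object (rooted or unrooted).
#' @param outgroup a tip label present in the tree.
#' @return a rooted `phylo` object.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    abort(sprintf("outgroup '%s' is not a tip of the tree", outgroup),
          class = "cpcapture_input_error")
  }
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  adj <- tree_adjacency(tree)
  tip <- which(tree$tip.label == outgroup)
  ek <- adj$nb[[tip]][1, 2]
  nbr <- adj$nb[[tip]][1, 1]
  half <- if (!is.null(adj$len)) adj$len[ek] / 2 else NULL
  og <- nwk_quote(outgroup)
  rest <- nwk_adj(adj, nbr, ek)$str
  if (nbr > adj$n && nzchar(adj$sup[ek])) rest <- paste0(rest, adj$sup[ek])
  if (!is.null(half)) {
    og <- paste0(og, ":", sprintf("%.10g", half))
    rest <- paste0(rest, ":", sprintf("%.10g", half))
  }
  parse_newick(paste0("(", og, ",", rest, ");"))
}

# ---- consensus ---------------------------------------------------------

#' Majority-rule consensus of a set of trees
#'
#' Retains bipartitions occurring in more than `threshold` of the input trees
#' and assembles them into a (possibly multifurcating) tree. Split frequencies
#' are attached as internal node labels and as the `split_freq` attribute.
#'
#' @param trees a list of `phylo` objects over the same leaf set.
#' @param threshold retention threshold as a fraction (>= 0.5 so retained
#'   splits are mutually compatible).
#' @return a `phylo` object without branch lengths.
#' @export
majority_rule_consensus <- function(trees, threshold = 0.5) {
  if (length(trees) < 1) {
    abort("need at least one tree", class = "cpcapture_input_error")
  }
  if (threshold < 0.5) {
    abort("threshold below 0.5 can retain incompatible splits",
          class = "cpcapture_input_error")
  }
  tips <- sort(trees[[1]]$tip.label, method = "radix")
  for (tr in trees) {
    if (!setequal(tr$tip.label, tips)) {
      abort("trees have different leaf sets", class = "cpcapture_input_error")
    }
  }
  keys <- unlist(lapply(trees, nontrivial_splits))
  freq <- table(keys) / length(trees)
  kept <- freq[freq > threshold]
  # each kept key is the side not containing the reference (smallest) tip:
  # in the view rooted at that tip these sides are nested clades
  clades <- lapply(names(kept), function(k) strsplit(k, "\t", fixed = TRUE)[[1]])
  ord <- order(lengths(clades), decreasing = TRUE)
  clades <- clades[ord]
  freqs <- as.numeric(kept)[ord]
  build <- function(members, avail) {
    # avail: indices of clades not yet placed; members: tip labels here
    parts <- character(0)
    used <- rep(FALSE, length(members))
    names(used) <- members
    for (i in avail) {
      cl <- clades[[i]]
      if (all(cl %in% members) && !any(used[cl])) {
        inner <- build(cl, setdiff(avail, i))
        parts <- c(parts, paste0(inner, sprintf("%.6g", freqs[i])))
        used[cl] <- TRUE
      }
    }
    singles <- members[!used]
    paste0("(", paste(c(vapply(singles, nwk_quote, character(1)), parts),
                      collapse = ","), ")")
  }
  txt <- paste0(build(tips, seq_along(clades)), ";")
  out <- parse_newick(txt)
  attr(out, "split_freq") <- setNames(freqs, names(kept)[ord])
  out
}

# ---- monophyly ---------------------------------------------------------

#' Check species monophyly on a tree
#'
#' A species is monophyletic when some bipartition of the (unrooted) tree
#' exactly separates its leaves from all others. Single-member species are
#' monophyletic by convention.
#'
#' @param tree a `phylo` object.
#' @param species named character vector mapping every tip label to a species.
#' @return named logical vector over species.
#' @export
monophyly_check <- function(tree, species) {
  miss <- setdiff(tree$tip.label, names(species))
  if (length(miss) > 0) {
    abort(sprintf("unlabeled leaf: %s", miss[1]),
          class = "cpcapture_input_error")
  }
  species <- species[tree$tip.label]
  all_sorted <- sort(tree$tip.label, method = "radix")
  keys <- unique(edge_splits(tree)$key)
  sp <- sort(unique(species))
  out <- vapply(sp, function(s) {
    tipset <- tree$tip.label[species == s]
    if (length(tipset) <= 1 || length(tipset) >= ape::Ntip(tree)) return(TRUE)
    split_key(tipset, all_sorted) %in% keys
  }, logical(1))
  setNames(out, sp)
}
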