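# Nonparametric site bootstrap for distance and small-ML trees

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Bootstrap support for a tree built from an alignment
#'
#' Builds a tree from the full alignment, then resamples alignment columns
#' with replacement `B` times, rebuilds, and reports for each internal edge of
#' the original tree the percentage of replicates containing the same
#' bipartition. Supports are attached as internal node labels (integer
#' percents; the root label is empty).
#'
#' @param alignment named character vector of equal-length IUPAC sequences.
#' @param builder `"nj"` (JC distances + neighbor joining) or
#'   `"exhaustive_ml"` (only for small leaf counts).
#' @param B number of bootstrap replicates.
#' @param seed integer seed making the resampling reproducible.
#' @param model,ambiguity distance options for the `"nj"` builder.
#' @return the original tree with `node.label` set to supports.
#' @export
bootstrap_support <- function(alignment, builder = c("nj", "exhaustive_ml"),
                              B = 100, seed = NULL, model = "JC69",
                              ambiguity = "expected_mismatch") {
  builder <- match.arg(builder)
  if (B < 1) abort("B must be >= 1", class = "cpcapture_input_error")
  if (builder == "nj") {
    mp <- mismatch_profile(alignment)
    p0 <- rowMeans(mp$profile)
    tree <- neighbor_joining(profile_to_dist(mp, p0, model))
  } else {
    tree <- exhaustive_ml_topology(alignment)
  }
  n <- ape::Ntip(tree)
  es <- edge_splits(tree)
  target <- es$key[es$size >= 2 & es$size <= n - 2]
  counts <- setNames(numeric(length(target)), target)
  L <- nchar(alignment[[1]])
  with_local_seed(seed, {
    if (builder == "nj") {
      W <- matrix(0, L, B)
      for (b in seq_len(B)) {
        W[, b] <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
      }
      PW <- mp$profile %*% W / L
      for (b in seq_len(B)) {
        rep_tree <- neighbor_joining(profile_to_dist(mp, PW[, b], model))
        hit <- intersect(target, nontrivial_splits(rep_tree))
        counts[hit] <- counts[hit] + 1
      }
    } else {
      A <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
      for (b in seq_len(B)) {
        idx <- sample.int(L, L, replace = TRUE)
        boot <- setNames(apply(A[, idx, drop = FALSE], 1, paste,
                               collapse = ""), names(alignment))
        rep_tree <- exhaustive_ml_topology(boot)
        hit <- intersect(target, nontrivial_splits(rep_tree))
        counts[hit] <- counts[hit] + 1
      }
    }
  })
  supp <- round(100 * counts / B)
  lab <- rep("", tree$Nnode)
  for (i in seq_len(nrow(es))) {
    if (es$node[i] > n && es$key[i] %in% names(supp)) {
      lab[es$node[i] - n] <- as.character(supp[[es$key[i]]])
    }
  }
  tree$node.label <- lab
  tree
}

#' Support value of a given bipartition on a tree with bootstrap labels
#'
#' @param tree a tree whose internal node labels are supports (as produced by
#'   [bootstrap_support()]).
#' @param tipset character vector: one side of the bipartition of interest.
#' @return the support (numeric) or `NA` if the edge is absent.
#' @export
split_support <- function(tree, tipset) {
  es <- edge_splits(tree)
  key <- split_key(tipset, sort(tree$tip.label, method = "radix"))
  hit <- which(es$key == key & !is.na(es$support))
  if (length(hit) == 0) return(NA_real_)
  max(es$support[hit])
}
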