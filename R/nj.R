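# Neighbor joining (Studier-Keppler) with deterministic tie-breaking

#' Neighbor-joining tree from a distance matrix
#'
#' Agglomerates by the Studier-Keppler Q criterion. Ties in Q are broken
#' lexicographically on the pair of smallest leaf labels contained in the two
#' clusters, so the result is deterministic. Negative estimated branch lengths
#' are clamped to zero with the deficit transferred to the sibling edge.
#'
#' @param D symmetric labelled distance matrix (finite entries, zero
#'   diagonal), at least 3 taxa.
#' @return an unrooted `phylo` object.
#' @export
neighbor_joining <- function(D) {
  if (is.null(dimnames(D)[[1]])) {
    abort("distance matrix must have labels", class = "cpcapture_input_error")
  }
  n <- nrow(D)
  if (n < 3) {
    abort("neighbor joining needs at least 3 taxa",
          class = "cpcapture_input_error")
  }
  if (any(!is.finite(D))) {
    abort("distance matrix has non-finite entries (saturated distances?)",
          class = "cpcapture_input_error")
  }
  labs <- dimnames(D)[[1]]
  frag <- vapply(labs, nwk_quote, character(1))
  minlab <- labs
  Dm <- unname(D)
  while (n > 3) {
    R <- rowSums(Dm)
    Q <- (n - 2) * Dm - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    keys <- apply(cand, 1, function(ij) {
      l <- sort(c(minlab[ij[1]], minlab[ij[2]]), method = "radix")
      paste(l, collapse = "\t")
    })
    pick <- cand[order(keys, method = "radix")[1], ]
    i <- pick[1]
    j <- pick[2]
    dij <- Dm[i, j]
    bi <- 0.5 * dij + (R[i] - R[j]) / (2 * (n - 2))
    bj <- dij - bi
    if (bi < 0) {
      bj <- bj + bi
      bi <- 0
    }
    if (bj < 0) {
      bi <- bi + bj
      bj <- 0
    }
    bi <- max(bi, 0)
    bj <- max(bj, 0)
    first <- minlab[i] <= minlab[j]
    newfrag <- if (first) {
      sprintf("(%s:%.10g,%s:%.10g)", frag[i], bi, frag[j], bj)
    } else {
      sprintf("(%s:%.10g,%s:%.10g)", frag[j], bj, frag[i], bi)
    }
    du <- 0.5 * (Dm[i, ] + Dm[j, ] - dij)
    Dm[i, ] <- du
    Dm[, i] <- du
    Dm[i, i] <- 0
    frag[i] <- newfrag
    minlab[i] <- min(minlab[i], minlab[j])
    keep <- setdiff(seq_len(n), j)
    Dm <- Dm[keep, keep, drop = FALSE]
    frag <- frag[keep]
    minlab <- minlab[keep]
    n <- n - 1
  }
  b1 <- max(0, (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2)
  b2 <- max(0, (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2)
  b3 <- max(0, (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], b1, frag[2], b2, frag[3], b3)
  parse_newick(txt)
}

#' Neighbor-joining tree from aligned sequences
#'
#' Convenience wrapper: JC69 (or p) distances followed by [neighbor_joining()].
#'
#' @param seqs named character vector of equal-length IUPAC sequences.
#' @inheritParams pairwise_distance
#' @return an unrooted `phylo` object.
#' @export
nj_tree <- function(seqs, model = "JC69", ambiguity = "expected_mismatch") {
  neighbor_joining(seq_dist(seqs, model = model, ambiguity = ambiguity))
}
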