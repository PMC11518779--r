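# Jukes-Cantor likelihood by Felsenstein pruning, and exhaustive
# maximum-likelihood topology search for small leaf counts.

# JC69 transition probability matrix for branch length t (subs/site)
jc_pmat <- function(t) {
  e <- exp(-4 * t / 3)
  m <- matrix(0.25 * (1 - e), 4, 4)
  diag(m) <- 0.25 + 0.75 * e
  m
}

#' Log-likelihood of an alignment on a tree under JC69
#'
#' Felsenstein pruning with uniform base frequencies. IUPAC ambiguity codes
#' enter as partial likelihoods (1 for every compatible base). Identical site
#' patterns are collapsed before the traversal.
#'
#' @param tree a `phylo` object with branch lengths; leaves must match the
#'   alignment names.
#' @param alignment named character vector of equal-length IUPAC sequences.
#' @param site_pattern_compression collapse repeated columns (default `TRUE`).
#' @return the log-likelihood (a single number).
#' @export
jc_log_likelihood <- function(tree, alignment,
                              site_pattern_compression = TRUE) {
  if (!setequal(tree$tip.label, names(alignment))) {
    abort("alignment names do not match tree leaves",
          class = "cpcapture_input_error")
  }
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths", class = "cpcapture_input_error")
  }
  A <- encode_alignment(alignment[tree$tip.label])
  if (site_pattern_compression) {
    key <- apply(A, 2, paste, collapse = "\r")
    tab <- table(key)
    first <- match(names(tab), key)
    A <- A[, first, drop = FALSE]
    wt <- as.numeric(tab)
  } else {
    wt <- rep(1, ncol(A))
  }
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  npat <- ncol(A)
  partial <- vector("list", n + m)
  for (i in seq_len(n)) partial[[i]] <- IUPAC_PARTIALS[A[i, ], , drop = FALSE]
  for (node in unique(po$edge[, 1])) partial[[node]] <- matrix(1, npat, 4)
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]
    ch <- po$edge[k, 2]
    M <- jc_pmat(po$edge.length[k])
    partial[[p]] <- partial[[p]] * (partial[[ch]] %*% t(M))
  }
  root <- setdiff(po$edge[, 1], po$edge[, 2])[1]
  site_l <- as.vector(partial[[root]] %*% rep(0.25, 4))
  sum(wt * log(site_l))
}

# all unrooted binary topologies over `tips` by sequential taxon insertion
# (canonical enumeration order: for each existing tree, the new taxon is
# attached to each edge in storage order)
enumerate_topologies <- function(tips) {
  n <- length(tips)
  stopifnot(n >= 3)
  # node ids: tips 1..n, internal nodes n+1, n+2, ...
  trees <- list(matrix(c(n + 1, 1, n + 1, 2, n + 1, 3),
                       ncol = 2, byrow = TRUE))
  if (n > 3) {
    for (k in 4:n) {
      w <- n + (k - 2)
      trees <- unlist(lapply(trees, function(ed) {
        lapply(seq_len(nrow(ed)), function(r) {
          a <- ed[r, 1]
          b <- ed[r, 2]
          rbind(ed[-r, , drop = FALSE],
                c(a, w), c(w, b), c(w, k))
        })
      }), recursive = FALSE)
    }
  }
  lapply(trees, edgelist_to_phylo, tips = tips)
}

# internal edge-list (undirected, over tip ids 1..n and internal ids > n)
# -> phylo, via a newick string rooted at internal node n+1
edgelist_to_phylo <- function(ed, tips) {
  n <- length(tips)
  nb <- list()
  for (r in seq_len(nrow(ed))) {
    a <- as.character(ed[r, 1])
    b <- as.character(ed[r, 2])
    nb[[a]] <- c(nb[[a]], ed[r, 2])
    nb[[b]] <- c(nb[[b]], ed[r, 1])
  }
  rec <- function(node, parent) {
    if (node <= n) return(nwk_quote(tips[node]))
    kids <- setdiff(nb[[as.character(node)]], parent)
    paste0("(", paste(vapply(kids, rec, character(1), parent = node),
                      collapse = ","), ")")
  }
  parse_newick(paste0(rec(n + 1, -1L), ";"))
}

#' Exhaustive maximum-likelihood topology search (small trees)
#'
#' Scores every unrooted binary topology — (2n-5)!! of them — under JC69,
#' optimizing branch lengths per topology by cyclic one-dimensional (Brent)
#' search, and returns the top-scoring tree. Ties keep the topology that comes
#' first in the canonical enumeration order.
#'
#' @param alignment named character vector of equal-length IUPAC sequences.
#' @param max_leaves refuse alignments with more leaves than this (default 7);
#'   use [neighbor_joining()] beyond that.
#' @param tol convergence tolerance on the log-likelihood per sweep.
#' @param max_sweeps maximum branch-length optimization sweeps per topology.
#' @return a `phylo` with optimized branch lengths; attributes `logL` and
#'   `n_topologies`.
#' @export
exhaustive_ml_topology <- function(alignment, max_leaves = 7, tol = 1e-6,
                                   max_sweeps = 20) {
  n <- length(alignment)
  if (n < 3) {
    abort("need at least 3 sequences", class = "cpcapture_input_error")
  }
  if (n > max_leaves) {
    abort(sprintf(
      "%d leaves exceeds max_leaves = %d; use neighbor_joining() for large trees",
      n, max_leaves), class = "cpcapture_input_error")
  }
  topos <- enumerate_topologies(names(alignment))
  best <- NULL
  best_ll <- -Inf
  for (tr in topos) {
    tr$edge.length <- rep(0.1, nrow(tr$edge))
    ll <- jc_log_likelihood(tr, alignment)
    for (sweep in seq_len(max_sweeps)) {
      for (k in seq_len(nrow(tr$edge))) {
        opt <- optimize(function(t) {
          tr$edge.length[k] <- t
          jc_log_likelihood(tr, alignment)
        }, interval = c(1e-9, 5), maximum = TRUE, tol = tol)
        tr$edge.length[k] <- opt$maximum
      }
      ll_new <- jc_log_likelihood(tr, alignment)
      if (ll_new - ll < tol) {
        ll <- ll_new
        break
      }
      ll <- ll_new
    }
    if (ll > best_ll) {
      best <- tr
      best_ll <- ll
    }
  }
  attr(best, "logL") <- best_ll
  attr(best, "n_topologies") <- length(topos)
  best
}
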