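# Independent oracles used across the suite: brute-force Fitch, exhaustive
# ancestral-state likelihood summation, an independent affine-gap local
# aligner, a literal transcription of the fixed-ploidy filter rules, and
# small random-data generators.

rand_dna <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

rand_aa <- function(L) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], L, replace = TRUE),
        collapse = "")
}

# random unrooted binary tree with branch lengths
rand_unrooted <- function(n, min_bl = 0.1, max_bl = 1) {
  tr <- ape::rtree(n, br = function(k) runif(k, min_bl, max_bl))
  ape::unroot(tr)
}

# minimum state changes by enumeration over all internal-node assignments
brute_fitch <- function(tree, character) {
  states <- sort(unique(character[tree$tip.label]))
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  leafs <- match(character[tree$tip.label], states)
  combos <- as.matrix(expand.grid(rep(list(seq_along(states)), m)))
  st <- cbind(matrix(leafs, nrow(combos), n, byrow = TRUE), combos)
  e <- tree$edge
  changes <- Reduce(`+`, lapply(seq_len(nrow(e)), function(k) {
    st[, e[k, 1]] != st[, e[k, 2]]
  }))
  min(changes)
}

# IUPAC compatibility vectors for the likelihood oracle
oracle_compat <- local({
  sets <- list(A = 1, C = 2, G = 3, T = 4, R = c(1, 3), Y = c(2, 4),
               S = c(2, 3), W = c(1, 4), K = c(3, 4), M = c(1, 2),
               B = 2:4, D = c(1, 3, 4), H = c(1, 2, 4), V = 1:3, N = 1:4)
  lapply(sets, function(s) as.numeric(1:4 %in% s))
})

oracle_pjc <- function(t) {
  e <- exp(-4 * t / 3)
  m <- matrix(0.25 * (1 - e), 4, 4)
  diag(m) <- 0.25 + 0.75 * e
  m
}

# log-likelihood by brute-force summation over all internal-node base
# assignments (uniform root prior)
brute_jc_loglik <- function(tree, aln) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  e <- tree$edge
  Pm <- lapply(tree$edge.length, oracle_pjc)
  combos <- as.matrix(expand.grid(rep(list(1:4), m)))
  L <- nchar(aln[[1]])
  total <- 0
  for (s in seq_len(L)) {
    probs <- rep(0.25, nrow(combos))
    for (k in seq_len(nrow(e))) {
      par <- e[k, 1]
      ch <- e[k, 2]
      sp <- combos[, par - n]
      if (ch <= n) {
        cb <- oracle_compat[[substr(aln[[tree$tip.label[ch]]], s, s)]]
        probs <- probs * as.vector(Pm[[k]] %*% cb)[sp]
      } else {
        probs <- probs * Pm[[k]][cbind(sp, combos[, ch - n])]
      }
    }
    total <- total + log(sum(probs))
  }
  total
}

# independent affine-gap local aligner (Gotoh recurrences in plain R);
# a gap of length L costs open + L * ext
sw_gotoh <- function(a, b, open = 11, ext = 1) {
  S <- get_blosum62()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      prev <- max(0, M[i, j], X[i, j], Y[i, j])
      M[i + 1, j + 1] <- S[av[i], bv[j]] + prev
      X[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext),
                             X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext),
                             Y[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
    }
  }
  best
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# literal transcription of the fixed-ploidy site rules (coverage 10 /
# count 3 / frequency 25%; het band 25-75%; hom 100%)
literal_call <- function(nA, nC, nG, nT, ref,
                         min_coverage = 10, min_count = 3, min_freq = 0.25,
                         het_lo = 0.25, het_hi = 0.75, hom_min = 1.0) {
  cnt <- c(A = nA, C = nC, G = nG, T = nT)
  d <- sum(cnt)
  if (d < min_coverage) return(NULL)
  f <- cnt / d
  cand <- names(cnt)[cnt >= min_count & f >= min_freq]
  if (length(cand) == 2 &&
      all(f[cand] >= het_lo) && all(f[cand] <= het_hi)) {
    return(list(zygosity = "heterozygous", alleles = sort(cand)))
  }
  if (length(cand) == 1 && cand != ref && f[[cand]] >= hom_min) {
    return(list(zygosity = "homozygous", alleles = cand))
  }
  NULL
}

# all base-count 4-vectors with total depth <= dmax
enumerate_counts <- function(dmax) {
  g <- expand.grid(nA = 0:dmax, nC = 0:dmax, nG = 0:dmax, nT = 0:dmax)
  g[rowSums(g) <= dmax, , drop = FALSE]
}

species_map_of <- function(dataset) {
  setNames(dataset$accessions$species, dataset$accessions$id)
}

# nuclear supermatrix straight from the simulated diploid truth (IUPAC
# consensus of the two haplotypes), bypassing pileups
truth_supermatrix <- function(dataset) {
  ids <- dataset$accessions$id
  og <- dataset$config$species_names[5]
  rows <- vapply(ids, function(id) {
    paste(vapply(names(dataset$nuclear), function(g) {
      diploid_consensus(dataset$nuclear[[g]]$hap1[[id]],
                        dataset$nuclear[[g]]$hap2[[id]])
    }, character(1)), collapse = "")
  }, character(1))
  c(rows, setNames(paste(dataset$outgroup_nuclear, collapse = ""), og))
}
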