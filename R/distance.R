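# Ambiguity-aware pairwise distances (p-distance and JC69)

jc_transform <- function(p) {
  d <- ifelse(p >= 0.75, Inf, -0.75 * log(1 - 4 * p / 3))
  # numerical guard: tiny negative p cannot occur (p is a mean of [0,1] terms)
  d
}

#' Pairwise distance between two aligned sequences
#'
#' The raw statistic is the mean per-site mismatch. Under
#' `ambiguity = "expected_mismatch"` an IUPAC code contributes the expected
#' mismatch over its base set (e.g. `A` vs `R` contributes 0.5); under
#' `"pairwise_delete"` sites where either sequence is ambiguous are dropped.
#' `model = "JC69"` applies d = -(3/4) log(1 - 4p/3); p >= 0.75 yields `Inf`
#' (saturated).
#'
#' @param a,b equal-length IUPAC nucleotide strings.
#' @param model `"p"` or `"JC69"`.
#' @param ambiguity `"expected_mismatch"` or `"pairwise_delete"`.
#' @return a single non-negative number (possibly `Inf` when saturated).
#' @export
pairwise_distance <- function(a, b, model = c("p", "JC69"),
                              ambiguity = c("expected_mismatch",
                                            "pairwise_delete")) {
  model <- match.arg(model)
  ambiguity <- match.arg(ambiguity)
  if (nchar(a) != nchar(b)) {
    abort("sequences have unequal lengths", class = "cpcapture_input_error")
  }
  xa <- encode_seq(a)
  xb <- encode_seq(b)
  if (ambiguity == "pairwise_delete") {
    keep <- xa <= 4 & xb <= 4
    if (!any(keep)) {
      abort("no unambiguous sites left after pairwise deletion",
            class = "cpcapture_input_error")
    }
    p <- mean(xa[keep] != xb[keep])
  } else {
    p <- mean(IUPAC_MISMATCH[cbind(xa, xb)])
  }
  if (model == "p") p else jc_transform(p)
}

#' Distance matrix over a set of aligned sequences
#'
#' @param seqs named character vector of equal-length IUPAC sequences.
#' @inheritParams pairwise_distance
#' @return symmetric matrix with zero diagonal, labelled by sequence names;
#'   attribute `saturated` is `TRUE` if any JC entry was non-finite.
#' @export
seq_dist <- function(seqs, model = c("p", "JC69"),
                     ambiguity = c("expected_mismatch", "pairwise_delete")) {
  model <- match.arg(model)
  ambiguity <- match.arg(ambiguity)
  A <- encode_alignment(seqs)
  n <- nrow(A)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (ambiguity == "pairwise_delete") {
        keep <- A[i, ] <= 4 & A[j, ] <= 4
        p <- mean(A[i, keep] != A[j, keep])
      } else {
        p <- mean(IUPAC_MISMATCH[(A[j, ] - 1L) * 15L + A[i, ]])
      }
      D[i, j] <- D[j, i] <- if (model == "p") p else jc_transform(p)
    }
  }
  attr(D, "saturated") <- any(!is.finite(D))
  D
}

# per-pair per-site expected-mismatch profile: (n choose 2) x L matrix, plus
# the pair index. Used by the fast bootstrap path: a column-resampled
# p-distance is profile %*% weights / L.
mismatch_profile <- function(seqs) {
  A <- encode_alignment(seqs)
  n <- nrow(A)
  L <- ncol(A)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  P <- matrix(0, nrow(pairs), L)
  for (k in seq_len(nrow(pairs))) {
    P[k, ] <- IUPAC_MISMATCH[(A[pairs[k, 2], ] - 1L) * 15L + A[pairs[k, 1], ]]
  }
  list(profile = P, pairs = pairs, labels = names(seqs), L = L)
}

# rebuild a labelled distance matrix from profile p-distances
profile_to_dist <- function(mp, p, model) {
  n <- length(mp$labels)
  D <- matrix(0, n, n, dimnames = list(mp$labels, mp$labels))
  d <- if (model == "p") p else jc_transform(p)
  D[mp$pairs] <- d
  D[mp$pairs[, c(2, 1), drop = FALSE]] <- d
  D
}
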