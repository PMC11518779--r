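# IUPAC nucleotide alphabet, integer encoding, and the expected-mismatch
# lookup used by ambiguity-aware distances and the pruning likelihood.

IUPAC_LETTERS <- c("A", "C", "G", "T",
                   "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# code for an unordered pair of distinct bases (het genotype encoding)
IUPAC_PAIR <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

# 15 x 15: expected per-site mismatch when each code is read as a uniform
# draw over its base set; A vs R = 0.5, R vs R = 0.5, A vs A = 0.
IUPAC_MISMATCH <- local({
  m <- matrix(0, 15, 15, dimnames = list(IUPAC_LETTERS, IUPAC_LETTERS))
  for (i in IUPAC_LETTERS) {
    for (j in IUPAC_LETTERS) {
      si <- IUPAC_SETS[[i]]
      sj <- IUPAC_SETS[[j]]
      m[i, j] <- 1 - length(intersect(si, sj)) / (length(si) * length(sj))
    }
  }
  m
})

# 15 x 4 indicator of compatible bases (leaf partial likelihoods)
IUPAC_PARTIALS <- local({
  m <- matrix(0, 15, 4, dimnames = list(IUPAC_LETTERS, c("A", "C", "G", "T")))
  for (i in IUPAC_LETTERS) m[i, IUPAC_SETS[[i]]] <- 1
  m
})

#' Encode a nucleotide string as integer IUPAC indices
#'
#' @param s a single character string over the IUPAC alphabet (case
#'   insensitive); `-` and `.` are not accepted.
#' @return integer vector with values in 1..15 (A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N).
#' @keywords internal
#' @noRd
encode_seq <- function(s) {
  x <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], IUPAC_LETTERS)
  if (anyNA(x)) {
    abort(sprintf("non-IUPAC nucleotide character at position %d",
                  which(is.na(x))[1]), class = "cpcapture_input_error")
  }
  x
}

decode_seq <- function(x) paste(IUPAC_LETTERS[x], collapse = "")

# named character vector of equal-length sequences -> n x L integer matrix
encode_alignment <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    abort("sequences have unequal lengths", class = "cpcapture_input_error")
  }
  m <- vapply(seqs, encode_seq, integer(lens[1]))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)  # single-site alignment
  structure(t(m), dimnames = list(names(seqs), NULL))
}

#' IUPAC ambiguity code for a heterozygous base pair
#'
#' @param a,b distinct bases in `A`, `C`, `G`, `T` (vectorised).
#' @return the one-letter ambiguity code (e.g. `A`,`G` -> `R`).
#' @export
#' @examples
#' iupac_ambiguity("A", "G")  # "R"
iupac_ambiguity <- function(a, b) {
  key <- ifelse(a < b, paste0(a, b), paste0(b, a))
  out <- unname(IUPAC_PAIR[key])
  if (anyNA(out)) {
    abort("iupac_ambiguity() needs two distinct bases among A,C,G,T",
          class = "cpcapture_input_error")
  }
  out
}
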