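# Fixed-ploidy (diploid) site classification and the post-filters:
# minimum coverage 10, minimum allele count 3, minimum allele frequency 25%;
# retained variants are heterozygous (both alleles within 25-75%) or
# homozygous non-reference (100% frequency by default).

#' Variant caller thresholds
#'
#' Defaults are the fixed-ploidy detection settings and manual frequency
#' filters of the source workflow: coverage >= 10, allele count >= 3, allele
#' frequency >= 25%; heterozygous calls need both alleles in the 25-75% band,
#' homozygous calls need 100% frequency. `hom_min` may be relaxed (e.g. 0.97)
#' for data with sequencing error.
#'
#' @param min_coverage minimum site depth.
#' @param min_count minimum reads supporting a candidate allele.
#' @param min_freq minimum candidate allele frequency.
#' @param het_lo,het_hi heterozygous allele-frequency band.
#' @param hom_min minimum frequency for a homozygous non-reference call.
#' @return a `cpcapture_caller_config` list.
#' @export
caller_config <- function(min_coverage = 10, min_count = 3, min_freq = 0.25,
                          het_lo = 0.25, het_hi = 0.75, hom_min = 1.0) {
  if (min_freq <= 0 || min_freq > het_lo || het_lo > het_hi || het_hi >= 1) {
    abort("need 0 < min_freq <= het_lo <= het_hi < 1",
          class = "cpcapture_config_error")
  }
  if (hom_min <= het_hi || hom_min > 1) {
    abort("need het_hi < hom_min <= 1", class = "cpcapture_config_error")
  }
  if (min_coverage < 1 || min_count < 1) {
    abort("min_coverage and min_count must be >= 1",
          class = "cpcapture_config_error")
  }
  structure(list(min_coverage = min_coverage, min_count = min_count,
                 min_freq = min_freq, het_lo = het_lo, het_hi = het_hi,
                 hom_min = hom_min),
            class = "cpcapture_caller_config")
}

#' Classify one site from its base counts
#'
#' Returns `NULL` (no-call) unless the site passes the fixed-ploidy rules:
#' depth >= `min_coverage`; candidate alleles are bases with count >=
#' `min_count` and frequency >= `min_freq`; a heterozygous call requires
#' exactly two candidates, both inside the `[het_lo, het_hi]` band; a
#' homozygous call requires exactly one candidate, different from the
#' reference, at frequency >= `hom_min`. Everything else is discarded.
#'
#' @param counts named numeric vector of base counts (names among A,C,G,T).
#' @param ref the reference base at the site.
#' @param cfg a [caller_config()].
#' @param gene_id,pos optional coordinates copied into the call.
#' @return a one-row tibble (`gene_id`, `pos`, `ref`, `alleles`, `freqs`,
#'   `zygosity`, `depth`) or `NULL`.
#' @export
call_site <- function(counts, ref, cfg = caller_config(),
                      gene_id = NA_character_, pos = NA_integer_) {
  if (any(counts < 0) || anyNA(counts) ||
      !all(names(counts) %in% c("A", "C", "G", "T"))) {
    abort("malformed base counts", class = "cpcapture_input_error")
  }
  if (!ref %in% c("A", "C", "G", "T")) {
    abort("ref base must be one of A,C,G,T", class = "cpcapture_input_error")
  }
  depth <- sum(counts)
  if (depth < cfg$min_coverage) return(NULL)
  freq <- counts / depth
  cand <- names(counts)[counts >= cfg$min_count & freq >= cfg$min_freq]
  if (length(cand) == 2) {
    f <- freq[cand]
    if (all(f >= cfg$het_lo & f <= cfg$het_hi)) {
      ord <- order(cand)
      return(tibble(gene_id = gene_id, pos = pos, ref = ref,
                    alleles = paste(cand[ord], collapse = "/"),
                    freqs = paste(sprintf("%.6g", f[ord]), collapse = "/"),
                    zygosity = "heterozygous", depth = depth))
    }
  } else if (length(cand) == 1 && cand != ref &&
             freq[cand] >= cfg$hom_min) {
    return(tibble(gene_id = gene_id, pos = pos, ref = ref,
                  alleles = cand, freqs = sprintf("%.6g", freq[[cand]]),
                  zygosity = "homozygous", depth = depth))
  }
  NULL
}

#' Call variants over a gene pileup (vectorised)
#'
#' Applies the [call_site()] rules to every row of a pileup table. Positions
#' absent from the pileup are no-calls.
#'
#' @param pileup tibble with columns `gene_id`, `pos` (1-based), `ref`, `nA`,
#'   `nC`, `nG`, `nT` (one or several genes).
#' @param ref_length optional named vector of reference CDS lengths; when
#'   given, positions outside the reference raise an error.
#' @param cfg a [caller_config()].
#' @return tibble of calls sorted by (`gene_id`, `pos`) with the [call_site()]
#'   columns.
#' @export
call_gene <- function(pileup, cfg = caller_config(), ref_length = NULL) {
  need <- c("gene_id", "pos", "ref", "nA", "nC", "nG", "nT")
  if (!all(need %in% names(pileup))) {
    abort(sprintf("pileup is missing column(s): %s",
                  paste(setdiff(need, names(pileup)), collapse = ", ")),
          class = "cpcapture_input_error")
  }
  if (!is.null(ref_length)) {
    bad <- pileup$pos < 1 | pileup$pos > ref_length[pileup$gene_id]
    if (any(bad, na.rm = TRUE) || anyNA(bad)) {
      abort("pileup position outside the reference CDS",
            class = "cpcapture_input_error")
    }
  }
  cm <- cbind(pileup$nA, pileup$nC, pileup$nG, pileup$nT)
  if (any(cm < 0) || anyNA(cm)) {
    abort("malformed base counts", class = "cpcapture_input_error")
  }
  bases <- c("A", "C", "G", "T")
  depth <- rowSums(cm)
  fq <- cm / pmax(depth, 1)
  is_cand <- cm >= cfg$min_count & fq >= cfg$min_freq & depth >= cfg$min_coverage
  ncand <- rowSums(is_cand)
  in_band <- is_cand & fq >= cfg$het_lo & fq <= cfg$het_hi
  het <- ncand == 2 & rowSums(in_band) == 2
  refi <- match(pileup$ref, bases)
  cand1 <- max.col(is_cand, ties.method = "first")
  hom <- ncand == 1 & cand1 != refi &
    fq[cbind(seq_len(nrow(cm)), cand1)] >= cfg$hom_min
  rows <- which(het | hom)
  if (length(rows) == 0) {
    return(tibble(gene_id = character(0), pos = integer(0),
                  ref = character(0), alleles = character(0),
                  freqs = character(0), zygosity = character(0),
                  depth = numeric(0)))
  }
  alleles <- freqs <- character(length(rows))
  for (k in seq_along(rows)) {
    r <- rows[k]
    a <- which(is_cand[r, ])
    alleles[k] <- paste(bases[a], collapse = "/")
    freqs[k] <- paste(sprintf("%.6g", fq[r, a]), collapse = "/")
  }
  out <- tibble(gene_id = pileup$gene_id[rows],
                pos = as.integer(pileup$pos[rows]),
                ref = pileup$ref[rows],
                alleles = alleles, freqs = freqs,
                zygosity = ifelse(het[rows], "heterozygous", "homozygous"),
                depth = depth[rows])
  dplyr::arrange(out, .data$gene_id, .data$pos)
}

#' Write / read a variant CSV table
#'
#' Lossless round-trip of call tables; columns `gene_id`, `pos` (1-based),
#' `ref`, `alleles` (e.g. `"A/G"`), `freqs` (e.g. `"0.4/0.6"`), `zygosity`,
#' `depth`.
#'
#' @param calls a call tibble as produced by [call_gene()].
#' @param path file path.
#' @return `write_variant_csv`: `path` invisibly; `read_variant_csv`: a call
#'   tibble.
#' @export
write_variant_csv <- function(calls, path) {
  readr::write_csv(calls[, c("gene_id", "pos", "ref", "alleles", "freqs",
                             "zygosity", "depth")], path)
  invisible(path)
}

#' @rdname write_variant_csv
#' @export
read_variant_csv <- function(path) {
  need <- c("gene_id", "pos", "ref", "alleles", "freqs", "zygosity", "depth")
  out <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(
      gene_id = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), alleles = readr::col_character(),
      freqs = readr::col_character(), zygosity = readr::col_character(),
      depth = readr::col_double())),
    warning = function(w) {
      abort(sprintf("unparseable variant CSV %s: %s", path,
                    conditionMessage(w)), class = "cpcapture_format_error")
    })
  if (!identical(names(out), need)) {
    abort(sprintf("variant CSV header mismatch in %s", path),
          class = "cpcapture_format_error")
  }
  as_tibble(out)
}

#' Call variants for every accession of a dataset
#'
#' @param pileups named list of pileup tibbles (see [simulate_pileups()]).
#' @param cfg a [caller_config()].
#' @return named list of call tibbles.
#' @export
call_pileups <- function(pileups, cfg = caller_config()) {
  lapply(pileups, call_gene, cfg = cfg)
}
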