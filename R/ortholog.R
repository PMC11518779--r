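# Single-copy ortholog selection: translated Smith-Waterman search of protein
# queries against nucleotide CDS databases, single-hit filtering, and
# intersection across reference databases.

AA_REGEX <- "^[ACDEFGHIKLMNPQRSTVWYBJZXU*]+$"
NT_REGEX <- "^[ACGTRYSWKMBDHVN]+$"

# forward-frame translations (frames 0,1,2) of a nucleotide string; optionally
# also the reverse-complement frames
translate_frames <- function(dna, reverse = FALSE) {
  d <- Biostrings::DNAString(dna)
  strands <- list(fwd = d)
  if (reverse) strands$rev <- Biostrings::reverseComplement(d)
  out <- list()
  for (sn in names(strands)) {
    s <- strands[[sn]]
    for (f in 0:2) {
      n <- length(s) - f
      n <- n - n %% 3
      if (n < 3) next
      aa <- suppressWarnings(Biostrings::translate(
        Biostrings::subseq(s, start = f + 1, width = n),
        if.fuzzy.codon = "X"))
      out[[paste0(sn, f)]] <- as.character(aa)
    }
  }
  out
}

#' Translate a coding sequence (frame 0)
#'
#' @param cds nucleotide string whose length is a multiple of 3.
#' @return amino-acid string (stop codons as `*`).
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3 != 0) {
    abort("CDS length is not a multiple of 3", class = "cpcapture_input_error")
  }
  as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "X")))
}

#' Translated local search of protein queries against a CDS database
#'
#' Smith-Waterman local alignment (BLOSUM62, affine gaps open 11 / extend 1 —
#' the classic translated-search defaults) of each query against all three
#' forward-frame translations of each subject. One hit is reported per
#' (query, subject) pair whose best frame scores at least `min_score` (raw
#' alignment score; see [bit_score()] for the bit conversion).
#'
#' @param queries named character vector of amino-acid sequences.
#' @param subjects named character vector of nucleotide CDS.
#' @param min_score raw-score acceptance threshold.
#' @param reverse_frames also search the three reverse-complement frames
#'   (default off: CDS databases are stranded).
#' @return tibble with columns `query_id`, `subject_id`, `frame`, `score`,
#'   `identity` (fraction of alignment columns), `aln_length`, sorted by
#'   (`query_id`, -`score`).
#' @export
translated_search <- function(queries, subjects, min_score = 70,
                              reverse_frames = FALSE) {
  if (length(subjects) == 0) {
    return(tibble(query_id = character(0), subject_id = character(0),
                  frame = character(0), score = numeric(0),
                  identity = numeric(0), aln_length = integer(0)))
  }
  if (!all(grepl(AA_REGEX, toupper(queries)))) {
    abort("queries contain non-amino-acid residues",
          class = "cpcapture_input_error")
  }
  if (!all(grepl(NT_REGEX, toupper(subjects)))) {
    abort("subjects contain non-IUPAC nucleotide characters",
          class = "cpcapture_input_error")
  }
  frames <- lapply(subjects, translate_frames, reverse = reverse_frames)
  frame_seq <- unlist(unname(Map(function(fr, sid) {
    setNames(unlist(fr), paste(sid, names(fr), sep = "\r"))
  }, frames, names(subjects))))
  frame_set <- Biostrings::AAStringSet(frame_seq)
  hits <- list()
  for (q in names(queries)) {
    pat <- Biostrings::AAString(toupper(queries[[q]]))
    sc <- Biostrings::pairwiseAlignment(
      frame_set, pat, type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    info <- do.call(rbind, strsplit(names(frame_seq), "\r", fixed = TRUE))
    best <- tapply(seq_along(sc), info[, 1], function(ix) ix[which.max(sc[ix])])
    for (sid in names(best)) {
      k <- best[[sid]]
      if (sc[k] < min_score) next
      aln <- Biostrings::pairwiseAlignment(
        frame_set[k], pat, type = "local",
        substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
      width <- unname(nchar(as.character(Biostrings::alignedPattern(aln))))
      hits[[length(hits) + 1]] <- tibble(
        query_id = q, subject_id = sid, frame = unname(info[k, 2]),
        score = unname(sc[k]),
        identity = unname(Biostrings::nmatch(aln)) / width,
        aln_length = width)
    }
  }
  if (length(hits) == 0) {
    return(tibble(query_id = character(0), subject_id = character(0),
                  frame = character(0), score = numeric(0),
                  identity = numeric(0), aln_length = integer(0)))
  }
  out <- dplyr::bind_rows(hits)
  dplyr::arrange(out, .data$query_id, dplyr::desc(.data$score))
}

#' Convert a raw local-alignment score to bits (and back)
#'
#' Uses the standard gapped BLOSUM62 Karlin-Altschul parameters
#' (lambda = 0.267, K = 0.041).
#'
#' @param raw raw alignment score.
#' @param lambda,K Karlin-Altschul parameters.
#' @return bit score.
#' @export
bit_score <- function(raw, lambda = 0.267, K = 0.041) {
  (lambda * raw - log(K)) / log(2)
}

#' @rdname bit_score
#' @param bits bit score.
#' @export
raw_score <- function(bits, lambda = 0.267, K = 0.041) {
  (bits * log(2) + log(K)) / lambda
}

#' Queries hitting exactly one distinct subject
#'
#' "Single hit" counts distinct subjects (single-copy detection), not HSPs;
#' the result is invariant to the ordering of the hit table.
#'
#' @param hits a hit tibble (see [translated_search()]).
#' @return sorted character vector of query ids.
#' @export
select_single_hit_queries <- function(hits) {
  if (nrow(hits) == 0) return(character(0))
  n_subj <- tapply(hits$subject_id, hits$query_id,
                   function(s) length(unique(s)))
  sort(names(n_subj)[n_subj == 1])
}

#' Intersect single-hit selections across reference databases
#'
#' Keeps the genes that are single-hit in every database, in the reference
#' panel's order (stable supermatrix column order).
#'
#' @param per_db_selected list of character vectors of selected query ids
#'   (one per reference database).
#' @param panel panel tibble (`gene_id`, `sequence`).
#' @return the panel restricted to the shared single-copy genes.
#' @export
intersect_across_references <- function(per_db_selected, panel) {
  if (length(per_db_selected) == 0) {
    abort("need at least one reference database result",
          class = "cpcapture_input_error")
  }
  shared <- Reduce(intersect, per_db_selected)
  out <- panel[panel$gene_id %in% shared, , drop = FALSE]
  if (nrow(out) == 0) {
    abort("no shared single-copy genes across the reference databases",
          class = "cpcapture_selection_error")
  }
  out
}

#' Import search hits from 12-column tabular output
#'
#' Reads the classic 12-column tab-separated hit format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bit score), so an external search tool can
#' substitute for the internal aligner.
#'
#' @param path file path.
#' @param dialect only `"blast_tab_12col"`.
#' @return hit tibble (`query_id`, `subject_id`, `identity` as a fraction,
#'   `aln_length`, `score` = bit score).
#' @export
import_tabular_hits <- function(path, dialect = "blast_tab_12col") {
  dialect <- match.arg(dialect, "blast_tab_12col")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(query_id = character(0), subject_id = character(0),
                  identity = numeric(0), aln_length = integer(0),
                  score = numeric(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12)
  if (length(bad) > 0) {
    abort(sprintf("malformed 12-column hit row at line %d of %s",
                  bad[1], path), class = "cpcapture_format_error")
  }
  m <- do.call(rbind, parts)
  num <- suppressWarnings(list(pident = as.numeric(m[, 3]),
                               len = as.integer(m[, 4]),
                               bits = as.numeric(m[, 12])))
  badnum <- which(is.na(num$pident) | is.na(num$len) | is.na(num$bits))
  if (length(badnum) > 0) {
    abort(sprintf("non-numeric field at line %d of %s", badnum[1], path),
          class = "cpcapture_format_error")
  }
  tibble(query_id = m[, 1], subject_id = m[, 2],
         identity = num$pident / 100, aln_length = num$len,
         score = num$bits)
}

#' @rdname import_tabular_hits
#' @param hits hit tibble with columns `query_id`, `subject_id`, `identity`,
#'   `aln_length`, `score`.
#' @export
write_tabular_hits <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%.4f\t%d\t0\t0\t1\t%d\t1\t%d\t0\t%.4f",
                   hits$query_id, hits$subject_id, hits$identity * 100,
                   hits$aln_length, hits$aln_length, hits$aln_length,
                   hits$score)
  writeLines(lines, path)
  invisible(path)
}

#' Select the single-copy gene panel from reference databases
#'
#' Full selection pipeline: translate the panel CDS, search each reference
#' database, keep single-hit queries per database, intersect across databases.
#'
#' @param panel reference panel tibble (`gene_id`, `sequence`).
#' @param reference_dbs named list of nucleotide CDS databases (named
#'   character vectors).
#' @param min_score raw-score threshold for [translated_search()].
#' @return the restricted panel, with attribute `per_db` (the per-database
#'   selections).
#' @export
select_gene_panel <- function(panel, reference_dbs, min_score = 70) {
  queries <- setNames(vapply(panel$sequence, translate_cds, character(1)),
                      panel$gene_id)
  per_db <- lapply(reference_dbs, function(db) {
    select_single_hit_queries(
      translated_search(queries, db, min_score = min_score))
  })
  out <- intersect_across_references(per_db, panel)
  attr(out, "per_db") <- per_db
  out
}
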