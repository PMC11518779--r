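# Per-accession CDS reconstruction from a variant table (heterozygous sites
# become IUPAC ambiguity codes) and concatenation into a supermatrix in fixed
# panel order.

#' Apply a variant table to a reference CDS
#'
#' Homozygous calls substitute the allele; heterozygous calls substitute the
#' IUPAC code of the two alleles (A/G -> R, C/T -> Y, ...). All other
#' positions keep the reference base (consensus semantics), or `N` when
#' `mask_nocall` positions are supplied. `haploidize = "major"` writes the
#' higher-frequency allele instead of the ambiguity code.
#'
#' @param ref_cds reference CDS string.
#' @param calls call tibble for this gene (may be empty).
#' @param gene_id used for error messages and to subset `calls`.
#' @param haploidize `"iupac"` (default) or `"major"`.
#' @param mask_nocall optional integer positions to set to `N` (e.g.
#'   low-coverage sites).
#' @return the reconstructed sequence string.
#' @export
apply_variants <- function(ref_cds, calls, gene_id = NULL,
                           haploidize = c("iupac", "major"),
                           mask_nocall = NULL) {
  haploidize <- match.arg(haploidize)
  if (!is.null(gene_id) && nrow(calls) > 0) {
    calls <- calls[calls$gene_id == gene_id, , drop = FALSE]
  }
  x <- strsplit(toupper(ref_cds), "", fixed = TRUE)[[1]]
  if (!is.null(mask_nocall)) x[mask_nocall] <- "N"
  if (nrow(calls) > 0) {
    if (any(calls$pos < 1 | calls$pos > length(x))) {
      abort("variant position outside the reference CDS",
            class = "cpcapture_input_error")
    }
    mism <- x[calls$pos] != calls$ref
    if (any(mism)) {
      k <- which(mism)[1]
      abort(sprintf(
        "reference mismatch at %s pos %d: CDS has %s, call says %s",
        calls$gene_id[k] %||% "?", calls$pos[k], x[calls$pos[k]],
        calls$ref[k]), class = "cpcapture_consistency_error")
    }
    for (k in seq_len(nrow(calls))) {
      al <- strsplit(calls$alleles[k], "/", fixed = TRUE)[[1]]
      if (length(al) == 1) {
        x[calls$pos[k]] <- al
      } else if (haploidize == "iupac") {
        x[calls$pos[k]] <- iupac_ambiguity(al[1], al[2])
      } else {
        fr <- as.numeric(strsplit(calls$freqs[k], "/", fixed = TRUE)[[1]])
        x[calls$pos[k]] <- al[which.max(fr)]
      }
    }
  }
  paste(x, collapse = "")
}

#' IUPAC consensus of a diploid haplotype pair
#'
#' Matching sites keep the base; mismatching sites become the two-base
#' ambiguity code. This is the genotype encoding that a perfect
#' pileup -> call -> [apply_variants()] chain reconstructs.
#'
#' @param hap1,hap2 equal-length A/C/G/T strings.
#' @return IUPAC consensus string.
#' @export
diploid_consensus <- function(hap1, hap2) {
  a <- encode_seq(hap1)
  b <- encode_seq(hap2)
  if (length(a) != length(b)) {
    abort("haplotypes have unequal lengths", class = "cpcapture_input_error")
  }
  if (any(a > 4) || any(b > 4)) {
    abort("haplotypes must be unambiguous A/C/G/T",
          class = "cpcapture_input_error")
  }
  bases <- c("A", "C", "G", "T")
  out <- bases[a]
  het <- which(a != b)
  if (length(het) > 0) {
    out[het] <- iupac_ambiguity(bases[a[het]], bases[b[het]])
  }
  paste(out, collapse = "")
}

#' Concatenate per-gene sequences in panel order
#'
#' @param per_gene named character vector or list mapping gene id to the
#'   accession's sequence for that gene.
#' @param panel tibble with columns `gene_id`, `sequence` (the reference
#'   panel; its row order fixes the supermatrix block order).
#' @return list with `sequence` (the concatenated row) and `blocks` (tibble
#'   `gene_id`, `start`, `end`, 0-based half-open).
#' @export
concatenate_genes <- function(per_gene, panel) {
  missing <- setdiff(panel$gene_id, names(per_gene))
  if (length(missing) > 0) {
    abort(sprintf("missing gene(s) for concatenation: %s",
                  paste(missing, collapse = ", ")),
          class = "cpcapture_completeness_error")
  }
  seqs <- unlist(per_gene[panel$gene_id])
  lens <- unname(nchar(seqs))
  ends <- cumsum(lens)
  list(sequence = paste(seqs, collapse = ""),
       blocks = tibble(gene_id = panel$gene_id,
                       start = ends - lens, end = ends))
}

#' Build the concatenated supermatrix for a set of accessions
#'
#' One row per accession: each gene is reconstructed from the accession's
#' variant table against that gene's reference CDS, then genes are joined in
#' panel order. Accessions with an empty variant table get the reference
#' concatenation (e.g. a reference-quality outgroup contributes its own
#' sequences via `extra_rows`).
#'
#' @param accession_ids character vector (row order of the supermatrix).
#' @param panel reference panel tibble (`gene_id`, `sequence`).
#' @param variant_tables named list: accession id -> call tibble (possibly
#'   empty). Genes are looked up inside each table by `gene_id`.
#' @param references optional named list: accession id -> named character
#'   vector of per-gene reference CDS, when accessions were called against
#'   different (e.g. own-species) references; default: the panel for all.
#' @param extra_rows optional named list: accession id -> named per-gene
#'   sequences appended verbatim (outgroup).
#' @param haploidize passed to [apply_variants()].
#' @return a `cpcapture_supermatrix`: list with `sequences` (named character
#'   vector) and `blocks` (gene coordinate tibble, 0-based half-open).
#' @export
build_supermatrix <- function(accession_ids, panel, variant_tables,
                              references = NULL, extra_rows = NULL,
                              haploidize = "iupac") {
  rows <- list()
  blocks <- NULL
  for (id in accession_ids) {
    calls <- variant_tables[[id]]
    if (is.null(calls)) {
      abort(sprintf("no variant table for accession %s", id),
            class = "cpcapture_completeness_error")
    }
    refs <- if (is.null(references)) {
      setNames(panel$sequence, panel$gene_id)
    } else {
      references[[id]]
    }
    per_gene <- setNames(vapply(panel$gene_id, function(g) {
      tryCatch(
        apply_variants(refs[[g]], calls, gene_id = g,
                       haploidize = haploidize),
        error = function(e) {
          abort(sprintf("accession %s: %s", id, conditionMessage(e)),
                class = class(e)[1])
        })
    }, character(1)), panel$gene_id)
    cc <- concatenate_genes(per_gene, panel)
    rows[[id]] <- cc$sequence
    blocks <- cc$blocks
  }
  for (id in names(extra_rows)) {
    cc <- concatenate_genes(extra_rows[[id]], panel)
    rows[[id]] <- cc$sequence
    blocks <- cc$blocks
  }
  structure(list(sequences = unlist(rows), blocks = blocks),
            class = "cpcapture_supermatrix")
}

#' Write a supermatrix as FASTA plus a partition table
#'
#' @param sm a `cpcapture_supermatrix`.
#' @param fasta_path,partition_path output paths (partition TSV columns:
#'   `gene_id`, `start`, `end`, 0-based half-open).
#' @return invisibly, the two paths.
#' @export
write_supermatrix <- function(sm, fasta_path, partition_path) {
  write_fasta(sm$sequences, fasta_path)
  readr::write_tsv(sm$blocks, partition_path)
  invisible(c(fasta_path, partition_path))
}
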