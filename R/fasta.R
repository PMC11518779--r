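# FASTA input/output (thin wrappers over Biostrings, returning tibbles)

#' Read a FASTA file
#'
#' Sequence ids are the header text up to the first whitespace; the remainder
#' is kept as the description. Works for nucleotide and protein records.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path),
          class = "cpcapture_input_error")
  }
  x <- Biostrings::readBStringSet(path)
  headers <- names(x)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(id)) {
    abort(sprintf("duplicate FASTA id: %s", id[duplicated(id)][1]),
          class = "cpcapture_format_error")
  }
  tibble(id = id, description = desc,
         sequence = toupper(as.character(x, use.names = FALSE)))
}

#' Write sequences to a FASTA file
#'
#' @param records either a named character vector of sequences or a tibble
#'   with columns `id`, `sequence` and optionally `description`.
#' @param path output path.
#' @param wrap line width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60) {
  if (is.character(records)) {
    if (is.null(names(records)) || any(names(records) == "")) {
      abort("a character vector of sequences must be named",
            class = "cpcapture_input_error")
    }
    records <- tibble(id = names(records), description = "",
                      sequence = unname(records))
  }
  if (anyDuplicated(records$id)) {
    abort("duplicate sequence ids", class = "cpcapture_input_error")
  }
  desc <- if ("description" %in% names(records)) records$description else ""
  headers <- ifelse(desc == "", records$id, paste(records$id, desc))
  x <- Biostrings::BStringSet(setNames(records$sequence, headers))
  Biostrings::writeXStringSet(x, filepath = path, width = wrap)
  invisible(path)
}

# convenience: tibble from read_fasta -> named character vector
fasta_as_vector <- function(fa) setNames(fa$sequence, fa$id)
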