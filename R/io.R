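# Readers/writers for the plain-text formats the pipeline consumes:
# FASTA for sequences, TSV-with-header for orthology/hit/term tables.

#' Read coding sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning the tabular
#' sequence representation used throughout the package. Duplicate record ids
#' are rejected. The id is the first whitespace-delimited token of the header.
#'
#' @param path FASTA file path.
#' @param species Optional species label attached to every record.
#' @param frame_offset 0-based frame offset applied to every record.
#' @return Tibble with columns `id`, `species`, `nucleotides`, `frame_offset`.
#' @export
read_fasta <- function(path, species = NA_character_, frame_offset = 0L) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate FASTA id(s) in ", path, ": ",
                 paste(dup, collapse = ", ")))
  }
  tibble(
    id = ids,
    species = species,
    nucleotides = unname(toupper(as.character(set))),
    frame_offset = as.integer(frame_offset)
  )
}

#' Write coding sequences to FASTA
#'
#' @param seqs Sequence tibble (columns `id`, `nucleotides`).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  seqs <- .as_sequence_tbl(seqs)
  set <- Biostrings::DNAStringSet(setNames(seqs$nucleotides, seqs$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read an orthology assignment table
#'
#' TSV with header columns `seq_id`, `group_id`, `bitscore`, `evalue`, one or
#' more rows per sequence (as produced by a profile search of each library
#' against a database of orthologous groups).
#'
#' @param path TSV path.
#' @return Tibble with the four columns, `evalue` validated non-negative.
#' @export
read_orthology <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           seq_id = readr::col_character(),
                           group_id = readr::col_character(),
                           bitscore = readr::col_double(),
                           evalue = readr::col_double()
                         ))
  if (any(tbl$evalue < 0)) abort("negative e-value in orthology table")
  tbl
}

#' @rdname read_orthology
#' @param tbl Orthology tibble to serialize.
#' @export
write_orthology <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read a 12-column BLAST outfmt-6-style hit table
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore. Coordinates are 1-based inclusive in the file and are
#' converted to 0-based half-open internally.
#'
#' @param path TSV path (no header).
#' @return Tibble with converted coordinates (`qstart`, `sstart` 0-based;
#'   `qend`, `send` exclusive).
#' @export
read_blast_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tbl <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                         col_types = "ccdiiiiiiidd")
  tbl |>
    mutate(
      qstart = .data$qstart - 1L,
      sstart = .data$sstart - 1L
    )
}

#' Read a term-to-category map
#'
#' TSV with header columns `term_id`, `categories` (string of single-letter
#' COG/KOG category codes; a term may map to several), and optionally
#' `description`.
#'
#' @param path TSV path.
#' @return Tibble with `term_id` and `categories`.
#' @export
read_term_map <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("term_id", "categories") %in% names(tbl))) {
    abort("term map needs columns `term_id` and `categories`")
  }
  tbl
}

#' Read a term hit table
#'
#' TSV with header columns `seq_id`, `term_id`, `evalue` and optionally
#' `bitscore`; multiple hits per sequence allowed.
#'
#' @param path TSV path.
#' @return Tibble of hits.
#' @export
read_term_hits <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("seq_id", "term_id", "evalue")
  if (!all(need %in% names(tbl))) {
    abort("term hit table needs columns seq_id, term_id, evalue")
  }
  bad <- which(is.na(tbl$seq_id) | is.na(tbl$term_id) | is.na(tbl$evalue) |
                 tbl$evalue < 0)
  if (length(bad)) {
    abort(paste0("malformed term hit row(s) at line ", bad[1] + 1L))
  }
  tbl
}
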