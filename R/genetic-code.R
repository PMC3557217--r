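# Genetic-code utilities shared by every stage of the pipeline.
#
# All codon-level lookups are precomputed once at load time as flat vectors
# indexed by codon string, so classification of large column tables stays
# vectorized.

#' The standard genetic code
#'
#' Returns the standard nuclear genetic code as a translation table plus the
#' synonymous codon families derived from it. The table is taken from
#' [Biostrings::GENETIC_CODE]; families group the 61 sense codons by the
#' amino acid they encode (serine's TCN and AGY codons form a single family,
#' because synonymy is defined purely by identical translation).
#'
#' @return A list of class `genetic_code` with elements
#'   * `table`: named character vector mapping the 64 codons to one-letter
#'     amino acids or `"*"` for stop,
#'   * `families`: named list mapping each amino acid to its codon vector.
#' @examples
#' code <- standard_genetic_code()
#' code$table[["ATG"]]
#' code$families[["S"]]
#' @export
standard_genetic_code <- function() {
  tab <- Biostrings::GENETIC_CODE
  fams <- split(names(tab)[tab != "*"], tab[tab != "*"])
  structure(list(table = c(tab), families = fams), class = "genetic_code")
}

# Internal lookup environment built from the standard code.
.code_env <- new.env(parent = emptyenv())

.init_code_tables <- function() {
  code <- standard_genetic_code()
  tab <- code$table
  .code_env$table <- tab
  .code_env$families <- code$families
  .code_env$sense_codons <- names(tab)[tab != "*"]
  .code_env$stop_codons <- names(tab)[tab == "*"]
  # 59 informative codons for usage analyses: sense minus ATG and TGG
  .code_env$usage_codons <- setdiff(.code_env$sense_codons, c("ATG", "TGG"))
  .code_env$nt3 <- substr(names(tab), 3, 3)
  names(.code_env$nt3) <- names(tab)
  .code_env$nt12 <- substr(names(tab), 1, 2)
  names(.code_env$nt12) <- names(tab)
  .code_env$at3 <- .code_env$nt3 %in% c("A", "T")
  names(.code_env$at3) <- names(tab)
  invisible(NULL)
}

.codon_table <- function() {
  if (is.null(.code_env$table)) .init_code_tables()
  .code_env
}

#' Split a nucleotide string into complete codons
#'
#' @param nucleotides A single DNA string (IUPAC alphabet, any case).
#' @param frame_offset 0-based offset of the first codon.
#' @return Character vector of codons; a trailing partial codon is dropped.
#' @export
split_codons <- function(nucleotides, frame_offset = 0) {
  stopifnot(length(nucleotides) == 1, frame_offset >= 0)
  s <- toupper(nucleotides)
  n <- nchar(s) - frame_offset
  n_codons <- n %/% 3
  if (n_codons < 1) {
    abort("no complete codon in sequence after frame offset")
  }
  starts <- frame_offset + 1 + 3 * (seq_len(n_codons) - 1)
  substring(s, starts, starts + 2)
}

# Vectorized codon -> amino acid; any codon with a non-ACGT symbol gives 'X'.
.translate_codons <- function(codons) {
  env <- .codon_table()
  aa <- unname(env$table[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Translate coding sequences
#'
#' Translates each coding sequence from its `frame_offset` onward using the
#' standard genetic code. Codons containing any non-ACGT symbol translate to
#' `"X"`; stop codons to `"*"`; a trailing partial codon is dropped.
#'
#' @param seqs A tibble of coding sequences with columns `id`, `species`,
#'   `nucleotides` and (optionally) `frame_offset` (default 0), as returned by
#'   [read_fasta()].
#' @param code A `genetic_code`; only the standard code is supported for the
#'   shipped analyses, but the table is injectable for testing.
#' @return A tibble of protein segments with columns `id`, `species`,
#'   `residues`, `source_id`, `start_codon`, `end_codon` (0-based half-open
#'   codon coordinates in the source).
#' @examples
#' seqs <- tibble::tibble(id = "s1", species = "A", nucleotides = "ATGGCTTAA")
#' translate_cds(seqs)
#' @export
translate_cds <- function(seqs, code = standard_genetic_code()) {
  seqs <- .as_sequence_tbl(seqs)
  tab <- code$table
  rows <- purrr::pmap(
    list(seqs$id, seqs$species, seqs$nucleotides, seqs$frame_offset),
    function(id, species, nt, off) {
      codons <- split_codons(nt, off)
      aa <- unname(tab[codons])
      aa[is.na(aa)] <- "X"
      tibble(
        id = id, species = species,
        residues = paste(aa, collapse = ""),
        source_id = id,
        start_codon = 0L, end_codon = length(aa)
      )
    }
  )
  bind_rows(rows)
}

#' GC fraction of nucleotide strings
#'
#' Fraction of G+C among the unambiguous (A/C/G/T) symbols of each string;
#' IUPAC ambiguity codes are excluded from numerator and denominator.
#'
#' @param x Character vector of nucleotide strings.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' gc_fraction(c("GGCC", "ACGT", "ANGT"))
#' @export
gc_fraction <- function(x) {
  stopifnot(is.character(x), all(nchar(x) > 0))
  up <- toupper(x)
  gc <- stringr::str_count(up, "[GC]")
  acgt <- stringr::str_count(up, "[ACGT]")
  if (any(acgt == 0)) {
    abort("sequence with zero A/C/G/T symbols has no defined GC fraction")
  }
  gc / acgt
}

.as_sequence_tbl <- function(seqs) {
  seqs <- as_tibble(seqs)
  if (!all(c("id", "nucleotides") %in% names(seqs))) {
    abort("sequence table needs columns `id` and `nucleotides`")
  }
  if (is.null(seqs[["species"]])) seqs$species <- NA_character_
  if (is.null(seqs[["frame_offset"]])) seqs$frame_offset <- 0L
  seqs$nucleotides <- toupper(seqs$nucleotides)
  if (anyDuplicated(seqs$id)) {
    dup <- unique(seqs$id[duplicated(seqs$id)])
    abort(paste0("duplicate sequence id(s): ", paste(dup, collapse = ", ")))
  }
  seqs
}
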