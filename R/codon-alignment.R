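# Codon alignments derived from protein alignments, with per-column
# classification. Columns are the unit every downstream statistic consumes:
#   indel         - gap in either species (excluded from all counts)
#   invalid       - a non-ACGT symbol inside an aligned codon (trips pair
#                   purging upstream; never silently skipped column-wise)
#   identical     - codons equal
#   synonymous    - codons differ, amino acid conserved
#   nonsynonymous - amino acid exchanged
# `nt12_conserved` flags non-indel columns whose first and second bases
# match, the conditioning used by the GC3/AT3 shift statistics.

#' Classify codon columns
#'
#' Takes a codon-column tibble (`pair_id`, `group_id`, `column`, `codon_a`,
#' `codon_b`, gaps as `"---"`) and attaches the per-column classification
#' plus amino acids and third-base annotations.
#'
#' @param cols Codon-column tibble.
#' @return The input with added columns `aa_a`, `aa_b`, `class`,
#'   `nt12_conserved`, `nt3_a`, `nt3_b`.
#' @export
classify_codon_columns <- function(cols) {
  cols <- as_tibble(cols)
  gap_a <- cols$codon_a == "---"
  gap_b <- cols$codon_b == "---"
  valid_a <- grepl("^[ACGT]{3}$", cols$codon_a)
  valid_b <- grepl("^[ACGT]{3}$", cols$codon_b)
  aa_a <- .translate_codons(cols$codon_a)
  aa_b <- .translate_codons(cols$codon_b)
  aa_a[gap_a] <- NA_character_
  aa_b[gap_b] <- NA_character_

  cls <- rep(NA_character_, nrow(cols))
  indel <- gap_a | gap_b
  invalid <- !indel & (!valid_a | !valid_b | aa_a == "*" | aa_b == "*")
  cls[indel] <- "indel"
  cls[invalid] <- "invalid"
  rest <- !indel & !invalid
  cls[rest & cols$codon_a == cols$codon_b] <- "identical"
  cls[rest & cols$codon_a != cols$codon_b & aa_a == aa_b] <- "synonymous"
  cls[rest & aa_a != aa_b] <- "nonsynonymous"

  cols |>
    mutate(
      aa_a = aa_a, aa_b = aa_b, class = cls,
      nt12_conserved = !indel &
        substr(cols$codon_a, 1, 2) == substr(cols$codon_b, 1, 2),
      nt3_a = ifelse(indel, NA, substr(cols$codon_a, 3, 3)),
      nt3_b = ifelse(indel, NA, substr(cols$codon_b, 3, 3))
    )
}

#' Back-translate protein alignments to codon alignments
#'
#' Maps each aligned residue column of every retained pair to the underlying
#' codon pair, inserting `"---"` for residue gaps, and verifies column-wise
#' that translating each codon reproduces the aligned residue (an error names
#' the first offending column otherwise).
#'
#' @param pairs Pair tibble as returned by [select_best_pairs()] /
#'   [filter_pairs()]: columns `pair_id`, `group_id`, `id_a`, `id_b`,
#'   `aligned_a`, `aligned_b`, `a_start`, `b_start`.
#' @param seqs Sequence tibble holding the coding sequences of both species
#'   (ids matching `id_a` / `id_b`).
#' @return Classified codon-column tibble (see [classify_codon_columns()]).
#' @export
backtranslate_pairs <- function(pairs, seqs) {
  seqs <- .as_sequence_tbl(seqs)
  codons_of <- setNames(
    purrr::map(seq_len(nrow(seqs)),
               function(i) split_codons(seqs$nucleotides[i],
                                        seqs$frame_offset[i])),
    seqs$id
  )
  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    res_a <- strsplit(p$aligned_a, "")[[1]]
    res_b <- strsplit(p$aligned_b, "")[[1]]
    ca <- codons_of[[p$id_a]]
    cb <- codons_of[[p$id_b]]
    if (is.null(ca) || is.null(cb)) {
      abort(paste0("missing coding sequence for pair ", p$pair_id))
    }
    ia <- p$a_start
    ib <- p$b_start
    cod_a <- character(length(res_a))
    cod_b <- character(length(res_b))
    for (k in seq_along(res_a)) {
      if (res_a[k] == "-") {
        cod_a[k] <- "---"
      } else {
        ia <- ia + 1L
        cod_a[k] <- ca[ia]
        if (.translate_codons(cod_a[k]) != res_a[k]) {
          abort(paste0("translation mismatch in pair ", p$pair_id,
                       " at column ", k, " (species A)"))
        }
      }
      if (res_b[k] == "-") {
        cod_b[k] <- "---"
      } else {
        ib <- ib + 1L
        cod_b[k] <- cb[ib]
        if (.translate_codons(cod_b[k]) != res_b[k]) {
          abort(paste0("translation mismatch in pair ", p$pair_id,
                       " at column ", k, " (species B)"))
        }
      }
    }
    tibble(pair_id = p$pair_id, group_id = p$group_id,
           column = seq_along(cod_a), codon_a = cod_a, codon_b = cod_b)
  })
  classify_codon_columns(bind_rows(rows))
}

#' Per-pair column summary counts
#'
#' @param cols Classified codon-column tibble.
#' @return Tibble with one row per pair: `aligned` (non-indel columns),
#'   `conserved`, `exchanged`, `synonymous` (amino-acid-conserved columns,
#'   identical codons included), `nt12_conserved_synonymous`, `indel`,
#'   `invalid`. `aligned == conserved + exchanged` always holds.
#' @export
classify_columns <- function(cols) {
  cols |>
    group_by(.data$pair_id) |>
    summarise(
      aligned = sum(.data$class %in%
                      c("identical", "synonymous", "nonsynonymous")),
      conserved = sum(.data$class %in% c("identical", "synonymous")),
      exchanged = sum(.data$class == "nonsynonymous"),
      synonymous = sum(.data$class %in% c("identical", "synonymous")),
      nt12_conserved_synonymous = sum(
        .data$class %in% c("identical", "synonymous") & .data$nt12_conserved),
      indel = sum(.data$class == "indel"),
      invalid = sum(.data$class == "invalid"),
      .groups = "drop"
    )
}
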