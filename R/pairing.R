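# Ortholog pairing: local alignment of translated segments within orthology
# groups, best-pair-per-group selection, and the identity / e-value /
# validity filter chain.

#' Align ortholog candidates within orthology groups
#'
#' For every orthology group with members in both species, aligns all
#' cross-species combinations of translated segments with [align_local()].
#'
#' @param seqs Sequence tibble holding both species' coding sequences.
#' @param orth_a,orth_b Orthology assignment tibbles (`seq_id`, `group_id`,
#'   `bitscore`, `evalue`) for species A and B.
#' @param scoring,gap_open,gap_ext Passed to [align_local()].
#' @return Alignment tibble: one row per candidate pair with `group_id`,
#'   `id_a`, `id_b`, `score`, `percent_identity`, `evalue` (`NA`: the
#'   internal aligner computes no database e-values), gapped alignment
#'   strings and residue ranges.
#' @export
align_ortholog_candidates <- function(seqs, orth_a, orth_b,
                                      scoring = NULL,
                                      gap_open = 11, gap_ext = 1) {
  prots <- translate_cds(seqs)
  res_of <- setNames(prots$residues, prots$id)
  groups <- dplyr::inner_join(
    orth_a |> select(id_a = "seq_id", "group_id") |> distinct(),
    orth_b |> select(id_b = "seq_id", "group_id") |> distinct(),
    by = "group_id", relationship = "many-to-many"
  )
  if (nrow(groups) == 0) {
    return(tibble(group_id = character(), id_a = character(),
                  id_b = character(), score = numeric(),
                  percent_identity = numeric(), evalue = numeric(),
                  length = integer(), aligned_a = character(),
                  aligned_b = character(), a_start = integer(),
                  a_end = integer(), b_start = integer(), b_end = integer()))
  }
  rows <- purrr::map(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    ra <- res_of[[g$id_a]]
    rb <- res_of[[g$id_b]]
    if (is.null(ra) || is.null(rb)) return(NULL)
    aln <- align_local(ra, rb, scoring = scoring,
                       gap_open = gap_open, gap_ext = gap_ext)
    bind_cols(tibble(group_id = g$group_id, id_a = g$id_a, id_b = g$id_b),
              aln |> mutate(evalue = NA_real_, .after = "percent_identity"))
  })
  bind_rows(rows)
}

#' Convert an external BLAST hit table to candidate pairs
#'
#' Joins a 12-column hit table (see [read_blast_hits()]) with the two
#' orthology tables, keeping hits whose query and subject share an orthology
#' group; the reported e-value and percent identity are used as-is.
#'
#' @param hits Hit tibble from [read_blast_hits()].
#' @param orth_a,orth_b Orthology tibbles for the query and subject species.
#' @return Candidate-pair tibble compatible with [select_best_pairs()].
#' @export
pairs_from_hits <- function(hits, orth_a, orth_b) {
  hits |>
    dplyr::inner_join(orth_a |> select(qseqid = "seq_id", "group_id") |>
                        distinct(),
                      by = "qseqid", relationship = "many-to-many") |>
    dplyr::inner_join(orth_b |> select(sseqid = "seq_id", "group_id") |>
                        distinct(),
                      by = c("sseqid", "group_id"),
                      relationship = "many-to-many") |>
    mutate(id_a = .data$qseqid, id_b = .data$sseqid,
           score = .data$bitscore, percent_identity = .data$pident,
           a_start = .data$qstart, a_end = .data$qend,
           b_start = .data$sstart, b_end = .data$send) |>
    select("group_id", "id_a", "id_b", "score", "percent_identity",
           "evalue", "a_start", "a_end", "b_start", "b_end")
}

#' Keep the single best pair per orthology group
#'
#' Per group, the alignment with the maximum score is retained; ties are
#' broken by higher percent identity, then lexicographically by (id_a,
#' id_b). A sequence may be best in several groups (retained, but flagged in
#' `multi_group`).
#'
#' @param alns Candidate alignment tibble.
#' @return Pair tibble with one row per group, a `pair_id`, and provenance
#'   counters in attribute `counters` (`groups_seen`, `candidates`).
#' @export
select_best_pairs <- function(alns) {
  if (nrow(alns) == 0) {
    out <- alns |> mutate(pair_id = character(0), multi_group = logical(0))
    attr(out, "counters") <- c(groups_seen = 0L, candidates = 0L, pairs = 0L)
    return(out)
  }
  best <- alns |>
    group_by(.data$group_id) |>
    arrange(dplyr::desc(.data$score), dplyr::desc(.data$percent_identity),
            .data$id_a, .data$id_b, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$group_id) |>
    mutate(pair_id = sprintf("pair_%s", .data$group_id),
           multi_group = .data$id_a %in% .data$id_a[duplicated(.data$id_a)] |
             .data$id_b %in% .data$id_b[duplicated(.data$id_b)])
  attr(best, "counters") <- c(
    groups_seen = dplyr::n_distinct(alns$group_id),
    candidates = nrow(alns), pairs = nrow(best)
  )
  best
}

#' Apply the identity and e-value filters
#'
#' Retains pairs with `percent_identity >= min_identity` and `evalue <=
#' max_evalue`. Pairs without an e-value (internally aligned, no database
#' context) are instead required to reach `min_score`; this substitution is
#' announced once per call.
#'
#' @param pairs Pair tibble from [select_best_pairs()].
#' @param min_identity Identity threshold in percent (0-100); the boundary
#'   is inclusive.
#' @param max_evalue E-value threshold (> 0).
#' @param min_score Score floor used when `evalue` is absent.
#' @return Filtered pair tibble; attribute `counters` records before/after.
#' @export
filter_pairs <- function(pairs, min_identity = 80, max_evalue = 1e-9,
                         min_score = 50) {
  if (min_identity < 0 || min_identity > 100) {
    abort("min_identity must be in [0, 100]")
  }
  if (max_evalue <= 0) abort("max_evalue must be positive")
  no_eval <- is.na(pairs$evalue)
  if (any(no_eval)) {
    rlang::inform(paste0(
      sum(no_eval), " pair(s) carry no e-value; ",
      "using the score floor (min_score = ", min_score, ") instead"
    ), class = "orthocodon_evalue_skip")
  }
  keep <- pairs$percent_identity >= min_identity &
    ifelse(no_eval, pairs$score >= min_score, pairs$evalue <= max_evalue)
  out <- pairs[keep, , drop = FALSE]
  attr(out, "counters") <- c(before = nrow(pairs), after = nrow(out))
  out
}

#' Purge pairs with stops or ambiguity codes in the aligned codon region
#'
#' Drops any pair whose classified codon columns contain an `invalid` column
#' (an in-frame stop codon or a non-ACGT nucleotide in either species).
#'
#' @param pairs Pair tibble.
#' @param cols Classified codon-column tibble covering these pairs.
#' @return Pair tibble without the invalid pairs; attribute `n_removed`
#'   reports the count.
#' @export
purge_invalid <- function(pairs, cols) {
  if (is.null(cols) || !all(c("pair_id", "class") %in% names(cols))) {
    abort("purge_invalid needs classified codon columns (see backtranslate_pairs)")
  }
  missing <- setdiff(pairs$pair_id, unique(cols$pair_id))
  if (length(missing)) {
    abort(paste0("missing codon alignment for pair(s): ",
                 paste(utils::head(missing, 3), collapse = ", ")))
  }
  bad <- unique(cols$pair_id[cols$class == "invalid"])
  out <- pairs[!pairs$pair_id %in% bad, , drop = FALSE]
  attr(out, "n_removed") <- nrow(pairs) - nrow(out)
  out
}
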