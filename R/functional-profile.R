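# Functional-category profiling: best term per sequence, pooling of
# orthology terms into COG/KOG single-letter categories, coverage against a
# reference gene set, and a library-specific term screen.
#
# These are presence/diversity profiles of normalized cDNA libraries, not
# expression levels: a term's count says how many distinct sequences hit it,
# nothing about transcript abundance.

#' Best term per sequence with an e-value cutoff
#'
#' Keeps, per sequence, the hit with the minimal e-value (ties broken by
#' higher bitscore if present, then lexicographic term id) and then drops
#' hits above `max_evalue`. Idempotent, and invariant to input row order.
#'
#' @param hits Term-hit tibble (`seq_id`, `term_id`, `evalue`, optionally
#'   `bitscore`).
#' @param max_evalue Inclusive e-value threshold.
#' @return Filtered one-row-per-sequence tibble.
#' @export
best_term_per_sequence <- function(hits, max_evalue = 1e-20) {
  if (!all(c("seq_id", "term_id", "evalue") %in% names(hits))) {
    abort("hits need columns seq_id, term_id, evalue")
  }
  if (any(is.na(hits$evalue)) || any(hits$evalue < 0)) {
    bad <- which(is.na(hits$evalue) | hits$evalue < 0)[1]
    abort(paste0("malformed e-value at row ", bad))
  }
  bs <- hits[["bitscore"]] %||% rep(0, nrow(hits))
  hits |>
    mutate(.bs = bs) |>
    group_by(.data$seq_id) |>
    arrange(.data$evalue, dplyr::desc(.data$.bs), .data$term_id,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-".bs") |>
    filter(.data$evalue <= max_evalue) |>
    arrange(.data$seq_id)
}

#' Pool term hits into COG/KOG categories
#'
#' Full counting: a term mapped to k categories contributes one increment to
#' each of the k (so the column sum can exceed the number of classified
#' sequences). Terms absent from the map are counted under `unknown`.
#'
#' @param hits Filtered term-hit tibble (one row per sequence).
#' @param term2cat Term map tibble (`term_id`, `categories` string of
#'   single-letter codes).
#' @param fractional If `TRUE`, a k-category term contributes 1/k per
#'   category instead.
#' @return List of class `category_profile`: `counts` (named numeric vector
#'   over the category alphabet), `unknown` (count of unmapped terms),
#'   `total_classified`.
#' @export
pool_categories <- function(hits, term2cat, fractional = FALSE) {
  cat_of <- setNames(term2cat$categories, term2cat$term_id)
  counts <- setNames(numeric(length(COG_CATEGORIES)), COG_CATEGORIES)
  unknown <- 0L
  for (term in hits$term_id) {
    cats <- unname(cat_of[term])
    if (is.na(cats) || !nzchar(cats)) {
      unknown <- unknown + 1L
      next
    }
    letters_k <- strsplit(cats, "")[[1]]
    letters_k <- letters_k[letters_k %in% COG_CATEGORIES]
    if (length(letters_k) == 0) {
      unknown <- unknown + 1L
      next
    }
    inc <- if (fractional) 1 / length(letters_k) else 1
    counts[letters_k] <- counts[letters_k] + inc
  }
  structure(list(counts = counts, unknown = unknown,
                 total_classified = nrow(hits) - unknown),
            class = "category_profile")
}

#' Per-category coverage against a reference profile
#'
#' `coverage = lib count / ref count`; may exceed 1 (a transcriptome can
#' show more distinct hits than a reference gene set, e.g. through splice
#' variants). Categories with zero reference count are reported as
#' undefined (`NA`), not 0. A count-weighted aggregate coverage is attached
#' as attribute `aggregate`.
#'
#' @param lib,ref `category_profile` objects.
#' @return Tibble with `category`, `lib_count`, `ref_count`, `coverage`.
#' @export
coverage_vs_reference <- function(lib, ref) {
  out <- tibble(
    category = COG_CATEGORIES,
    lib_count = unname(lib$counts[COG_CATEGORIES]),
    ref_count = unname(ref$counts[COG_CATEGORIES])
  ) |>
    mutate(coverage = ifelse(.data$ref_count > 0,
                             .data$lib_count / .data$ref_count, NA_real_))
  attr(out, "aggregate") <-
    sum(out$lib_count[out$ref_count > 0]) / sum(out$ref_count)
  out
}

#' Library-specific term screen
#'
#' For each term seen in either filtered library, builds the 2x2 table
#' `[[count_A, total_A - count_A], [count_B, total_B - count_B]]`, computes
#' the two-sided Fisher exact p-value, ranks by p then by absolute count
#' difference, and attaches Benjamini-Hochberg q-values.
#'
#' @param hits_a,hits_b Filtered term-hit tibbles (one row per sequence).
#' @return Tibble with `term_id`, `count_a`, `count_b`, `diff`
#'   (`count_a - count_b`), `p_value`, `q_value`, ordered by rank.
#' @export
library_specific_terms <- function(hits_a, hits_b) {
  ta <- table(hits_a$term_id)
  tb <- table(hits_b$term_id)
  terms <- union(names(ta), names(tb))
  total_a <- nrow(hits_a)
  total_b <- nrow(hits_b)
  ca <- as.integer(ifelse(terms %in% names(ta), ta[terms], 0L))
  cb <- as.integer(ifelse(terms %in% names(tb), tb[terms], 0L))
  p <- vapply(seq_along(terms), function(i) {
    fisher_exact_2x2(matrix(c(ca[i], total_a - ca[i],
                              cb[i], total_b - cb[i]), 2, byrow = TRUE))
  }, 0.0)
  tibble(term_id = terms, count_a = ca, count_b = cb,
         diff = ca - cb, p_value = p,
         q_value = p.adjust(p, method = "BH")) |>
    arrange(.data$p_value, dplyr::desc(abs(.data$diff)), .data$term_id)
}
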