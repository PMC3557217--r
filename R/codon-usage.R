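# Synonymous-codon analysis: GC3/AT3 paired shift accounting, per-codon
# usage shifts with Fisher's exact contingency test, within-group
# correspondence analysis (WCA) of synonymous codon usage, and GC summaries.
#
# Throughout, "synonymous positions" are the aligned non-indel columns whose
# amino acid is conserved (identical codons included); the GC3 ledger
# additionally conditions on conserved first and second bases.

#' GC3/AT3 shift ledger over synonymous codon pairs
#'
#' Only columns that are amino-acid conserved AND nt1/nt2-conserved
#' contribute. `gc3_to_at3` counts columns where species A carries A or T in
#' the third position while species B carries G or C; `at3_to_gc3` the
#' reverse. `net_gc3_loss_a = gc3_to_at3 - at3_to_gc3` is positive when
#' species A has shifted towards A/T at the wobble position.
#'
#' @param cols Classified codon-column tibble.
#' @return List of class `codon_ledger` with the counts above plus
#'   `n_aligned_residue_pairs` and `n_synonymous_nt12_conserved`.
#' @export
gc3_ledger <- function(cols) {
  aligned <- cols$class %in% c("identical", "synonymous", "nonsynonymous")
  syn12 <- cols$class %in% c("identical", "synonymous") & cols$nt12_conserved
  at3_a <- cols$nt3_a %in% c("A", "T")
  at3_b <- cols$nt3_b %in% c("A", "T")
  structure(list(
    n_aligned_residue_pairs = sum(aligned),
    n_synonymous_nt12_conserved = sum(syn12),
    gc3_to_at3 = sum(syn12 & at3_a & !at3_b),
    at3_to_gc3 = sum(syn12 & !at3_a & at3_b),
    net_gc3_loss_a = sum(syn12 & at3_a & !at3_b) -
      sum(syn12 & !at3_a & at3_b)
  ), class = "codon_ledger")
}

#' @export
print.codon_ledger <- function(x, ...) {
  cat("Synonymous GC3/AT3 shift ledger\n")
  cat(sprintf("  aligned residue pairs:            %d\n",
              x$n_aligned_residue_pairs))
  cat(sprintf("  synonymous, nt1/nt2 conserved:    %d\n",
              x$n_synonymous_nt12_conserved))
  cat(sprintf("  GC3 (B) -> AT3 (A):               %d\n", x$gc3_to_at3))
  cat(sprintf("  AT3 (B) -> GC3 (A):               %d\n", x$at3_to_gc3))
  cat(sprintf("  net GC3 loss in species A:        %d\n", x$net_gc3_loss_a))
  invisible(x)
}

#' Per-codon usage shift table
#'
#' Codon usage frequencies per species over the 59 informative sense codons
#' (61 minus ATG and TGG, whose families are invariant), computed from the
#' synonymous (amino-acid conserved) positions of the retained pairs.
#' `shift = freq_a - freq_b`; codons fall into a positive, negative or zero
#' panel.
#'
#' @param cols Classified codon-column tibble.
#' @return Tibble with columns `codon`, `aa`, `at3`, `count_a`, `count_b`,
#'   `freq_a`, `freq_b`, `shift`, `panel`.
#' @export
codon_shift_table <- function(cols) {
  env <- .codon_table()
  syn <- cols$class %in% c("identical", "synonymous")
  universe <- env$usage_codons
  ca <- table(factor(cols$codon_a[syn], levels = universe))
  cb <- table(factor(cols$codon_b[syn], levels = universe))
  if (sum(ca) == 0 || sum(cb) == 0) {
    abort("zero codon counts; no synonymous positions available")
  }
  tibble(
    codon = universe,
    aa = unname(env$table[universe]),
    at3 = unname(env$at3[universe]),
    count_a = as.integer(ca), count_b = as.integer(cb),
    freq_a = as.numeric(ca) / sum(ca),
    freq_b = as.numeric(cb) / sum(cb)
  ) |>
    mutate(
      shift = .data$freq_a - .data$freq_b,
      panel = dplyr::case_when(
        .data$shift > 0 ~ "positive",
        .data$shift < 0 ~ "negative",
        TRUE ~ "zero"
      )
    )
}

#' AT3-vs-GC3 shift contingency table
#'
#' 2x2 table of codon counts: rows AT3 / GC3 (third base identity), columns
#' positive / negative shift (higher usage in species A / in species B).
#' Zero-shift codons are recorded separately and excluded from the table.
#'
#' @param shift_tbl Result of [codon_shift_table()].
#' @return List of class `shift_contingency`: `table` (2x2 integer matrix),
#'   `n_zero_shift`, `p_value` (two-sided Fisher).
#' @export
shift_contingency <- function(shift_tbl) {
  nonzero <- shift_tbl |> filter(.data$panel != "zero")
  tab <- matrix(c(
    sum(nonzero$at3 & nonzero$panel == "positive"),
    sum(nonzero$at3 & nonzero$panel == "negative"),
    sum(!nonzero$at3 & nonzero$panel == "positive"),
    sum(!nonzero$at3 & nonzero$panel == "negative")
  ), nrow = 2, byrow = TRUE,
  dimnames = list(third_base = c("AT3", "GC3"),
                  shift = c("positive", "negative")))
  structure(list(
    table = tab,
    n_zero_shift = sum(shift_tbl$panel == "zero"),
    p_value = fisher_exact_2x2(tab)
  ), class = "shift_contingency")
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact conditional test: with margins fixed, the two-sided p-value sums the
#' hypergeometric probabilities of all tables whose point probability does
#' not exceed that of the observed table (the point-probability convention).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2))
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("need a 2x2 table")
  if (any(table < 0)) abort("negative cell count")
  fisher.test(table, alternative = "two.sided")$p.value
}

#' Per-segment codon usage counts for ordination
#'
#' Builds the rows-by-codons count matrix consumed by [wca()]: one row per
#' retained sequence segment and species, columns the 59 informative codons,
#' counts taken over the synonymous (amino-acid conserved) positions.
#'
#' @param cols Classified codon-column tibble.
#' @param pooled If `TRUE`, pool all segments into one row per species.
#' @return List with `counts` (numeric matrix) and `species` (character
#'   vector labelling the rows `"A"`/`"B"`).
#' @export
codon_usage_counts <- function(cols, pooled = FALSE) {
  env <- .codon_table()
  universe <- env$usage_codons
  syn <- cols |> filter(.data$class %in% c("identical", "synonymous"))
  key <- if (pooled) rep("all", nrow(syn)) else syn$pair_id
  ta <- table(key, factor(syn$codon_a, levels = universe))
  tb <- table(key, factor(syn$codon_b, levels = universe))
  counts <- rbind(unclass(ta), unclass(tb))
  species <- c(rep("A", nrow(ta)), rep("B", nrow(tb)))
  rownames(counts) <- paste0(species, "_", c(rownames(ta), rownames(tb)))
  keep <- rowSums(counts) > 0
  list(counts = counts[keep, , drop = FALSE], species = species[keep])
}

#' Within-group correspondence analysis of synonymous codon usage
#'
#' Correspondence analysis of codon counts after removing amino-acid
#' composition effects: each row's codon counts are first expressed relative
#' to that row's synonymous-family totals, the family-expected frequencies
#' (count-weighted column means) are centered out, and the standardized
#' residual matrix is decomposed by SVD. Rows are weighted by their total
#' codon counts. Because CA axes are sign-indeterminate, axis 1 is oriented
#' so that the mean coordinate of A/T-ending codons is positive.
#'
#' @param counts Rows-by-codons count matrix (e.g. from
#'   [codon_usage_counts()]); column names must be codons.
#' @param species Character vector labelling each row's species (for the
#'   covariance ellipses); optional.
#' @param n_axes Number of axes to keep.
#' @param ellipse_scale Ellipse radius in standard deviations (default 1.5).
#' @return Object of class `wca`: `eigenvalues`, `row_coords` (tibble with
#'   `row`, `species`, `axis1`, `axis2`, ...), `col_coords` (tibble with
#'   `codon`, `aa`, `at3`, axes), `ellipses` (per-species mean and 2x2
#'   covariance of the first two axes, with `scale`).
#' @export
wca <- function(counts, species = NULL, n_axes = 2L, ellipse_scale = 1.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("negative codon counts")
  if (is.null(colnames(counts))) abort("count matrix must have codon colnames")
  env <- .codon_table()
  fam_of <- unname(env$table[colnames(counts)])
  if (anyNA(fam_of)) abort("unknown codon in count matrix columns")
  keep_rows <- rowSums(counts) > 0
  counts <- counts[keep_rows, , drop = FALSE]
  if (!is.null(species)) species <- species[keep_rows]

  n <- nrow(counts)
  w <- rowSums(counts) / sum(counts) # row weights: total codon counts

  # within-family row profiles: counts relative to the row's family total
  fam_idx <- split(seq_len(ncol(counts)), fam_of)
  P <- matrix(0, n, ncol(counts), dimnames = dimnames(counts))
  for (idx in fam_idx) {
    tot <- rowSums(counts[, idx, drop = FALSE])
    nz <- tot > 0
    P[nz, idx] <- counts[nz, idx, drop = FALSE] / tot[nz]
  }
  # family-expected column frequencies (weighted over rows), centered out
  cexp <- as.numeric(crossprod(w, P))
  names(cexp) <- colnames(counts)
  usable <- cexp > 0
  X <- sweep(P[, usable, drop = FALSE], 2, cexp[usable], "-")
  Z <- sweep(X * sqrt(w), 2, sqrt(cexp[usable]), "/")

  sv <- svd(Z)
  pos <- sv$d > max(sv$d) * 1e-10
  if (!any(pos)) {
    abort("degenerate codon usage table: no within-family variation")
  }
  n_axes <- min(n_axes, sum(pos))
  d <- sv$d[seq_len(n_axes)]
  U <- sv$u[, seq_len(n_axes), drop = FALSE]
  V <- sv$v[, seq_len(n_axes), drop = FALSE]
  row_coords <- sweep(U, 1, sqrt(w), "/") %*% diag(d, n_axes)
  col_coords <- sweep(V, 1, sqrt(cexp[usable]), "/") %*% diag(d, n_axes)

  # orient axis 1: AT3 codons positive on average
  at3 <- unname(env$at3[colnames(counts)[usable]])
  if (mean(col_coords[at3, 1]) < 0) {
    row_coords[, 1] <- -row_coords[, 1]
    col_coords[, 1] <- -col_coords[, 1]
  }
  axis_names <- paste0("axis", seq_len(n_axes))
  sp_vec <- if (is.null(species)) rep(NA_character_, n) else species
  rc <- bind_cols(
    tibble(row = rownames(counts) %||% paste0("row", seq_len(n)),
           species = sp_vec),
    as_tibble(setNames(as.data.frame(row_coords), axis_names))
  )
  cc <- bind_cols(
    tibble(codon = colnames(counts)[usable], aa = fam_of[usable], at3 = at3),
    as_tibble(setNames(as.data.frame(col_coords), axis_names))
  )

  ellipses <- NULL
  if (!is.null(species) && n_axes >= 2) {
    ellipses <- rc |>
      group_by(.data$species) |>
      summarise(
        mean_axis1 = mean(.data$axis1), mean_axis2 = mean(.data$axis2),
        var_axis1 = stats::var(.data$axis1),
        var_axis2 = stats::var(.data$axis2),
        cov_12 = stats::cov(.data$axis1, .data$axis2),
        n = dplyr::n(), .groups = "drop"
      ) |>
      mutate(scale = ellipse_scale)
  }

  structure(list(
    eigenvalues = sv$d[pos]^2,
    row_coords = rc, col_coords = cc, ellipses = ellipses,
    row_weights = w, ellipse_scale = ellipse_scale
  ), class = "wca")
}

#' @export
print.wca <- function(x, ...) {
  cat("Within-group correspondence analysis of synonymous codon usage\n")
  cat(sprintf("  rows: %d, codons: %d, axes kept: %d\n",
              nrow(x$row_coords), nrow(x$col_coords),
              sum(grepl("^axis", names(x$row_coords)))))
  ev <- x$eigenvalues
  cat(sprintf("  inertia on axis 1: %.1f%%\n", 100 * ev[1] / sum(ev)))
  invisible(x)
}

#' Mean GC fraction per species over retained segments
#'
#' GC fraction of each segment's gap-free aligned coding region, averaged
#' (unweighted) over segments and reported in percent. A count-weighted
#' pooled value is reported alongside, since either convention is defensible
#' for a library-level summary.
#'
#' @param cols Classified codon-column tibble.
#' @return Tibble with columns `species`, `mean_gc_percent`,
#'   `pooled_gc_percent`, `n_segments`.
#' @export
mean_gc <- function(cols) {
  per_seg <- cols |>
    filter(.data$codon_a != "---", .data$codon_b != "---") |>
    group_by(.data$pair_id) |>
    summarise(
      seq_a = paste(.data$codon_a, collapse = ""),
      seq_b = paste(.data$codon_b, collapse = ""),
      .groups = "drop"
    )
  tibble(
    species = c("A", "B"),
    mean_gc_percent = c(mean(gc_fraction(per_seg$seq_a)) * 100,
                        mean(gc_fraction(per_seg$seq_b)) * 100),
    pooled_gc_percent = c(
      gc_fraction(paste(per_seg$seq_a, collapse = "")) * 100,
      gc_fraction(paste(per_seg$seq_b, collapse = "")) * 100
    ),
    n_segments = nrow(per_seg)
  )
}
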