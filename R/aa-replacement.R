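# Non-synonymous analysis: replacement counts between species, the
# antisymmetric imbalance matrix, net per-amino-acid usage change, and the
# ERK (E+R+K) paired Wilcoxon screen.

#' Count amino-acid replacements between species
#'
#' Over all classified, non-indel, valid columns: an exchanged column with
#' residue i in species A and j in species B increments `C[i, j]`; a
#' conserved column increments the diagonal `C[i, i]`.
#'
#' @param cols Classified codon-column tibble (see
#'   [classify_codon_columns()]); `X` residues must not occur in retained
#'   pairs (they are purged upstream) and trip an error here.
#' @return A 20x20 count matrix of class `replacement_matrix` with attribute
#'   `total_exchanged`.
#' @export
count_replacements <- function(cols) {
  if (!all(c("aa_a", "aa_b", "class") %in% names(cols))) {
    abort("columns must be classified first (classify_codon_columns)")
  }
  use <- cols$class %in% c("identical", "synonymous", "nonsynonymous")
  aa_a <- cols$aa_a[use]
  aa_b <- cols$aa_b[use]
  if (any(aa_a == "X" | aa_b == "X")) {
    abort("'X' residues in classified columns; purge invalid pairs first")
  }
  C <- table(factor(aa_a, levels = AA_LETTERS),
             factor(aa_b, levels = AA_LETTERS))
  C <- unclass(C)
  dimnames(C) <- list(species_a = AA_LETTERS, species_b = AA_LETTERS)
  structure(C, class = c("replacement_matrix", "matrix"),
            total_exchanged = sum(C) - sum(diag(C)))
}

#' Replacement imbalance matrix
#'
#' The antisymmetric transform `D[i, j] = C[i, j] - C[j, i]`. A positive
#' `D[i, j]` means amino acid i is preferred in species A at positions where
#' species B carries j.
#'
#' @param C A `replacement_matrix`.
#' @return 20x20 matrix of class `imbalance_matrix` (antisymmetric, zero
#'   diagonal).
#' @export
imbalance <- function(C) {
  D <- unclass(C) - t(unclass(C))
  structure(D, class = c("imbalance_matrix", "matrix"), total_exchanged = NULL)
}

#' Net amino-acid usage change for species A
#'
#' `net(i) = sum_j D[i, j]`; the nets always sum to zero (every exchange
#' gained by one amino acid is lost by another).
#'
#' @param D An `imbalance_matrix`.
#' @return Tibble with columns `aa` and `net`, in standard amino-acid order.
#' @export
net_usage <- function(D) {
  tibble(aa = rownames(D), net = unname(rowSums(unclass(D))))
}

#' Aggregate net usage over user-supplied amino-acid classes
#'
#' Utility for pooling the imbalance into classes (e.g. a polar/unpolar
#' partition). The partition is the caller's: the package takes no stance on
#' any particular polarity scheme.
#'
#' @param D An `imbalance_matrix`.
#' @param partition Named character vector mapping each amino acid to a
#'   class label.
#' @return Tibble with columns `class` and `net`.
#' @export
aa_class_net <- function(D, partition) {
  if (!all(AA_LETTERS %in% names(partition))) {
    abort("partition must cover all 20 amino acids")
  }
  net_usage(D) |>
    mutate(class = unname(partition[.data$aa])) |>
    group_by(.data$class) |>
    summarise(net = sum(.data$net), .groups = "drop")
}

#' Render the imbalance matrix in its lower-triangular layout
#'
#' Companion output for visual comparison with published replacement-
#' imbalance tables: rows C..Y against columns A..W, each unordered amino
#' acid pair appearing once.
#'
#' @param D An `imbalance_matrix`.
#' @return A data frame with row names C..Y and columns A..W; the upper
#'   triangle is `NA`.
#' @export
imbalance_lower_triangle <- function(D) {
  D <- unclass(D)
  out <- D[-1, -20, drop = FALSE]
  out[upper.tri(out, diag = FALSE)] <- NA
  as.data.frame(out)
}

#' Paired Wilcoxon test on E+R+K usage at exchanged positions
#'
#' Per pair, counts residues in {E, R, K} among the exchanged
#' (non-synonymous) positions in each species and tests the paired
#' differences `d = erk_a - erk_b` with a two-sided Wilcoxon signed-rank
#' test. Zero differences are dropped (Wilcoxon's original rule); the null
#' distribution is enumerated exactly when the effective n is at most 25 and
#' there are no tied |d|, otherwise the normal approximation with continuity
#' correction is used.
#'
#' @param cols Classified codon-column tibble.
#' @param fraction If `TRUE`, use the fraction of exchanged positions (count
#'   divided by exchanged positions of the pair) instead of the raw count.
#' @return List of class `erk_test`: `records` (per-pair tibble with
#'   `erk_a`, `erk_b`, `exchanged`, `d`), `statistic` (V), `p_value`,
#'   `n_effective`, `method`.
#' @export
erk_test <- function(cols, fraction = FALSE) {
  erk_set <- c("E", "R", "K")
  records <- cols |>
    filter(.data$class %in% c("identical", "synonymous", "nonsynonymous")) |>
    group_by(.data$pair_id) |>
    summarise(
      exchanged = sum(.data$class == "nonsynonymous"),
      erk_a = sum(.data$class == "nonsynonymous" & .data$aa_a %in% erk_set),
      erk_b = sum(.data$class == "nonsynonymous" & .data$aa_b %in% erk_set),
      .groups = "drop"
    )
  if (!any(records$exchanged > 0)) {
    abort("no pair with an exchanged position; ERK test undefined")
  }
  records$d <- if (fraction) {
    ifelse(records$exchanged > 0,
           (records$erk_a - records$erk_b) / pmax(records$exchanged, 1), 0)
  } else {
    records$erk_a - records$erk_b
  }
  dd <- records$d[records$d != 0]
  n_eff <- length(dd)
  if (n_eff == 0) {
    warn("all paired ERK differences are zero; p = 1")
    return(structure(list(records = records, statistic = NA_real_,
                          p_value = 1.0, n_effective = 0L,
                          method = "degenerate (all zero differences)"),
                     class = "erk_test"))
  }
  exact <- n_eff <= 25 && !any(duplicated(abs(dd)))
  wt <- suppressWarnings(
    wilcox.test(dd, alternative = "two.sided", mu = 0,
                exact = exact, correct = TRUE)
  )
  structure(list(
    records = records,
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n_effective = n_eff,
    method = if (exact) "exact signed-rank" else
      "normal approximation (continuity-corrected)"
  ), class = "erk_test")
}

#' @export
print.erk_test <- function(x, ...) {
  cat("Paired Wilcoxon signed-rank test on E+R+K counts at exchanged positions\n")
  cat(sprintf("  pairs: %d (effective n = %d, %s)\n",
              nrow(x$records), x$n_effective, x$method))
  cat(sprintf("  V = %s, two-sided p = %.4g\n",
              format(x$statistic), x$p_value))
  invisible(x)
}
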