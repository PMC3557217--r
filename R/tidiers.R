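# broom-style tidy()/glance() methods for the fitted/derived objects.

#' @describeIn count_replacements Tidy a replacement matrix into long form
#'   (`aa_a`, `aa_b`, `count`), off-diagonal cells only unless
#'   `diagonal = TRUE`.
#' @param x A `replacement_matrix`.
#' @param diagonal Keep the conserved (diagonal) cells.
#' @param ... Unused.
#' @export
tidy.replacement_matrix <- function(x, diagonal = FALSE, ...) {
  out <- as_tibble(as.data.frame.table(unclass(x), stringsAsFactors = FALSE))
  names(out) <- c("aa_a", "aa_b", "count")
  if (!diagonal) out <- out |> filter(.data$aa_a != .data$aa_b)
  out
}

#' @describeIn imbalance Tidy an imbalance matrix into long form (`aa_a`,
#'   `aa_b`, `imbalance`), one row per ordered pair, zero diagonal dropped.
#' @param x An `imbalance_matrix`.
#' @param ... Unused.
#' @export
tidy.imbalance_matrix <- function(x, ...) {
  out <- as_tibble(as.data.frame.table(unclass(x), stringsAsFactors = FALSE))
  names(out) <- c("aa_a", "aa_b", "imbalance")
  out |> filter(.data$aa_a != .data$aa_b)
}

#' @describeIn erk_test Per-pair ERK records with the paired difference.
#' @param x An `erk_test`.
#' @param ... Unused.
#' @export
tidy.erk_test <- function(x, ...) {
  x$records
}

#' @describeIn erk_test One-row test summary (`statistic`, `p_value`,
#'   `n_pairs`, `n_effective`, `method`).
#' @export
glance.erk_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         n_pairs = nrow(x$records), n_effective = x$n_effective,
         method = x$method)
}

#' @describeIn wca Row (segment) coordinates, one row per segment and
#'   species.
#' @param x A `wca` object.
#' @param which `"rows"` or `"columns"` (codon coordinates).
#' @param ... Unused.
#' @export
tidy.wca <- function(x, which = c("rows", "columns"), ...) {
  which <- match.arg(which)
  if (which == "rows") x$row_coords else x$col_coords
}

#' @describeIn wca One row per axis: eigenvalue and inertia fraction.
#' @export
glance.wca <- function(x, ...) {
  ev <- x$eigenvalues
  tibble(axis = seq_along(ev), eigenvalue = ev,
         inertia_fraction = ev / sum(ev))
}

#' @describeIn gc3_ledger One-row tibble of the ledger counts.
#' @param x A `codon_ledger`.
#' @param ... Unused.
#' @export
glance.codon_ledger <- function(x, ...) {
  as_tibble(x[c("n_aligned_residue_pairs", "n_synonymous_nt12_conserved",
                "gc3_to_at3", "at3_to_gc3", "net_gc3_loss_a")])
}
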