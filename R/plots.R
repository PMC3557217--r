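# ggplot2 views of the main result types.

#' Bar chart of net amino-acid usage change
#'
#' @param nets Tibble from [net_usage()].
#' @return A ggplot object.
#' @export
plot_net_usage <- function(nets) {
  nets$aa <- factor(nets$aa, levels = unique(nets$aa))
  ggplot2::ggplot(nets, ggplot2::aes(
    x = .data$aa, y = .data$net, fill = .data$net > 0
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "#b2182b")) +
    ggplot2::labs(x = "amino acid",
                  y = "net change in species A (non-synonymous positions)") +
    ggplot2::theme_minimal()
}

#' Two-panel codon usage shift plot
#'
#' Codons with higher usage in species A (positive panel) and in species B
#' (negative panel); A/T-ending codons are marked with `>` after the codon
#' label.
#'
#' @param shift_tbl Tibble from [codon_shift_table()].
#' @return A ggplot object.
#' @export
plot_codon_shifts <- function(shift_tbl) {
  df <- shift_tbl |>
    filter(.data$panel != "zero") |>
    mutate(
      label = paste0(.data$codon, ifelse(.data$at3, " >", "")),
      panel = ifelse(.data$panel == "positive",
                     "higher in species A", "higher in species B")
    ) |>
    arrange(dplyr::desc(abs(.data$shift)))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$label, abs(.data$shift)),
    y = abs(.data$shift), fill = .data$at3
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "|usage frequency shift|",
                  fill = "A/T third base") +
    ggplot2::theme_minimal()
}

#' Factorial map of a within-group correspondence analysis
#'
#' Codon coordinates on the first two axes with per-species covariance
#' ellipses of the segment coordinates, in the style of a synonymous
#' codon-usage factorial map.
#'
#' @param object A `wca` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wca <- function(object, ...) {
  cc <- object$col_coords
  p <- ggplot2::ggplot(cc, ggplot2::aes(.data$axis1, .data$axis2)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_text(ggplot2::aes(
      label = paste0(.data$codon, ifelse(.data$at3, ">", "")),
      colour = .data$at3
    ), size = 2.6, show.legend = FALSE) +
    ggplot2::labs(x = "axis 1", y = "axis 2") +
    ggplot2::theme_minimal()
  if (!is.null(object$ellipses)) {
    ell <- purrr::pmap(object$ellipses, function(species, mean_axis1,
                                                 mean_axis2, var_axis1,
                                                 var_axis2, cov_12, n,
                                                 scale) {
      S <- matrix(c(var_axis1, cov_12, cov_12, var_axis2), 2)
      eg <- eigen(S, symmetric = TRUE)
      t <- seq(0, 2 * pi, length.out = 120)
      pts <- t(eg$vectors %*% (scale * sqrt(pmax(eg$values, 0)) *
                                 rbind(cos(t), sin(t))))
      tibble(species = species, axis1 = pts[, 1] + mean_axis1,
             axis2 = pts[, 2] + mean_axis2)
    }) |> bind_rows()
    p <- p + ggplot2::geom_path(
      data = ell, ggplot2::aes(group = .data$species,
                               linetype = .data$species),
      colour = "grey30"
    )
  }
  p
}

#' Grouped bar chart of COG/KOG category counts
#'
#' @param profiles Named list of `category_profile` objects (e.g. one per
#'   library plus a reference).
#' @return A ggplot object.
#' @export
plot_category_profile <- function(profiles) {
  df <- purrr::imap(profiles, function(p, nm) {
    tibble(set = nm, category = names(p$counts),
           count = unname(p$counts))
  }) |> bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$count,
                                   fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "COG/KOG category", y = "term count", fill = NULL) +
    ggplot2::theme_minimal()
}
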