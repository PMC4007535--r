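# ggplot2 displays for the result tables

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Distribution of standardized cis/trans effect sizes
#'
#' Density of the standardized contrast estimates (estimate divided by the
#' RNA residual SD) for significant tests, split by contrast family and sex
#' -- the usual display for comparing the spread of cis versus trans
#' effects. Negative values mean the reference (st e) allele is the lower
#' expressed one.
#'
#' @param object An `ase_contrasts` tibble (after [adjust_fdr()]).
#' @param families Contrast families to show (default the F1 cis and trans
#'   families).
#' @param significant_only Restrict to significant tests (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ase_contrasts
#' @export
autoplot.ase_contrasts <- function(object,
                                   families = c("C1_CIS_F1", "C3_TRANS_F1"),
                                   significant_only = TRUE, ...) {
  d <- object |>
    dplyr::filter(.data$testable, .data$family %in% families)
  if (significant_only && "significant" %in% names(d)) {
    d <- dplyr::filter(d, .data$significant)
  }
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$effect_size, linetype = .data$family, colour = .data$sex
  )) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chromosome), scales = "free_y") +
    ggplot2::labs(
      x = "standardized effect (st e allele relative to allele 2)",
      y = "density", colour = "sex", linetype = "contrast"
    ) +
    ggplot2::theme_minimal()
}

#' Sex-bias call composition
#'
#' Bar chart of female-biased, male-biased and unbiased gene counts,
#' optionally split by chromosome when gene annotation is supplied.
#'
#' @param object An `ase_sexbias` tibble ([classify_sex_bias()]).
#' @param genes Optional gene annotation with `chromosome` to facet by.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ase_sexbias
#' @export
autoplot.ase_sexbias <- function(object, genes = NULL, ...) {
  d <- object
  if (!is.null(genes)) {
    d <- dplyr::inner_join(d, genes, by = "gene_id")
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$class, fill = .data$class)) +
    ggplot2::geom_bar(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal()
  if (!is.null(genes)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$chromosome))
  }
  p
}

#' Observed versus expected counts for a contingency table
#'
#' Dodged bar chart of observed and independence-expected counts from a long
#' contingency tibble (as produced inside [build_summary_tables()]).
#'
#' @param table_long A tibble with `row`, `col`, `observed`, `expected`.
#' @return A ggplot object.
#' @export
plot_observed_expected <- function(table_long) {
  assert_columns(table_long, c("row", "col", "observed", "expected"))
  d <- table_long |>
    tidyr::pivot_longer(c("observed", "expected"),
      names_to = "kind", values_to = "count")
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$col, y = .data$count, fill = .data$kind
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$row)) +
    ggplot2::labs(x = NULL, y = "genes", fill = NULL) +
    ggplot2::theme_minimal()
}
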