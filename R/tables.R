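#' Percentage of significant tests, display-rounded
#'
#' `100 * significant / tested`, rounded half-up to `digits` decimals (the
#' convention of the summary tables; 2 decimals for per-contrast tables,
#' 0 for text-style whole-percent summaries).
#'
#' @param n_significant,n_tested Counts.
#' @param digits Decimal places (default 2).
#' @export
#' @examples
#' percent_significant(501, 1633) # 30.68
#' percent_significant(162, 1633) # 9.92
percent_significant <- function(n_significant, n_tested, digits = 2) {
  round_half_up(100 * n_significant / n_tested, digits)
}

#' Build the three summary-table shapes and text-style percent summaries
#'
#' Assembles, from classified results, the three table shapes used to report
#' regulatory variation:
#'
#' * **per-contrast** (`table1`): per contrast family, sex and chromosome,
#'   the number of significant genes, the number tested, and the percentage
#'   (2 decimals, half-up);
#' * **sex bias by location** (`table2`): sex-bias class by chromosome with
#'   observed and independence-expected counts;
#' * **sex-limited variation by sex bias** (`table3_cis`, `table3_trans`):
#'   sex-bias class against the sex-limited class of cis (trans) variation
#'   for autosomal genes, with expected counts. Marginals are always derived
#'   from the cells.
#'
#' `text_summary` carries the whole-percent headline numbers: genes with any
#' regulatory variation, cis-only, trans-only, both, and (X-linked females)
#' cis-by-trans interactions.
#'
#' @param results FDR-adjusted contrast results ([adjust_fdr()]).
#' @param calls Gene regulatory calls ([classify_genes()]).
#' @param sexbias Sex-bias calls ([classify_sex_bias()]).
#' @param genes Gene annotation (`gene_id`, `chromosome`).
#' @return A list of class `ase_summary_tables` with tibbles `table1`,
#'   `table2`, `table3_cis`, `table3_trans`, `text_summary`.
#' @export
build_summary_tables <- function(results, calls, sexbias, genes) {
  # gene-level counts: a gene is tested (significant) in a family when any
  # of its per-line contrasts is testable (significant)
  table1 <- results |>
    dplyr::filter(.data$testable) |>
    dplyr::group_by(.data$family, .data$sex, .data$chromosome) |>
    dplyr::summarise(
      genes_significant = dplyr::n_distinct(.data$gene_id[.data$significant]),
      genes_tested = dplyr::n_distinct(.data$gene_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      percent_significant = percent_significant(
        .data$genes_significant, .data$genes_tested
      )
    )

  bias_levels <- c("MALE_BIASED", "FEMALE_BIASED", "UNBIASED")
  sb <- sexbias |>
    dplyr::inner_join(genes, by = "gene_id") |>
    dplyr::mutate(
      chromosome = factor(.data$chromosome, levels = c("X", "A")),
      class = factor(.data$class, levels = bias_levels)
    )
  obs2 <- table(sb$chromosome, sb$class)
  table2 <- contingency_long(unclass(obs2))

  limited_levels <- c("NONE", "MALE_ONLY", "FEMALE_ONLY", "BOTH_SEXES")
  auto <- calls |>
    dplyr::filter(.data$chromosome == "A") |>
    dplyr::inner_join(dplyr::select(sexbias, "gene_id", bias = "class"),
      by = "gene_id") |>
    dplyr::mutate(bias = factor(.data$bias, levels = bias_levels))

  t3 <- function(col) {
    d <- auto[!is.na(auto[[col]]), ]
    obs <- table(
      factor(d$bias, levels = bias_levels),
      factor(d[[col]], levels = limited_levels)
    )
    contingency_long(unclass(obs))
  }
  table3_cis <- t3("cis_sex_class")
  table3_trans <- t3("trans_sex_class")

  n_classified <- nrow(calls)
  n_x_c6 <- results |>
    dplyr::filter(.data$family == "C6_CIS_BY_TRANS", .data$testable) |>
    dplyr::distinct(.data$gene_id) |>
    nrow()
  n_c6_sig <- sum(calls$cistrans_any)
  text_summary <- tibble::tibble(
    quantity = c(
      "any_regulatory_variation", "cis_only", "trans_only", "both",
      "cistrans_interaction_x"
    ),
    n = c(
      sum(calls$category != "NONE"),
      sum(calls$category == "CIS_ONLY"),
      sum(calls$category == "TRANS_ONLY"),
      sum(calls$category == "BOTH"),
      n_c6_sig
    ),
    denominator = c(rep(n_classified, 4), n_x_c6)
  ) |>
    dplyr::mutate(percent = percent_significant(.data$n, .data$denominator, 0))

  structure(
    list(
      table1 = table1, table2 = table2, table3_cis = table3_cis,
      table3_trans = table3_trans, text_summary = text_summary
    ),
    class = "ase_summary_tables"
  )
}

# long observed/expected form of a counts matrix, marginals derived from cells
contingency_long <- function(obs) {
  expected <- expected_counts(obs)
  tidyr::expand_grid(
    row = rownames(obs) %||% as.character(seq_len(nrow(obs))),
    col = colnames(obs) %||% as.character(seq_len(ncol(obs)))
  ) |>
    dplyr::mutate(
      observed = as.vector(t(obs)),
      expected = as.vector(t(expected)),
      expected_rounded = round_half_up(.data$expected)
    )
}

#' Strata for the odds-ratio homogeneity test
#'
#' Builds, from a long sex-limited table (`table3_cis`/`table3_trans` of
#' [build_summary_tables()] or any tibble with `row`, `col`, `observed`), one
#' 2x2 stratum per sex-bias class, oriented
#' `[[both-sexes, female-only], [male-only, none]]`, for [breslow_day()].
#'
#' @param table3_long A long contingency tibble.
#' @return A named list of 2x2 matrices, one per sex-bias class.
#' @export
sex_limited_strata <- function(table3_long) {
  wide <- table3_long |>
    tidyr::pivot_wider(
      id_cols = "row", names_from = "col", values_from = "observed"
    )
  lapply(seq_len(nrow(wide)), function(i) {
    m <- matrix(
      c(
        wide$BOTH_SEXES[i], wide$FEMALE_ONLY[i],
        wide$MALE_ONLY[i], wide$NONE[i]
      ),
      nrow = 2, byrow = TRUE,
      dimnames = list(
        c("both", "male_only"), c("present", "absent")
      )
    )
    m
  }) |>
    setNames(wide$row)
}
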