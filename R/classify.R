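#' Classify genes by regulatory variation
#'
#' Collapses FDR-adjusted contrast results to one regulatory call per gene.
#' A gene shows cis variation if any C1/C2 contrast is significant in any
#' line (per sex where both sexes are testable), trans variation if any
#' C3/C4/C5 contrast is, and cis-by-trans interaction if a C6 contrast is
#' significant *in a line where the gene also shows a significant C1 or C2*
#' (an interaction without a detectable composite cis effect is not
#' interpretable as a cis-by-trans difference and is not counted). The
#' overall category is `CIS_ONLY`, `TRANS_ONLY`, `BOTH` or `NONE`.
#'
#' For autosomal genes (testable in both sexes) each effect type also gets a
#' sex-limited class: `FEMALE_ONLY`, `MALE_ONLY`, `BOTH_SEXES` or `NONE`,
#' from the per-sex any-line flags. X-linked genes are female-testable only,
#' so their sex-limited classes are `NA`.
#'
#' @param results FDR-adjusted contrast results ([adjust_fdr()] output).
#' @return A tibble with one row per gene: flags `cis_any`, `trans_any`,
#'   `cistrans_any`, per-sex flags, `category` and per-effect sex-limited
#'   classes.
#' @export
classify_genes <- function(results) {
  assert_columns(results, c(
    "gene_id", "chromosome", "family", "line", "sex", "significant", "testable"
  ))
  res <- dplyr::filter(results, .data$testable)

  cis_fams <- c("C1_CIS_F1", "C2_CIS_XHET")
  trans_fams <- c("C3_TRANS_F1", "C4_TRANS_XHET_STE", "C5_TRANS_XHET_SUB")

# cis-by-trans gate: C6 significant in a line whose C1 or C2 is significant
  ct_gate <- res |>
    dplyr::group_by(.data$gene_id, .data$line) |>
    dplyr::summarise(
      ct = any(.data$family == "C6_CIS_BY_TRANS" & .data$significant) &
        any(.data$family %in% cis_fams & .data$significant),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(cistrans_any = any(.data$ct), .groups = "drop")

  sex_limited <- function(f, m, testable_m) {
    dplyr::case_when(
      !testable_m ~ NA_character_,
      f & m ~ "BOTH_SEXES",
      f ~ "FEMALE_ONLY",
      m ~ "MALE_ONLY",
      TRUE ~ "NONE"
    )
  }

  calls <- res |>
    dplyr::group_by(.data$gene_id, .data$chromosome) |>
    dplyr::summarise(
      cis_f = any(.data$family %in% cis_fams & .data$sex == "F" & .data$significant),
      cis_m = any(.data$family %in% cis_fams & .data$sex == "M" & .data$significant),
      trans_f = any(.data$family %in% trans_fams & .data$sex == "F" & .data$significant),
      trans_m = any(.data$family %in% trans_fams & .data$sex == "M" & .data$significant),
      tested_m = any(.data$sex == "M"),
      .groups = "drop"
    ) |>
    dplyr::left_join(ct_gate, by = "gene_id") |>
    dplyr::mutate(
      cis_any = .data$cis_f | .data$cis_m,
      trans_any = .data$trans_f | .data$trans_m,
      cistrans_any = dplyr::coalesce(.data$cistrans_any, FALSE),
      category = dplyr::case_when(
        cis_any & trans_any ~ "BOTH",
        cis_any ~ "CIS_ONLY",
        trans_any ~ "TRANS_ONLY",
        TRUE ~ "NONE"
      ),
      cis_sex_class = sex_limited(
        .data$cis_f, .data$cis_m, .data$chromosome == "A" & .data$tested_m
      ),
      trans_sex_class = sex_limited(
        .data$trans_f, .data$trans_m, .data$chromosome == "A" & .data$tested_m
      )
    ) |>
    dplyr::select(
      "gene_id", "chromosome", "cis_any", "trans_any", "cistrans_any",
      "cis_f", "cis_m", "trans_f", "trans_m", "category",
      "cis_sex_class", "trans_sex_class"
    )

  calls
}
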