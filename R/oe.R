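#' Fit the overall-expression cell-means model
#'
#' Fits, per 3' expression probe set, a cell-means model on the normalized
#' expression values of the RNA hybridizations: every genotype-by-sex
#' combination is its own cell (males and females from the same cross are
#' separate genotypes), cell means are sample means, and a single pooled
#' residual variance is estimated with `df = sum(n_cell - 1)`.
#'
#' @param norm Normalized expression values ([summarize_expression()]).
#' @param samples Sample metadata; only RNA samples are used.
#' @return An object of class `ase_oefit`: tibbles `cells` (`probeset_id`,
#'   `cross_type`, `line`, `sex`, `mean`, `n`) and `variances`
#'   (`probeset_id`, `var`, `df`).
#' @export
fit_oe <- function(norm, samples) {
  assert_columns(norm, c("probeset_id", "sample_id", "value"))
  obs <- norm |>
    dplyr::inner_join(
      samples |>
        dplyr::filter(.data$nucleic_acid == "RNA") |>
        dplyr::select("sample_id", "line", "cross_type", "sex"),
      by = "sample_id"
    )

  cells <- obs |>
    dplyr::group_by(.data$probeset_id, .data$cross_type, .data$line, .data$sex) |>
    dplyr::summarise(
      mean = mean(.data$value), n = dplyr::n(),
      ss = sum((.data$value - mean(.data$value))^2),
      .groups = "drop"
    )

  variances <- cells |>
    dplyr::group_by(.data$probeset_id) |>
    dplyr::summarise(
      var = ifelse(sum(.data$n - 1) > 0, sum(.data$ss) / sum(.data$n - 1), NA_real_),
      df = sum(.data$n - 1),
      .groups = "drop"
    )

  structure(
    list(cells = dplyr::select(cells, -"ss"), variances = variances),
    class = "ase_oefit"
  )
}

#' @export
print.ase_oefit <- function(x, ...) {
  cat(sprintf(
    "<ase_oefit> %d probe sets, %d genotype-sex cells\n",
    nrow(x$variances), nrow(x$cells)
  ))
  invisible(x)
}

#' Overall-expression contrasts: substitution, dominance, X-variability, sex
#'
#' Builds and tests the overall-expression contrasts from a fitted
#' [fit_oe()] model:
#'
#' * **substitution** (per line): the homozygous X-substitution genotype
#'   against the reference homozygote -- females compare the substitution
#'   homozygote directly; males use the X-heterozygote males, which are
#'   genetically identical to substitution males. These contrasts read as
#'   cis tests for X-linked genes (the substituted chromosome) and trans
#'   tests for autosomal genes.
#' * **dominance** (per line, females): the X-heterozygote against the
#'   midparent mean of the substitution and reference homozygotes.
#' * **X-variability**: a joint F-test that all genotype means (averaged
#'   over the sexes present) are equal.
#' * **sex**: the average female-minus-male difference over the genotypes
#'   hybridized in both sexes.
#'
#' Single-df contrasts use `F = (estimate/se)^2` with
#' `se^2 = var * sum(c^2/n)`; the joint test is the standard general linear
#' hypothesis F on `G - 1` numerator df. All OE contrasts are adjusted in a
#' single pooled Benjamini-Hochberg family.
#'
#' @param fit An [fit_oe()] object.
#' @param fdr_level FDR threshold for the `significant` flag (default 0.20).
#' @return A tibble of contrast results with `family` in
#'   `OE_SUBSTITUTION`/`OE_DOMINANCE`/`OE_XVAR`/`OE_SEX`.
#' @export
oe_contrasts <- function(fit, fdr_level = 0.2) {
  stopifnot(inherits(fit, "ase_oefit"))
  cells <- fit$cells

  lines <- sort(setdiff(unique(cells$line), ref_line))

  cell_key <- function(cross, line, sex) paste(cross, line, sex, sep = "|")
  cells <- dplyr::mutate(
    cells,
    key = cell_key(.data$cross_type, .data$line, .data$sex)
  )

  # one-df contrasts as (key, coef) specs
  specs <- list()
  for (g in lines) {
    specs[[paste0("SUB_F_", g)]] <- tibble::tibble(
      family = "OE_SUBSTITUTION", line = g, sex = "F",
      key = c(cell_key("HOMO_SUB", g, "F"), cell_key("HOMO_STE", ref_line, "F")),
      coef = c(1, -1)
    )
    specs[[paste0("SUB_M_", g)]] <- tibble::tibble(
      family = "OE_SUBSTITUTION", line = g, sex = "M",
      key = c(cell_key("XHET", g, "M"), cell_key("HOMO_STE", ref_line, "M")),
      coef = c(1, -1)
    )
    specs[[paste0("DOM_F_", g)]] <- tibble::tibble(
      family = "OE_DOMINANCE", line = g, sex = "F",
      key = c(
        cell_key("XHET", g, "F"), cell_key("HOMO_SUB", g, "F"),
        cell_key("HOMO_STE", ref_line, "F")
      ),
      coef = c(1, -0.5, -0.5)
    )
  }
  # sex effect: mean F - M over genotypes hybridized in both sexes
  two_sex <- cells |>
    dplyr::distinct(.data$cross_type, .data$line, .data$sex) |>
    dplyr::count(.data$cross_type, .data$line) |>
    dplyr::filter(.data$n == 2)
  if (nrow(two_sex) > 0) {
    k <- nrow(two_sex)
    specs[["SEX"]] <- tibble::tibble(
      family = "OE_SEX", line = "all", sex = "FM",
      key = c(
        cell_key(two_sex$cross_type, two_sex$line, "F"),
        cell_key(two_sex$cross_type, two_sex$line, "M")
      ),
      coef = c(rep(1 / k, k), rep(-1 / k, k))
    )
  }
  spec_tbl <- dplyr::bind_rows(specs)

  joined <- dplyr::inner_join(
    spec_tbl,
    dplyr::select(cells, "probeset_id", "key", "mean", "n"),
    by = "key", relationship = "many-to-many"
  )
  n_cells_needed <- spec_tbl |> dplyr::count(.data$family, .data$line, .data$sex)

  one_df <- joined |>
    dplyr::group_by(.data$probeset_id, .data$family, .data$line, .data$sex) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      estimate = sum(.data$coef * .data$mean),
      a = sum(.data$coef^2 / .data$n),
      .groups = "drop"
    ) |>
    dplyr::left_join(n_cells_needed, by = c("family", "line", "sex")) |>
    dplyr::left_join(fit$variances, by = "probeset_id") |>
    dplyr::mutate(
      testable = .data$n_cells == .data$n & .data$df > 0 & !is.na(.data$var),
      se2 = .data$var * .data$a,
      F = dplyr::case_when(
        !.data$testable ~ NA_real_,
        .data$se2 > 0 ~ .data$estimate^2 / .data$se2,
        .data$estimate == 0 ~ 0,
        TRUE ~ Inf
      ),
      df_num = 1L,
      df_den = ifelse(.data$testable, .data$df, NA_real_),
      p = dplyr::case_when(
        !.data$testable ~ NA_real_,
        .data$se2 > 0 ~ pf(.data$estimate^2 / .data$se2, 1, .data$df, lower.tail = FALSE),
        .data$estimate == 0 ~ 1,
        TRUE ~ 0
      ),
      effect_size = ifelse(
        .data$testable & .data$var > 0, .data$estimate / sqrt(.data$var), NA_real_
      )
    ) |>
    dplyr::mutate(estimate = ifelse(.data$testable, .data$estimate, NA_real_)) |>
    dplyr::select(
      "probeset_id", "family", "line", "sex", "estimate", "F", "df_num",
      "df_den", "p", "effect_size", "testable"
    )

  xvar <- oe_xvar_test(fit)

  out <- dplyr::bind_rows(one_df, xvar) |>
    dplyr::arrange(.data$probeset_id, .data$family, .data$line, .data$sex)
  out <- adjust_fdr(out, group = character(0), fdr_level = fdr_level)
  out
}

# joint F-test that all genotype means (sex-averaged) are equal
oe_xvar_test <- function(fit) {
  geno_means <- fit$cells |>
    dplyr::group_by(.data$probeset_id, .data$cross_type, .data$line) |>
    dplyr::summarise(
      gmean = mean(.data$mean),
      gvar_unit = sum((1 / dplyr::n())^2 / .data$n),
      .groups = "drop"
    )

  geno_means |>
    dplyr::group_by(.data$probeset_id) |>
    dplyr::summarise(
      stat = {
        g <- dplyr::n()
        if (g < 2) {
          NA_real_
        } else {
          # GLH F for H0: all genotype means equal, against the reference
          # genotype; V = var * diag(gvar_unit) on the genotype means
          d <- .data$gmean[-1] - .data$gmean[1]
          a <- .data$gvar_unit
          v <- diag(a[-1], nrow = g - 1) + a[1]
          drop(t(d) %*% solve(v, d)) / (g - 1)
        }
      },
      df_num = dplyr::n() - 1L,
      .groups = "drop"
    ) |>
    dplyr::left_join(fit$variances, by = "probeset_id") |>
    dplyr::mutate(
      family = "OE_XVAR", line = "all", sex = "FM",
      testable = .data$df > 0 & !is.na(.data$var) & !is.na(.data$stat),
      F = ifelse(.data$testable & .data$var > 0, .data$stat / .data$var,
        ifelse(.data$testable & .data$stat == 0, 0, NA_real_)
      ),
      F = ifelse(.data$testable & .data$var == 0 & .data$stat > 0, Inf, .data$F),
      df_den = ifelse(.data$testable, .data$df, NA_real_),
      p = ifelse(
        .data$testable,
        pf(.data$F, .data$df_num, .data$df, lower.tail = FALSE), NA_real_
      ),
      estimate = NA_real_, effect_size = NA_real_
    ) |>
    dplyr::select(
      "probeset_id", "family", "line", "sex", "estimate", "F", "df_num",
      "df_den", "p", "effect_size", "testable"
    )
}

#' Classify genes as female-, male- or un-biased
#'
#' Collapses FDR-adjusted overall-expression sex contrasts to a per-gene
#' sex-bias call. With multiple probe sets per gene the call comes from the
#' probe set with the smallest sex-effect q (ties broken by larger absolute
#' estimate). A gene is `FEMALE_BIASED` when the sex contrast (female minus
#' male) is significantly positive, `MALE_BIASED` when significantly
#' negative, `UNBIASED` otherwise.
#'
#' @param oe_results [oe_contrasts()] output (must contain `OE_SEX` rows
#'   with `q`).
#' @param probe_gene_map Tibble mapping `probeset_id` to `gene_id`.
#' @param fdr_level Significance threshold on q (default 0.20).
#' @return A tibble of class `ase_sexbias`: `gene_id`, `class`, `estimate`,
#'   `q`.
#' @export
classify_sex_bias <- function(oe_results, probe_gene_map, fdr_level = 0.2) {
  assert_columns(oe_results, c("probeset_id", "family", "estimate", "q"))
  assert_columns(probe_gene_map, c("probeset_id", "gene_id"))

  out <- oe_results |>
    dplyr::filter(.data$family == "OE_SEX", .data$testable) |>
    dplyr::inner_join(
      dplyr::distinct(probe_gene_map, .data$probeset_id, .data$gene_id),
      by = "probeset_id"
    ) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(.data$q, dplyr::desc(abs(.data$estimate)), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      class = dplyr::case_when(
        .data$q <= fdr_level & .data$estimate > 0 ~ "FEMALE_BIASED",
        .data$q <= fdr_level & .data$estimate < 0 ~ "MALE_BIASED",
        TRUE ~ "UNBIASED"
      )
    ) |>
    dplyr::select("gene_id", "class", "estimate", "q")

  class(out) <- c("ase_sexbias", class(out))
  out
}
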