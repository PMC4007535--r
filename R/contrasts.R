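contrast_families <- c(
  "C1_CIS_F1", "C2_CIS_XHET", "C3_TRANS_F1", "C4_TRANS_XHET_STE",
  "C5_TRANS_XHET_SUB", "C6_CIS_BY_TRANS"
)

#' Build the six DNA-controlled contrast families
#'
#' Emits, per substitution line and applicable sex, the cell-coefficient
#' vectors of the six allele-specific tests. Writing `mu(allele, genotype,
#' acid[, sex])` for a cell mean, with `S` the st e allele, `A2` the
#' substituted line's allele, `R`/`D` RNA and DNA (DNA cells carry no sex
#' index):
#'
#' * **C1, cis in F1**: `[mu(S,F1,R,s) - mu(A2,F1,R,s)] - [mu(S,F1,D) -
#'   mu(A2,F1,D)]` -- allelic imbalance in the F1 relative to the DNA dosage
#'   control. X-linked genes: females only; autosomal genes: each sex.
#' * **C2, cis in X-het**: as C1 with X-heterozygote RNA; the F1 DNA is the
#'   dosage control (X-het DNA was not hybridized; its expected allele ratio
#'   is identical). X-linked females only.
#' * **C3, trans in F1**: `[mu(S,F1,R,s) - mu(S,STE,R,s)] - [mu(S,F1,D) -
#'   mu(S,STE,D)]` -- the st e allele followed from the reference background
#'   into the F1 background.
#' * **C4, trans in X-het (st e allele)** and **C5, trans in X-het
#'   (substituted allele)**: the corresponding single-allele comparisons into
#'   the X-heterozygote background. X-linked females only.
#' * **C6, cis-by-trans**: the change in allelic imbalance between F1 and
#'   X-het females; DNA terms cancel. X-linked females only.
#'
#' Every coefficient vector sums to zero, and the st e cell carries the
#' positive coefficient, so genes whose st e allele is expressed lower yield
#' negative estimates.
#'
#' @param lines Character vector of substitution line identifiers.
#' @param families Contrast families to emit (default all six).
#' @return A tibble with one row per contrast cell: identifiers `family`,
#'   `line`, `sex`, `chromosome` (scope), and cell coordinates
#'   `allele_class`, `cross_type`, `cell_line`, `nucleic_acid`, `cell_sex`,
#'   `coef`.
#' @export
build_contrasts <- function(lines, families = contrast_families) {
  bad <- setdiff(families, contrast_families)
  if (length(bad) > 0) {
    abort(sprintf("unknown contrast family: %s", paste(bad, collapse = ", ")),
      class = "asecis_scope_error")
  }

  cell <- function(allele, cross, line, acid, sex, coef) {
    tibble::tibble(
      allele_class = allele, cross_type = cross, cell_line = line,
      nucleic_acid = acid, cell_sex = sex, coef = coef
    )
  }

  one_family <- function(family, g, chromosome, sex) {
    # RNA cell sex index exists only for autosomal genes
    rs <- if (chromosome == "A") sex else "ALL"
    cells <- switch(family,
      C1_CIS_F1 = dplyr::bind_rows(
        cell("STE", "F1", g, "RNA", rs, 1),
        cell("ALLELE2", "F1", g, "RNA", rs, -1),
        cell("STE", "F1", g, "DNA", "ALL", -1),
        cell("ALLELE2", "F1", g, "DNA", "ALL", 1)
      ),
      C2_CIS_XHET = dplyr::bind_rows(
        cell("STE", "XHET", g, "RNA", rs, 1),
        cell("ALLELE2", "XHET", g, "RNA", rs, -1),
        cell("STE", "F1", g, "DNA", "ALL", -1),
        cell("ALLELE2", "F1", g, "DNA", "ALL", 1)
      ),
      C3_TRANS_F1 = dplyr::bind_rows(
        cell("STE", "F1", g, "RNA", rs, 1),
        cell("STE", "HOMO_STE", ref_line, "RNA", rs, -1),
        cell("STE", "F1", g, "DNA", "ALL", -1),
        cell("STE", "HOMO_STE", ref_line, "DNA", "ALL", 1)
      ),
      C4_TRANS_XHET_STE = dplyr::bind_rows(
        cell("STE", "XHET", g, "RNA", rs, 1),
        cell("STE", "HOMO_STE", ref_line, "RNA", rs, -1),
        cell("STE", "F1", g, "DNA", "ALL", -1),
        cell("STE", "HOMO_STE", ref_line, "DNA", "ALL", 1)
      ),
      C5_TRANS_XHET_SUB = dplyr::bind_rows(
        cell("ALLELE2", "XHET", g, "RNA", rs, 1),
        cell("ALLELE2", "HOMO_SUB", g, "RNA", rs, -1),
        cell("ALLELE2", "F1", g, "DNA", "ALL", -1),
        cell("ALLELE2", "HOMO_SUB", g, "DNA", "ALL", 1)
      ),
      C6_CIS_BY_TRANS = dplyr::bind_rows(
        cell("STE", "F1", g, "RNA", rs, 1),
        cell("ALLELE2", "F1", g, "RNA", rs, -1),
        cell("STE", "XHET", g, "RNA", rs, -1),
        cell("ALLELE2", "XHET", g, "RNA", rs, 1)
      )
    )
    dplyr::mutate(cells,
      family = family, line = g, sex = sex, chromosome = chromosome,
      .before = 1
    )
  }

  scope <- dplyr::bind_rows(
    tidyr::expand_grid(
      family = intersect(families, contrast_families), chromosome = "X",
      sex = "F"
    ),
    tidyr::expand_grid(
      family = intersect(families, c("C1_CIS_F1", "C3_TRANS_F1")),
      chromosome = "A", sex = c("F", "M")
    )
  )

  purrr::pmap(
    tidyr::expand_grid(scope, g = lines),
    function(family, chromosome, sex, g) one_family(family, g, chromosome, sex)
  ) |>
    dplyr::bind_rows()
}

#' Test cell-means contrasts with heteroscedastic F-tests
#'
#' Evaluates every contrast of `specs` against every gene in `fit` whose
#' chromosome matches the contrast's scope. For a coefficient vector `c` over
#' cells with means `mu` and per-cell counts `n`:
#' `estimate = sum(c * mu)`;
#' `se^2 = var_RNA * sum_RNA(c^2 / n) + var_DNA * sum_DNA(c^2 / n)`;
#' `F = (estimate / se)^2` on 1 numerator df, with denominator df by
#' Satterthwaite combination of the RNA and DNA variance groups. The
#' standardized effect size is `estimate / sqrt(var_RNA)` (RNA noise is the
#' sampling scale of the biological signal).
#'
#' A contrast whose required cells are not all present for a gene (for
#' example a line with no informative probe set) is returned untestable
#' (`testable = FALSE`, `NA` statistics) rather than erroring. A zero
#' standard error yields `p = 1` when the estimate is zero and `p = 0` (with
#' a degenerate-variance warning) otherwise.
#'
#' @param fit An [fit_cell_means()] object.
#' @param specs A contrast specification from [build_contrasts()].
#' @return A tibble of class `ase_contrasts`: one row per gene by family by
#'   line by sex with `estimate`, `se`, `F`, `df_den`, `p`, `effect_size`
#'   and `testable`.
#' @export
test_contrasts <- function(fit, specs) {
  stopifnot(inherits(fit, "ase_cellmeans"))

  joined <- dplyr::inner_join(
    fit$cells, specs,
    by = c(
      "chromosome", "allele_class", "cross_type",
      "line" = "cell_line", "nucleic_acid", "sex" = "cell_sex"
    ),
    relationship = "many-to-many"
  )
  # after the join, line.x/sex.x are the cell's coordinates and line.y/sex.y
  # the contrast's own identifiers
  n_needed_tbl <- specs |>
    dplyr::count(.data$chromosome, .data$family, .data$line, .data$sex,
      name = "n_needed")
  stats_tbl <- joined |>
    dplyr::group_by(
      .data$gene_id, .data$chromosome, .data$family,
      line = .data$line.y, sex = .data$sex.y
    ) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      estimate = sum(.data$coef * .data$mean),
      a_rna = sum((.data$coef^2 / .data$n)[.data$nucleic_acid == "RNA"]),
      a_dna = sum((.data$coef^2 / .data$n)[.data$nucleic_acid == "DNA"]),
      .groups = "drop"
    )

  res <- stats_tbl |>
    dplyr::left_join(n_needed_tbl,
      by = c("chromosome", "family", "line", "sex")) |>
    dplyr::left_join(fit$variances, by = "gene_id") |>
    dplyr::mutate(
      testable = .data$n_cells == .data$n_needed &
        !(.data$a_dna > 0 & (.data$df_dna == 0 | is.na(.data$var_dna))) &
        !(.data$a_rna > 0 & (.data$df_rna == 0 | is.na(.data$var_rna)))
    )

  v_r <- ifelse(res$a_rna > 0, res$var_rna * res$a_rna, 0)
  v_d <- ifelse(res$a_dna > 0, res$var_dna * res$a_dna, 0)
  se2 <- v_r + v_d
  df_den <- satterthwaite_df(v_r, res$df_rna, v_d, res$df_dna)

  f_stat <- ifelse(se2 > 0, res$estimate^2 / se2, ifelse(res$estimate == 0, 0, Inf))
  p <- ifelse(
    se2 > 0, pf(f_stat, 1, df_den, lower.tail = FALSE),
    ifelse(res$estimate == 0, 1, 0)
  )
  if (any(res$testable & se2 <= 0 & res$estimate != 0, na.rm = TRUE)) {
    warn("degenerate zero variance with nonzero estimate; p set to 0")
  }

  out <- res |>
    dplyr::mutate(
      estimate = ifelse(.data$testable, .data$estimate, NA_real_),
      se = ifelse(.data$testable, sqrt(se2), NA_real_),
      F = ifelse(.data$testable, f_stat, NA_real_),
      df_num = 1L,
      df_den = ifelse(.data$testable, df_den, NA_real_),
      p = ifelse(.data$testable, p, NA_real_),
      effect_size = ifelse(
        .data$testable & !is.na(.data$var_rna) & .data$var_rna > 0,
        .data$estimate / sqrt(.data$var_rna), NA_real_
      )
    ) |>
    dplyr::select(
      "gene_id", "chromosome", "family", "line", "sex", "estimate", "se",
      "F", "df_num", "df_den", "p", "effect_size", "testable"
    ) |>
    dplyr::arrange(.data$family, .data$gene_id, .data$line, .data$sex)

  class(out) <- c("ase_contrasts", class(out))
  out
}

# Satterthwaite effective df for a linear combination of two independent
# variance-group components; groups with zero contribution are dropped.
satterthwaite_df <- function(v1, df1, v2, df2) {
  num <- (v1 + v2)^2
  den <- ifelse(v1 > 0, v1^2 / df1, 0) + ifelse(v2 > 0, v2^2 / df2, 0)
  ifelse(den > 0, num / den, NA_real_)
}

#' Benjamini-Hochberg adjustment within contrast families
#'
#' Adjusts raw contrast p-values for multiple testing by the
#' Benjamini-Hochberg step-up procedure, applied *within* groups (by default
#' the contrast family, pooled across lines, sexes and chromosomes, matching
#' how the tests were grouped in the source design). Adds `q` and a
#' `significant` flag at the chosen false discovery rate.
#'
#' @param results A contrast result tibble with a `p` column.
#' @param group Column names defining the adjustment families.
#' @param fdr_level FDR threshold for the `significant` flag (default 0.20,
#'   chosen to balance type I and II error in this design).
#' @return `results` with `q` and `significant` columns; untestable rows
#'   keep `NA`.
#' @export
adjust_fdr <- function(results, group = "family", fdr_level = 0.2) {
  assert_columns(results, c("p", group))
  out <- results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::mutate(q = p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = !is.na(.data$q) & .data$q <= fdr_level)
  class(out) <- unique(c(class(results)[1], class(out)))
  out
}
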