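#' Fit the per-gene heteroscedastic cell-means model
#'
#' Fits, for every gene at once, the cell-means model underlying the
#' allele-specific tests: the normalized allele signal `Y_ijklm` is modelled
#' as a free mean per cell -- allele (st e vs allele 2) by genotype (line by
#' cross type) by nucleic acid (RNA vs DNA) by sex -- plus residual noise,
#' with *separate* residual variances for DNA and RNA hybridizations (DNA
#' controls are far less variable than RNA). Cell means are the sample means
#' of their cells; each nucleic acid's variance is the within-cell sum of
#' squares pooled over that acid's cells, with `df = sum(n_cell - 1)`.
#'
#' Scoping follows the biology of the design:
#'
#' * X-linked genes use female RNA only (males are hemizygous, so no
#'   within-male allelic contrast exists) and carry no sex index; genotypes
#'   F1, X-heterozygote, substitution homozygote and reference homozygote all
#'   enter.
#' * autosomal genes use both sexes of the F1 and reference genotypes (the
#'   X-substitution genotypes are autosomally reference-homozygous and carry
#'   no allelic signal); RNA cells are sex-indexed.
#' * DNA cells never carry a sex index (all DNA came from females) and are
#'   shared by both sexes' contrasts.
#'
#' When a gene has several informative probe sets they are considered
#' jointly: values are first centered and then pooled as replicate
#' observations within cells. The default centering subtracts each probe
#' set *and allele class's* mean across the retained samples
#' (`center = "class"`). Allele classes of a probe set carry fixed affinity
#' offsets (different probes interrogate each allele); these offsets cancel
#' exactly in every DNA-controlled contrast, but if left in the residual --
#' as grand-mean centering (`center = "probeset"`) leaves them -- they
#' inflate the pooled variance and deflate every F statistic. `center =
#' "none"` fits raw values (useful for hand-checking cell means). A probe
#' set only contributes to a line's genotype cells when its allele
#' assignment for that line is not dropped.
#'
#' @param allele_signal Normalized allele signals ([normalize_snp_probesets()]
#'   output with `STE`/`ALLELE2` classes; `MM` rows are ignored).
#' @param samples Sample metadata.
#' @param probes Probe annotation (maps probe sets to genes).
#' @param genes Gene annotation (`gene_id`, `chromosome`).
#' @param assignments Harmonized allele assignments ([assign_alleles()] then
#'   [harmonize_assignments()]); used to gate line-specific cells.
#' @param center Probe-set centering: `"class"` (default), `"probeset"` or
#'   `"none"` (see Details).
#' @return An object of class `ase_cellmeans`: a list with tibbles `cells`
#'   (`gene_id`, `chromosome`, `allele_class`, `cross_type`, `line`,
#'   `nucleic_acid`, `sex`, `mean`, `n`) and `variances` (`gene_id`,
#'   `var_rna`, `df_rna`, `var_dna`, `df_dna`).
#' @export
fit_cell_means <- function(allele_signal, samples, probes, genes,
                           assignments = NULL,
                           center = c("class", "probeset", "none")) {
  center <- match.arg(center)
  assert_columns(allele_signal, c("probeset_id", "sample_id", "allele_class", "value"))
  probe_map <- probes |>
    dplyr::filter(.data$module == "SNP") |>
    dplyr::distinct(.data$probeset_id, .data$gene_id)

  obs <- allele_signal |>
    dplyr::filter(.data$allele_class %in% c("STE", "ALLELE2")) |>
    dplyr::inner_join(probe_map, by = "probeset_id") |>
    dplyr::inner_join(
      dplyr::select(
        samples, "sample_id", "line", "cross_type", "sex", "nucleic_acid"
      ),
      by = "sample_id"
    ) |>
    dplyr::inner_join(genes, by = "gene_id")

  if (!is.null(assignments)) {
    ok <- assignments |>
      dplyr::filter(.data$status != "DROPPED") |>
      dplyr::distinct(.data$probeset_id, .data$line)
    line_specific <- obs$cross_type %in% c("F1", "XHET", "HOMO_SUB")
    keep_ls <- paste(obs$probeset_id, obs$line) %in% paste(ok$probeset_id, ok$line)
    keep_ref <- obs$probeset_id %in% ok$probeset_id
    obs <- obs[ifelse(line_specific, keep_ls, keep_ref), ]
  }

  # design scope per chromosome (see Details)
  obs <- obs |>
    dplyr::filter(
      (.data$chromosome == "A" &
        .data$cross_type %in% c("F1", "HOMO_STE")) |
        (.data$chromosome == "X" &
          (.data$nucleic_acid == "DNA" |
            .data$sex == "F"))
    )

  # Probe-set centering before pooling probe sets as replicates. The
  # centering constant is computed over the samples retained by *every*
  # probe set of the gene: probe sets informative for different line subsets
  # see different genotype mixtures, and means over unequal mixtures would
  # let genotype structure leak into the offsets (inflating within-cell
  # variance). On the shared subset the offsets of all probe sets are the
  # same functional of the genotype pattern and cancel exactly.
  if (center != "none") {
    grouping <- if (center == "class") {
      c("probeset_id", "allele_class")
    } else {
      "probeset_id"
    }
    n_ps_gene <- obs |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::mutate(n_ps = dplyr::n_distinct(.data$probeset_id)) |>
      dplyr::ungroup()
    shared <- n_ps_gene |>
      dplyr::group_by(.data$gene_id, .data$sample_id) |>
      dplyr::mutate(
        in_shared = dplyr::n_distinct(.data$probeset_id) == .data$n_ps[1]
      ) |>
      dplyr::ungroup()
    offsets <- shared |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
      dplyr::summarise(
        offset = if (any(.data$in_shared)) {
          mean(.data$value[.data$in_shared])
        } else {
          mean(.data$value)
        },
        .groups = "drop"
      )
    obs <- obs |>
      dplyr::left_join(offsets, by = grouping) |>
      dplyr::mutate(value = .data$value - .data$offset) |>
      dplyr::select(-"offset")
  }

  obs <- obs |>
    dplyr::mutate(
      sex_cell = ifelse(
        .data$nucleic_acid == "RNA" & .data$chromosome == "A",
        .data$sex, "ALL"
      )
    )

  cells <- obs |>
    dplyr::group_by(
      .data$gene_id, .data$chromosome, .data$allele_class, .data$cross_type,
      .data$line, .data$nucleic_acid, sex = .data$sex_cell
    ) |>
    dplyr::summarise(
      mean = mean(.data$value),
      n = dplyr::n(),
      ss = sum((.data$value - mean(.data$value))^2),
      .groups = "drop"
    )

  variances <- cells |>
    dplyr::group_by(.data$gene_id, .data$nucleic_acid) |>
    dplyr::summarise(
      ss = sum(.data$ss), df = sum(.data$n - 1), .groups = "drop"
    ) |>
    dplyr::mutate(var = ifelse(.data$df > 0, .data$ss / .data$df, NA_real_)) |>
    dplyr::select(-"ss") |>
    tidyr::pivot_wider(
      names_from = "nucleic_acid", values_from = c("var", "df"),
      names_glue = "{.value}_{tolower(nucleic_acid)}", values_fill = list(df = 0L)
    )
  for (nm in c("var_rna", "var_dna")) {
    if (!nm %in% names(variances)) variances[[nm]] <- NA_real_
  }
  for (nm in c("df_rna", "df_dna")) {
    if (!nm %in% names(variances)) variances[[nm]] <- 0L
  }

  structure(
    list(
      cells = dplyr::select(cells, -"ss"),
      variances = variances
    ),
    class = "ase_cellmeans"
  )
}

#' @export
print.ase_cellmeans <- function(x, ...) {
  cat(sprintf(
    "<ase_cellmeans> %d genes, %d cells\n",
    nrow(x$variances), nrow(x$cells)
  ))
  invisible(x)
}
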