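# broom-style tidiers for the fitted objects

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cell-means fit into one row per cell
#'
#' @param x An `ase_cellmeans` object.
#' @param ... Unused.
#' @return The cell-mean tibble (`gene_id`, cell coordinates, `mean`, `n`).
#' @method tidy ase_cellmeans
#' @export
tidy.ase_cellmeans <- function(x, ...) x$cells

#' Per-gene variance summary of a cell-means fit
#'
#' @param x An `ase_cellmeans` object.
#' @param ... Unused.
#' @return One row per gene with `var_rna`, `df_rna`, `var_dna`, `df_dna`.
#' @method glance ase_cellmeans
#' @export
glance.ase_cellmeans <- function(x, ...) x$variances

#' @rdname tidy.ase_cellmeans
#' @method tidy ase_oefit
#' @export
tidy.ase_oefit <- function(x, ...) x$cells

#' @rdname glance.ase_cellmeans
#' @method glance ase_oefit
#' @export
glance.ase_oefit <- function(x, ...) x$variances

#' Tidy an association-test report
#'
#' @param x An `asecis_test` object.
#' @param ... Unused.
#' @return A one-row tibble with `test`, `statistic`, `df`, `p.value` and,
#'   where defined, `odds_ratio`.
#' @method tidy asecis_test
#' @export
tidy.asecis_test <- function(x, ...) {
  tibble::tibble(
    test = x$test,
    statistic = x$statistic %||% NA_real_,
    df = as.numeric(x$df %||% NA_real_),
    p.value = x$p.value,
    odds_ratio = x$odds_ratio %||% NA_real_
  )
}

#' One-line summary of a pipeline run
#'
#' @param x An `ase_run` object.
#' @param ... Unused.
#' @return A one-row tibble with gene, contrast and call counts.
#' @method glance ase_run
#' @export
glance.ase_run <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$genes),
    n_contrasts_tested = sum(x$contrasts$testable),
    n_significant = sum(x$contrasts$significant, na.rm = TRUE),
    n_cis_any = sum(x$calls$cis_any),
    n_trans_any = sum(x$calls$trans_any),
    n_female_biased = sum(x$sexbias$class == "FEMALE_BIASED"),
    n_male_biased = sum(x$sexbias$class == "MALE_BIASED")
  )
}
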