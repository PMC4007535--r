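#' Draw ground-truth regulatory effects for a synthetic experiment
#'
#' Samples, per gene and substitution line, the cis, trans and cis-by-trans
#' effects (natural-log scale) that the signal generator will embed, plus a
#' per-gene sex effect and baseline expression level. Gene-line pairs enter
#' each effect class independently with the configured probabilities; effects
#' for pairs outside a class are exactly zero. A drawn cis or trans effect is
#' shared between the sexes unless the pair is sampled as sex-limited, in
#' which case one sex's effect is zeroed (emulating sex-limited expression of
#' the underlying trans factors, or sex-specific cis action).
#'
#' Orientations: `cis_effect_*` and `cistrans_effect` are recorded as the
#' expected st e-minus-allele2 allelic log-difference -- the quantity the
#' C1/C2 (and C6) contrasts estimate -- so a negative cis effect means the
#' st e allele is the lower expressed one. `trans_effect_*` is the effect of
#' one heterozygous dose of the line's trans background on both alleles (the
#' C3 orientation). `sex_effect` is female minus male. `effect_mean_cis` shifts the
#' cis draw's center away from zero, e.g. to emulate a systematic deficit of
#' the reference allele.
#'
#' X-linked genes carry male cis/trans truth like any other gene, but the
#' `testable_male_ase` flag records that male allelic tests are impossible
#' (males are hemizygous), so those truths are invisible to the ASE analysis.
#'
#' @param config An [sim_config()] object.
#' @param design The matching [sim_design()] output.
#' @return A tibble with one row per gene-line pair: effect columns
#'   `cis_effect_f/m`, `trans_effect_f/m`, `cistrans_effect`, gene-level
#'   `sex_effect`, `base_log`, `chromosome` and `testable_male_ase`.
#' @export
sim_truth <- function(config, design) {
  stopifnot(inherits(config, "ase_sim_config"), inherits(design, "ase_design"))
  with_stage_seed(config$seed, "truth", {
    genes <- design$genes
    n_genes <- nrow(genes)

    u <- runif(n_genes)
    sex_effect <- numeric(n_genes)
    fem <- u < config$frac_female_bias
    mal <- !fem & u < config$frac_female_bias + config$frac_male_bias
    sex_effect[fem] <- abs(rnorm(sum(fem), 0, config$effect_sd_sex))
    sex_effect[mal] <- -abs(rnorm(sum(mal), 0, config$effect_sd_sex))

    gene_level <- genes |>
      dplyr::mutate(
        sex_effect = sex_effect,
        base_log = rnorm(n_genes, config$base_log_mean, config$base_log_sd)
      )

    pairs <- tidyr::expand_grid(gene_id = genes$gene_id, line = sub_lines(config))
    n <- nrow(pairs)

    draw_sexed <- function(frac, sd, mu = 0) {
      member <- runif(n) < frac
      effect <- ifelse(member, rnorm(n, mu, sd), 0)
      limited <- member & runif(n) < config$frac_sex_limited
      limited_to_f <- runif(n) < 0.5
      list(
        f = ifelse(limited & !limited_to_f, 0, effect),
        m = ifelse(limited & limited_to_f, 0, effect)
      )
    }

    cis <- draw_sexed(config$frac_cis, config$effect_sd_cis,
      config$effect_mean_cis %||% 0)
    trans <- draw_sexed(config$frac_trans, config$effect_sd_trans)
    ct_member <- runif(n) < config$frac_cistrans
    cistrans <- ifelse(ct_member, rnorm(n, 0, config$effect_sd_cistrans), 0)

    pairs |>
      dplyr::mutate(
        cis_effect_f = cis$f, cis_effect_m = cis$m,
        trans_effect_f = trans$f, trans_effect_m = trans$m,
        cistrans_effect = cistrans
      ) |>
      dplyr::left_join(gene_level, by = "gene_id") |>
      dplyr::mutate(testable_male_ase = .data$chromosome == "A") |>
      dplyr::select(
        "gene_id", "line", "chromosome", "cis_effect_f", "cis_effect_m",
        "trans_effect_f", "trans_effect_m", "cistrans_effect", "sex_effect",
        "base_log", "testable_male_ase"
      )
  })
}
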