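#' Simulate probe-level intensities for a synthetic experiment
#'
#' Realizes the generative model behind the whole analysis: intensity of probe
#' `p` in sample `s` is
#' `exp(alpha_p) * (q_match + kappa * q_other + b) * exp(slide_s + eps)`,
#' where `alpha_p` is a fixed log-normal probe affinity, `kappa` the
#' cross-hybridization fraction, `b` a small optical background, `slide_s` a
#' per-slide scale factor and `eps` log-scale noise whose SD is chosen by
#' nucleic acid. For DNA hybridizations `q` is allele copy number (0/1/2 by
#' genotype, with male-X hemizygosity never arising because DNA comes from
#' females); for RNA hybridizations `q` composes per-copy expression from the
#' gene's baseline with the cis, trans, cis-by-trans and sex effects of the
#' truth table. Mismatch probes receive no target signal (`q_match = 0`).
#' Hemizygous male X-linked expression is fully dosage-compensated (the
#' single copy is expressed at twice the per-copy rate); DNA copy number is
#' not.
#'
#' The model is multiplicative on the intensity scale, so on the natural-log
#' scale probe affinities are additive offsets that identical DNA and RNA
#' contrasts cancel exactly -- the property the DNA-control contrasts rely on.
#'
#' @param config An [sim_config()] object.
#' @param design The matching [sim_design()] output.
#' @param truth The matching [sim_truth()] output.
#' @return A tibble (`SignalTable`): `probe_id`, `sample_id`, `intensity`,
#'   `slide_id`.
#' @export
sim_signals <- function(config, design, truth) {
  stopifnot(inherits(config, "ase_sim_config"), inherits(design, "ase_design"))
  with_stage_seed(config$seed, "signals", {
    probes <- design$probes |>
      dplyr::mutate(alpha = rnorm(dplyr::n(), 0, config$affinity_sd))
    samples <- design$samples |>
      dplyr::mutate(slide_lfc = rnorm(dplyr::n(), 0, config$slide_sd))

    q_snp <- snp_allele_quantities(config, design, truth, samples)
    snp <- snp_probe_intensities(config, probes, q_snp)
    oe <- oe_probe_intensities(config, probes, samples, truth)

    dplyr::bind_rows(snp, oe) |>
      dplyr::arrange(.data$sample_id, .data$probe_id) |>
      dplyr::select("probe_id", "sample_id", "intensity", "slide_id")
  })
}

# trans dose carried by each cross type's genetic background, relative to the
# full heterozygous (F1) background; the X-substitution genotypes carry only
# the X's share of the donor line's trans factors
trans_dose <- function(cross_type, x_trans_frac) {
  dplyr::case_when(
    cross_type == "F1" ~ 1,
    cross_type == "XHET" ~ x_trans_frac,
    cross_type == "HOMO_SUB" ~ 2 * x_trans_frac,
    TRUE ~ 0
  )
}

# allele copy numbers by genotype, sex, nucleic acid and chromosome;
# DNA samples are female so hemizygosity applies to RNA males only
allele_copies <- function(cross_type, sex, nucleic_acid, chromosome) {
  male_x <- nucleic_acid == "RNA" & sex == "M" & chromosome == "X"
  het_x <- chromosome == "X" & cross_type %in% c("F1", "XHET")
  het_a <- chromosome == "A" & cross_type == "F1"
  sub_homo_x <- chromosome == "X" & cross_type == "HOMO_SUB"

  sub <- dplyr::case_when(
    male_x & cross_type %in% c("F1", "XHET") ~ 1,
    male_x ~ 0,
    sub_homo_x ~ 2,
    het_x | het_a ~ 1,
    TRUE ~ 0
  )
  ste <- dplyr::case_when(
    male_x ~ ifelse(cross_type == "HOMO_STE", 1, 0),
    sub_homo_x ~ 0,
    het_x | het_a ~ 1,
    TRUE ~ 2
  )
  list(ste = ste, sub = sub)
}

# per (SNP probe set x sample): target quantity on each interrogated base
snp_allele_quantities <- function(config, design, truth, samples) {
  sets <- probeset_bases(design$probes) |>
    dplyr::left_join(
      design$probes |>
        dplyr::filter(.data$module == "SNP") |>
        dplyr::distinct(.data$probeset_id, .data$gene_id),
      by = "probeset_id"
    )
  grid <- tidyr::expand_grid(
    probeset_id = sets$probeset_id,
    sample_id = samples$sample_id
  ) |>
    dplyr::left_join(sets, by = "probeset_id") |>
    dplyr::left_join(samples, by = "sample_id") |>
    dplyr::left_join(
      truth |>
        dplyr::select(
          "gene_id", "line", "cis_effect_f", "cis_effect_m", "trans_effect_f",
          "trans_effect_m", "cistrans_effect", "sex_effect", "base_log",
          "chromosome"
        ),
      by = c("gene_id", "line")
    )

  # reference-homozygote samples have no line-specific truth row: zero effects,
  # gene-level baseline/sex effect joined from any line's row
  gene_level <- truth |>
    dplyr::distinct(.data$gene_id, .data$sex_effect, .data$base_log, .data$chromosome)
  ref_rows <- is.na(grid$base_log)
  if (any(ref_rows)) {
    fill <- gene_level[match(grid$gene_id[ref_rows], gene_level$gene_id), ]
    grid$base_log[ref_rows] <- fill$base_log
    grid$sex_effect[ref_rows] <- fill$sex_effect
    grid$chromosome[ref_rows] <- fill$chromosome
    zero_cols <- c(
      "cis_effect_f", "cis_effect_m", "trans_effect_f", "trans_effect_m",
      "cistrans_effect"
    )
    for (cc in zero_cols) grid[[cc]][ref_rows] <- 0
  }

  is_f <- grid$sex == "F"
  cis <- ifelse(is_f, grid$cis_effect_f, grid$cis_effect_m)
  trans <- ifelse(is_f, grid$trans_effect_f, grid$trans_effect_m)
  d_tr <- trans_dose(grid$cross_type, config$x_trans_frac)
  d_int <- as.numeric(grid$cross_type == "F1")

  copies <- allele_copies(grid$cross_type, grid$sex, grid$nucleic_acid, grid$chromosome)

  is_rna <- grid$nucleic_acid == "RNA"
  shared <- grid$base_log + d_tr * trans + ifelse(is_f, grid$sex_effect, 0)
  # per-copy quantities; a homozygote (two copies) at zero effects totals
  # exp(base_log) for RNA and dna_scale for DNA
  # cis and cis-by-trans truth is recorded in the contrast orientation
  # (st e minus allele2), so the substituted allele is scaled by exp(-effect).
  # Hemizygous male X expression is fully dosage-compensated (doubled per
  # copy), as in Drosophila; DNA dosage is not.
  dc <- ifelse(is_rna & grid$sex == "M" & grid$chromosome == "X", 2, 1)
  q_ste <- ifelse(is_rna, dc * exp(shared) / 2, config$dna_scale / 2) * copies$ste
  q_sub <- ifelse(
    is_rna, dc * exp(shared - cis - d_int * grid$cistrans_effect) / 2,
    config$dna_scale / 2
  ) * copies$sub

  # true (unmasked) bases; the line of a reference-homozygote sample is the
  # reference itself, whose base always matches q_ste's allele
  truth_base <- setNames(
    design$snps_truth$allele_base,
    paste(design$snps_truth$probeset_id, design$snps_truth$line)
  )
  ste_base <- unname(truth_base[paste(grid$probeset_id, ref_line)])
  line_base <- unname(truth_base[paste(grid$probeset_id, grid$line)])

  tibble::tibble(
    probeset_id = grid$probeset_id,
    sample_id = grid$sample_id,
    slide_id = grid$slide_id,
    slide_lfc = grid$slide_lfc,
    nucleic_acid = grid$nucleic_acid,
    q_pm1 = q_ste * (ste_base == grid$pm1_base) + q_sub * (line_base == grid$pm1_base),
    q_pm2 = q_ste * (ste_base == grid$pm2_base) + q_sub * (line_base == grid$pm2_base)
  )
}

background_level <- function(config, nucleic_acid) {
  config$background_frac *
    ifelse(nucleic_acid == "RNA", exp(config$base_log_mean), config$dna_scale)
}

snp_probe_intensities <- function(config, probes, q_snp) {
  snp_probes <- probes |>
    dplyr::filter(.data$module == "SNP") |>
    dplyr::select("probe_id", "probeset_id", "role", "alpha")

  d <- dplyr::inner_join(snp_probes, q_snp, by = "probeset_id",
    relationship = "many-to-many")
  q_match <- dplyr::case_when(
    d$role == "PM1" ~ d$q_pm1,
    d$role == "PM2" ~ d$q_pm2,
    TRUE ~ 0
  )
  q_other <- dplyr::case_when(
    d$role == "PM1" ~ d$q_pm2,
    d$role == "PM2" ~ d$q_pm1,
    TRUE ~ d$q_pm1 + d$q_pm2
  )
  noise_sd <- ifelse(d$nucleic_acid == "RNA", config$noise_sd_rna, config$noise_sd_dna)
  b <- background_level(config, d$nucleic_acid)
  eps <- rnorm(nrow(d), 0, noise_sd)

  tibble::tibble(
    probe_id = d$probe_id,
    sample_id = d$sample_id,
    slide_id = d$slide_id,
    intensity = exp(d$alpha + d$slide_lfc + eps) *
      (q_match + config$cross_hyb * q_other + b)
  )
}

oe_probe_intensities <- function(config, probes, samples, truth) {
  oe_probes <- probes |>
    dplyr::filter(.data$module == "EXPR3P") |>
    dplyr::select("probe_id", "probeset_id", "gene_id", "role", "alpha")

  d <- tidyr::expand_grid(
    probe_id = oe_probes$probe_id, sample_id = samples$sample_id
  ) |>
    dplyr::left_join(oe_probes, by = "probe_id") |>
    dplyr::left_join(samples, by = "sample_id") |>
    dplyr::left_join(
      truth |>
        dplyr::select(
          "gene_id", "line", "cis_effect_f", "cis_effect_m", "trans_effect_f",
          "trans_effect_m", "cistrans_effect", "sex_effect", "base_log",
          "chromosome"
        ),
      by = c("gene_id", "line")
    )

  gene_level <- truth |>
    dplyr::distinct(.data$gene_id, .data$sex_effect, .data$base_log, .data$chromosome)
  ref_rows <- is.na(d$base_log) & !is.na(d$gene_id)
  if (any(ref_rows)) {
    fill <- gene_level[match(d$gene_id[ref_rows], gene_level$gene_id), ]
    d$base_log[ref_rows] <- fill$base_log
    d$sex_effect[ref_rows] <- fill$sex_effect
    d$chromosome[ref_rows] <- fill$chromosome
    for (cc in c(
      "cis_effect_f", "cis_effect_m", "trans_effect_f", "trans_effect_m",
      "cistrans_effect"
    )) {
      d[[cc]][ref_rows] <- 0
    }
  }

  is_bg <- is.na(d$gene_id)
  is_rna <- d$nucleic_acid == "RNA"
  is_f <- d$sex == "F"
  cis <- ifelse(is_f, d$cis_effect_f, d$cis_effect_m)
  trans <- ifelse(is_f, d$trans_effect_f, d$trans_effect_m)
  d_tr <- trans_dose(d$cross_type, config$x_trans_frac)
  d_int <- as.numeric(d$cross_type == "F1")
  copies <- allele_copies(d$cross_type, d$sex, d$nucleic_acid, d$chromosome)

  shared <- d$base_log + d_tr * trans + ifelse(is_f, d$sex_effect, 0)
  dc <- ifelse(is_rna & d$sex == "M" & d$chromosome == "X", 2, 1)
  q_total <- ifelse(
    is_bg, 0,
    ifelse(
      is_rna,
      dc * (exp(shared) / 2 * copies$ste +
        exp(shared - cis - d_int * d$cistrans_effect) / 2 * copies$sub),
      config$dna_scale / 2 * (copies$ste + copies$sub)
    )
  )
  q_total[is.na(q_total)] <- 0

  noise_sd <- ifelse(is_rna, config$noise_sd_rna, config$noise_sd_dna)
  b <- background_level(config, d$nucleic_acid)
  eps <- rnorm(nrow(d), 0, noise_sd)

  tibble::tibble(
    probe_id = d$probe_id,
    sample_id = d$sample_id,
    slide_id = d$slide_id,
    intensity = exp(d$alpha + d$slide_lfc + eps) * (q_total + b)
  )
}

#' Simulate a complete synthetic ASE experiment
#'
#' Convenience wrapper running [sim_design()], [sim_truth()] and
#' [sim_signals()] under one configuration. Identical configurations (and
#' seeds) produce bit-identical output.
#'
#' @param config An [sim_config()] object.
#' @return A list of class `ase_sim` with elements `config`, `design`,
#'   `truth` and `signals`.
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes_x = 2, n_genes_auto = 2, seed = 7))
#' names(sim)
simulate_experiment <- function(config) {
  design <- sim_design(config)
  truth <- sim_truth(config, design)
  signals <- sim_signals(config, design, truth)
  structure(
    list(config = config, design = design, truth = truth, signals = signals),
    class = "ase_sim"
  )
}
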