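#' Configuration for the synthetic ASE experiment generator
#'
#' Builds a validated configuration describing a simulated X-substitution
#' experiment: how many genes sit on the X versus the autosomes, how many
#' substitution lines and replicates are hybridized, which fractions of
#' gene-by-line combinations carry cis, trans, cis-by-trans or sex effects,
#' and the log-scale magnitudes of effects, probe affinities and measurement
#' noise. The defaults mirror the hybridization design of the study being
#' emulated: five X-substitution lines, three RNA replicates per genotype and
#' sex, and a single female DNA control per homozygous and F1 genotype.
#'
#' All effect and noise magnitudes are standard deviations on the natural-log
#' intensity scale. Fractions are probabilities in `[0, 1]`; cis/trans/
#' cis-by-trans memberships are drawn independently, so a gene-line pair can
#' carry several effect types at once.
#'
#' @param n_genes_x,n_genes_auto Number of X-linked and autosomal genes.
#' @param n_lines Number of X-substitution lines crossed to the reference.
#' @param reps_rna RNA replicates per genotype and sex.
#' @param reps_dna_default DNA control hybridizations per eligible genotype.
#' @param frac_cis,frac_trans,frac_cistrans Per gene-line probabilities of a
#'   nonzero cis, trans, or cis-by-trans effect.
#' @param frac_female_bias,frac_male_bias Per-gene probabilities of female- or
#'   male-biased expression (mutually exclusive draws).
#' @param frac_sex_limited Probability that a drawn cis or trans effect is
#'   expressed in one sex only.
#' @param effect_sd_cis,effect_sd_trans,effect_sd_sex,effect_sd_cistrans
#'   Log-scale standard deviations of the corresponding effect draws.
#' @param effect_mean_cis Center of the cis-effect draw, in the st e minus
#'   allele2 orientation (default 0; negative values emulate a systematic
#'   deficit of the reference allele).
#' @param noise_sd_rna,noise_sd_dna Log-scale measurement noise for RNA and
#'   DNA hybridizations (must be positive).
#' @param affinity_sd Log-scale SD of fixed per-probe affinities.
#' @param cross_hyb Fraction of the non-target allele's signal picked up by a
#'   perfect-match probe (in `[0, 1)`).
#' @param background_frac Optical background as a fraction of the base signal.
#' @param frac_missing_seq Probability that a line-by-probe-set SNP genotype is
#'   missing from the sequence table (exercises the LDA fallback).
#' @param frac_monomorphic Probability that a line shares the reference base at
#'   a probe set (no polymorphism, probe set uninformative for that cross).
#' @param probesets_per_gene SNP probe sets designed per gene.
#' @param probes_per_class SNP probes per role (PM1/PM2/MM), one per offset.
#' @param oe_probes_per_set Perfect-match probes per 3' expression probe set.
#' @param base_log_mean,base_log_sd Mean and SD of per-gene baseline log
#'   expression (natural-intensity scale is `exp()` of this).
#' @param dna_scale Intensity contributed by two genomic copies in a DNA
#'   hybridization.
#' @param slide_sd Log-scale SD of per-slide scale factors. The default model
#'   has no slide term (`0`); nonzero values exercise the per-slide median
#'   normalization, at the cost of correlating observations that share a
#'   slide, which the independent-error cell-means model deliberately
#'   ignores.
#' @param x_trans_frac Fraction of a line's trans effect attributable to its X
#'   chromosome: the trans dose carried by an X-heterozygote background
#'   relative to the full F1 background.
#' @param seed Integer seed governing all draws (split internally per stage).
#'
#' @return A list of class `ase_sim_config`.
#' @seealso [sim_design()], [sim_truth()], [sim_signals()],
#'   [simulate_experiment()]
#' @export
#' @examples
#' cfg <- sim_config(n_genes_x = 5, n_genes_auto = 10, seed = 1)
#' cfg$n_lines
sim_config <- function(n_genes_x = 150,
                       n_genes_auto = 850,
                       n_lines = 5,
                       reps_rna = 3,
                       reps_dna_default = 1,
                       frac_cis = 0.30,
                       frac_trans = 0.15,
                       frac_cistrans = 0.06,
                       frac_female_bias = 0.42,
                       frac_male_bias = 0.27,
                       frac_sex_limited = 0.20,
                       effect_mean_cis = 0,
                       effect_sd_cis = 0.5,
                       effect_sd_trans = 0.4,
                       effect_sd_sex = 1.0,
                       effect_sd_cistrans = 0.5,
                       noise_sd_rna = 0.15,
                       noise_sd_dna = 0.10,
                       affinity_sd = 0.3,
                       cross_hyb = 0.05,
                       background_frac = 0.01,
                       frac_missing_seq = 0.10,
                       frac_monomorphic = 0.05,
                       probesets_per_gene = 2,
                       probes_per_class = 3,
                       oe_probes_per_set = 5,
                       base_log_mean = log(300),
                       base_log_sd = 0.8,
                       dna_scale = 500,
                       slide_sd = 0,
                       x_trans_frac = 0.2,
                       seed = 1L) {
  cfg <- as.list(environment())

  counts <- c(
    "n_genes_x", "n_genes_auto", "n_lines", "reps_rna", "reps_dna_default",
    "probesets_per_gene", "probes_per_class", "oe_probes_per_set"
  )
  for (nm in counts) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != floor(v)) {
      abort(sprintf("`%s` must be a non-negative integer (got %s).", nm, format(v)),
        class = "asecis_config_error")
    }
    cfg[[nm]] <- as.integer(v)
  }
  if (cfg$n_genes_x + cfg$n_genes_auto < 1) {
    abort("at least one gene must be simulated.", class = "asecis_config_error")
  }
  if (cfg$n_lines < 1 || cfg$reps_rna < 1 || cfg$reps_dna_default < 1) {
    abort("`n_lines`, `reps_rna` and `reps_dna_default` must be >= 1.",
      class = "asecis_config_error")
  }

  props <- c(
    "frac_cis", "frac_trans", "frac_cistrans", "frac_female_bias",
    "frac_male_bias", "frac_sex_limited", "frac_missing_seq",
    "frac_monomorphic", "background_frac"
  )
  for (nm in props) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a proportion in [0, 1] (got %s).", nm, format(v)),
        class = "asecis_config_error")
    }
  }
  if (cfg$frac_female_bias + cfg$frac_male_bias > 1) {
    abort("`frac_female_bias + frac_male_bias` must not exceed 1.",
      class = "asecis_config_error")
  }
  if (cfg$cross_hyb < 0 || cfg$cross_hyb >= 1) {
    abort("`cross_hyb` must lie in [0, 1).", class = "asecis_config_error")
  }
  if (cfg$noise_sd_rna <= 0 || cfg$noise_sd_dna <= 0) {
    abort("noise standard deviations must be positive.",
      class = "asecis_config_error")
  }
  if (!is.numeric(cfg$effect_mean_cis) || length(cfg$effect_mean_cis) != 1 ||
    is.na(cfg$effect_mean_cis)) {
    abort("`effect_mean_cis` must be a number.", class = "asecis_config_error")
  }
  nonneg <- c(
    "effect_sd_cis", "effect_sd_trans", "effect_sd_sex", "effect_sd_cistrans",
    "affinity_sd", "base_log_sd", "slide_sd", "x_trans_frac"
  )
  for (nm in nonneg) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || is.na(cfg[[nm]]) ||
      cfg[[nm]] < 0) {
      abort(sprintf("`%s` must be a non-negative number.", nm),
        class = "asecis_config_error")
    }
  }
  if (cfg$dna_scale <= 0) {
    abort("`dna_scale` must be positive.", class = "asecis_config_error")
  }
  cfg$seed <- as.integer(seed)

  structure(cfg, class = "ase_sim_config")
}

#' @export
print.ase_sim_config <- function(x, ...) {
  cat("<ase_sim_config>\n")
  cat(sprintf(
    "  genes: %d X-linked, %d autosomal; %d lines, %d RNA reps, %d DNA reps\n",
    x$n_genes_x, x$n_genes_auto, x$n_lines, x$reps_rna, x$reps_dna_default
  ))
  cat(sprintf(
    "  effects: cis %.2f (sd %.2f), trans %.2f (sd %.2f), cis x trans %.2f\n",
    x$frac_cis, x$effect_sd_cis, x$frac_trans, x$effect_sd_trans, x$frac_cistrans
  ))
  cat(sprintf(
    "  noise: RNA %.3f, DNA %.3f; affinity sd %.2f; cross-hyb %.2f; seed %d\n",
    x$noise_sd_rna, x$noise_sd_dna, x$affinity_sd, x$cross_hyb, x$seed
  ))
  invisible(x)
}
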