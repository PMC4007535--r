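#' Generate the hybridization design for a synthetic experiment
#'
#' Expands a [sim_config()] into the full set of samples, probes, genes and
#' SNP genotypes implied by an X-substitution design. The design carries the
#' asymmetries of the real experiment:
#'
#' * RNA is hybridized for both sexes of every F1 and X-heterozygote genotype
#'   and of the reference homozygote, but only for females of the homozygous
#'   substitution genotypes -- substitution males are genetically identical to
#'   X-heterozygote males and are not hybridized twice.
#' * DNA controls come from females only, and only for the homozygous and F1
#'   genotypes (X-heterozygote DNA would duplicate F1 allele dosage).
#'
#' Each SNP probe set carries PM1/PM2/MM probe triples at offsets -4, 0 and +4
#' around the interrogated SNP; each 3' expression probe set carries
#' perfect-match probes, with shared GC-binned mismatch probes serving as
#' background controls. The SNP genotype table records, per line and probe
#' set, the line's base at the SNP (or `"MISSING"` where resequencing data are
#' absent).
#'
#' @param config An [sim_config()] object.
#' @return A list of class `ase_design` with tibbles `samples`, `probes`,
#'   `genes` and `snps`.
#' @export
#' @examples
#' d <- sim_design(sim_config(n_genes_x = 2, n_genes_auto = 3, seed = 1))
#' nrow(dplyr::filter(d$samples, nucleic_acid == "RNA"))
sim_design <- function(config) {
  if (!inherits(config, "ase_sim_config")) {
    abort("`config` must be created by sim_config().", class = "asecis_config_error")
  }
  with_stage_seed(config$seed, "design", {
    probes <- design_probes(config)
    snp_tables <- design_snps(config, probes)
    list(
      samples = design_samples(config),
      probes = probes,
      genes = design_genes(config),
      snps = snp_tables$observed,
      snps_truth = snp_tables$truth
    ) |>
      structure(class = "ase_design")
  })
}

ref_line <- "ste"

sub_lines <- function(config) sprintf("L%d", seq_len(config$n_lines))

design_samples <- function(config) {
  lines <- sub_lines(config)
  sexes <- c("F", "M")

  rna <- dplyr::bind_rows(
    tidyr::expand_grid(
      line = lines, cross_type = c("F1", "XHET"), sex = sexes,
      replicate = seq_len(config$reps_rna)
    ),
    tidyr::expand_grid(
      line = ref_line, cross_type = "HOMO_STE", sex = sexes,
      replicate = seq_len(config$reps_rna)
    ),
    tidyr::expand_grid(
      line = lines, cross_type = "HOMO_SUB", sex = "F",
      replicate = seq_len(config$reps_rna)
    )
  ) |>
    dplyr::mutate(nucleic_acid = "RNA")

  dna <- tidyr::expand_grid(
    line = c(lines, ref_line), cross_type = c("HOMO_SUB", "F1", "HOMO_STE"),
    sex = "F", replicate = seq_len(config$reps_dna_default)
  ) |>
    dplyr::filter(
      (.data$line == ref_line) == (.data$cross_type == "HOMO_STE")
    ) |>
    dplyr::mutate(nucleic_acid = "DNA")

  dplyr::bind_rows(rna, dna) |>
    dplyr::mutate(
      sample_id = sprintf(
        "%s_%s_%s_%s_r%d", .data$nucleic_acid, .data$cross_type, .data$line,
        .data$sex, .data$replicate
      ),
      slide_id = .data$sample_id
    ) |>
    dplyr::select(
      "sample_id", "line", "cross_type", "sex", "nucleic_acid", "replicate",
      "slide_id"
    )
}

design_genes <- function(config) {
  n <- config$n_genes_x + config$n_genes_auto
  tibble::tibble(
    gene_id = sprintf("g%05d", seq_len(n)),
    chromosome = rep(c("X", "A"), c(config$n_genes_x, config$n_genes_auto))
  )
}

bases <- c("A", "C", "G", "T")

design_probes <- function(config) {
  genes <- design_genes(config)

  snp_sets <- tidyr::expand_grid(
    gene_id = genes$gene_id, set = seq_len(config$probesets_per_gene)
  ) |>
    dplyr::mutate(probeset_id = sprintf("SNP_%s_%d", .data$gene_id, .data$set))
  # two distinct interrogated bases per SNP probe set
  pm1 <- sample(bases, nrow(snp_sets), replace = TRUE)
  shift <- sample(1:3, nrow(snp_sets), replace = TRUE)
  pm2 <- bases[(match(pm1, bases) - 1L + shift) %% 4L + 1L]
  snp_sets$pm1_base <- pm1
  snp_sets$pm2_base <- pm2

  offsets <- c(-4L, 0L, 4L)[seq_len(min(config$probes_per_class, 3L))]
  snp_probes <- tidyr::expand_grid(
    snp_sets, role = c("PM1", "PM2", "MM"), offset = offsets
  ) |>
    dplyr::mutate(
      module = "SNP",
      probe_id = sprintf("%s_%s_o%+d", .data$probeset_id, .data$role, .data$offset),
      target_base = dplyr::case_when(
        role == "PM1" ~ .data$pm1_base,
        role == "PM2" ~ .data$pm2_base,
        TRUE ~ NA_character_
      ),
      gc_count = sample(6:18, dplyr::n(), replace = TRUE),
      strand = sample(c("+", "-"), dplyr::n(), replace = TRUE)
    )

  oe_probes <- tidyr::expand_grid(
    gene_id = genes$gene_id, probe = seq_len(config$oe_probes_per_set)
  ) |>
    dplyr::mutate(
      probeset_id = sprintf("OE_%s", .data$gene_id),
      probe_id = sprintf("%s_p%d", .data$probeset_id, .data$probe),
      module = "EXPR3P", role = "PM",
      offset = 0L, target_base = NA_character_,
      gc_count = sample(6:18, dplyr::n(), replace = TRUE),
      strand = sample(c("+", "-"), dplyr::n(), replace = TRUE)
    )

  # array-wide GC-binned background mismatch controls, shared by all probe sets
  bg_probes <- tidyr::expand_grid(gc_count = 6:18, probe = 1:8) |>
    dplyr::mutate(
      probeset_id = sprintf("BG_gc%02d", .data$gc_count),
      probe_id = sprintf("%s_p%d", .data$probeset_id, .data$probe),
      gene_id = NA_character_,
      module = "EXPR3P", role = "MM",
      offset = 0L, target_base = NA_character_,
      strand = "+"
    )

  dplyr::bind_rows(snp_probes, oe_probes, bg_probes) |>
    dplyr::select(
      "probe_id", "probeset_id", "gene_id", "module", "role", "gc_count",
      "offset", "strand", "target_base"
    )
}

# per-probe-set interrogated bases, recovered from the probe annotation
probeset_bases <- function(probes) {
  probes |>
    dplyr::filter(.data$module == "SNP", .data$role %in% c("PM1", "PM2")) |>
    dplyr::distinct(.data$probeset_id, .data$role, .data$target_base) |>
    tidyr::pivot_wider(names_from = "role", values_from = "target_base") |>
    dplyr::rename(pm1_base = "PM1", pm2_base = "PM2")
}

design_snps <- function(config, probes) {
  sets <- probeset_bases(probes)

  ste_is_pm1 <- runif(nrow(sets)) < 0.5
  ste_base <- ifelse(ste_is_pm1, sets$pm1_base, sets$pm2_base)
  other_base <- ifelse(ste_is_pm1, sets$pm2_base, sets$pm1_base)

  per_line <- tidyr::expand_grid(
    probeset_id = sets$probeset_id, line = sub_lines(config)
  ) |>
    dplyr::left_join(
      tibble::tibble(
        probeset_id = sets$probeset_id,
        ste_base = ste_base, other_base = other_base
      ),
      by = "probeset_id"
    ) |>
    dplyr::mutate(
      allele_base = ifelse(
        runif(dplyr::n()) < config$frac_monomorphic,
        .data$ste_base, .data$other_base
      )
    )

  truth <- dplyr::bind_rows(
    tibble::tibble(
      probeset_id = sets$probeset_id, line = ref_line, allele_base = ste_base
    ),
    dplyr::select(per_line, "probeset_id", "line", "allele_base")
  ) |>
    dplyr::arrange(.data$probeset_id, .data$line)

  # the observed table masks a fraction of genotypes, as resequencing gaps do;
  # the unmasked truth is retained separately for the signal generator
  observed <- truth |>
    dplyr::mutate(
      allele_base = ifelse(
        runif(dplyr::n()) < config$frac_missing_seq, "MISSING",
        .data$allele_base
      )
    )

  list(observed = observed, truth = truth)
}
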