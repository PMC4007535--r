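# Shared fixtures: all simulated in code, cached so several test files can
# reuse the same moderate-size experiment.

tiny_config <- function(...) {
  sim_config(
    n_genes_x = 3, n_genes_auto = 5, seed = 101,
    frac_missing_seq = 0, frac_monomorphic = 0, ...
  )
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# default-condition run, mixed effects, used by several modules
cached_run <- function() {
  fixture("run_default", function() {
    run_ase_pipeline(
      sim_config(n_genes_x = 12, n_genes_auto = 28, seed = 7),
      out_dir = NULL
    )
  })
}

# effect-free, clean-assignment simulation for identity checks
cached_null_sim <- function() {
  fixture("sim_null", function() {
    simulate_experiment(sim_config(
      n_genes_x = 6, n_genes_auto = 10, seed = 31,
      frac_cis = 0, frac_trans = 0, frac_cistrans = 0,
      frac_female_bias = 0, frac_male_bias = 0,
      frac_missing_seq = 0, frac_monomorphic = 0
    ))
  })
}

# manual cell-means object builder for direct contrast testing
manual_fit <- function(cells, var_rna, df_rna, var_dna = NA_real_, df_dna = 0L,
                       gene_id = "g1", chromosome = "X") {
  cells <- dplyr::mutate(cells,
    gene_id = gene_id, chromosome = chromosome,
    .before = 1
  )
  structure(
    list(
      cells = tibble::as_tibble(cells),
      variances = tibble::tibble(
        gene_id = gene_id, var_rna = var_rna, df_rna = df_rna,
        var_dna = var_dna, df_dna = df_dna
      )
    ),
    class = "ase_cellmeans"
  )
}

cell_row <- function(allele, cross, line, acid, sex, mean, n) {
  tibble::tibble(
    allele_class = allele, cross_type = cross, line = line,
    nucleic_acid = acid, sex = sex, mean = mean, n = n
  )
}
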