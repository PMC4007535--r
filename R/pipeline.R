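#' Run the full analysis pipeline on simulated or supplied data
#'
#' Orchestrates simulate (optional) -> summarize/normalize -> assign ->
#' fit/test allele-specific contrasts -> overall-expression contrasts ->
#' classify -> summary tables, writing every intermediate table as TSV into
#' `out_dir` together with the effective configuration, an input-hash
#' manifest and a run log. Re-running with an identical configuration and
#' inputs reproduces byte-identical outputs.
#'
#' @param config An [sim_config()] for a simulate-and-analyze run, or `NULL`
#'   when `input_dir` supplies pre-existing tables (`signals.tsv`,
#'   `samples.tsv`, `probes.tsv`, `genes.tsv`, `snps.tsv`).
#' @param out_dir Output directory (created if needed). `NULL` keeps
#'   everything in memory.
#' @param input_dir Directory of input TSVs for non-simulation runs.
#' @param fdr_level FDR threshold used throughout (default 0.20).
#' @param band_factor Heterozygote band width for the LDA assignment rule.
#' @param write_signals Write the (large) simulated signal table (default
#'   `TRUE`; disable for big simulations where only results matter).
#' @return A list of class `ase_run` with all intermediate and final tables.
#' @export
run_ase_pipeline <- function(config = sim_config(), out_dir = NULL,
                             input_dir = NULL, fdr_level = 0.2,
                             band_factor = 0.6, write_signals = TRUE) {
  t0 <- Sys.time()
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(
      "[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
      sprintf(fmt, ...)
    )
    log_lines <<- c(log_lines, line)
    invisible(line)
  }

  if (is.null(config) && is.null(input_dir)) {
    abort("either a simulation `config` or an `input_dir` is required.",
      class = "asecis_config_error")
  }

  if (!is.null(input_dir)) {
    needed <- c("signals.tsv", "samples.tsv", "probes.tsv", "genes.tsv", "snps.tsv")
    paths <- file.path(input_dir, needed)
    missing <- needed[!file.exists(paths)]
    if (length(missing) > 0) {
      format_error(sprintf(
        "input directory %s is missing: %s", input_dir,
        paste(missing, collapse = ", ")
      ))
    }
    say("reading inputs from %s", input_dir)
    signals <- read_signal_table(file.path(input_dir, "signals.tsv"))
    samples <- read_sample_table(file.path(input_dir, "samples.tsv"))
    probes <- read_probe_table(file.path(input_dir, "probes.tsv"))
    genes <- read_gene_table(file.path(input_dir, "genes.tsv"))
    snps <- read_snp_table(file.path(input_dir, "snps.tsv"))
    truth <- NULL
    manifest <- tibble::tibble(file = needed, md5 = unname(tools::md5sum(paths)))
  } else {
    say("simulating: %d genes, %d lines, seed %d",
      config$n_genes_x + config$n_genes_auto, config$n_lines, config$seed)
    sim <- simulate_experiment(config)
    signals <- sim$signals
    samples <- sim$design$samples
    probes <- sim$design$probes
    genes <- sim$design$genes
    snps <- sim$design$snps
    truth <- sim$truth
    manifest <- tibble::tibble(
      file = "simulated", md5 = sprintf("seed:%d", config$seed)
    )
  }

  say("summarizing 3' expression probe sets")
  norm <- summarize_expression(signals, probes, samples)

  say("assigning alleles")
  assignments <- assign_alleles(signals, probes, samples, snps, genes,
    band_factor = band_factor) |>
    harmonize_assignments()

  say("normalizing SNP probe sets")
  allele_signal <- normalize_snp_probesets(signals, probes, samples, assignments)

  say("fitting allele-specific cell-means models")
  fit <- fit_cell_means(allele_signal, samples, probes, genes, assignments)
  specs <- build_contrasts(lines = setdiff(unique(snps$line), ref_line))
  contrasts <- test_contrasts(fit, specs) |>
    adjust_fdr(fdr_level = fdr_level)
  calls <- classify_genes(contrasts)

  say("overall-expression analysis")
  oefit <- fit_oe(norm, samples)
  oe_res <- oe_contrasts(oefit, fdr_level = fdr_level)
  probe_gene_map <- probes |>
    dplyr::filter(.data$module == "EXPR3P", !is.na(.data$gene_id)) |>
    dplyr::distinct(.data$probeset_id, .data$gene_id)
  sexbias <- classify_sex_bias(oe_res, probe_gene_map, fdr_level = fdr_level)

  say("building summary tables")
  tables <- build_summary_tables(contrasts, calls, sexbias, genes)

  run <- structure(
    list(
      config = config, samples = samples, probes = probes, genes = genes,
      snps = snps, truth = truth, normalized = norm,
      assignments = assignments, allele_signal = allele_signal,
      fit = fit, contrasts = contrasts, calls = calls,
      oe_contrasts = oe_res, sexbias = sexbias, tables = tables,
      manifest = manifest, log = log_lines
    ),
    class = "ase_run"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
    ok <- FALSE
    on.exit(if (!ok) writeLines("FAILED", file.path(out_dir, "FAILED")))

    if (write_signals) {
      write_signal_table(signals, file.path(out_dir, "signals.tsv"))
    }
    write_sample_table(samples, file.path(out_dir, "samples.tsv"))
    write_probe_table(probes, file.path(out_dir, "probes.tsv"))
    write_gene_table(genes, file.path(out_dir, "genes.tsv"))
    write_snp_table(snps, file.path(out_dir, "snps.tsv"))
    if (!is.null(truth)) {
      write_truth_table(truth, file.path(out_dir, "truth.tsv"))
    }
    write_normalized_expression(norm, file.path(out_dir, "normalized.tsv"))
    write_assignment_table(assignments, file.path(out_dir, "assignments.tsv"))
    write_allele_signal(allele_signal, file.path(out_dir, "allele_signal.tsv"))
    readr::write_tsv(contrasts, file.path(out_dir, "contrasts.tsv"), progress = FALSE)
    readr::write_tsv(calls, file.path(out_dir, "calls.tsv"), progress = FALSE)
    readr::write_tsv(oe_res, file.path(out_dir, "oe_contrasts.tsv"), progress = FALSE)
    readr::write_tsv(sexbias, file.path(out_dir, "sexbias.tsv"), progress = FALSE)
    for (nm in names(tables)) {
      readr::write_tsv(
        tables[[nm]], file.path(out_dir, "tables", paste0(nm, ".tsv")),
        progress = FALSE
      )
    }
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"), progress = FALSE)
    if (!is.null(config)) {
      cfg <- tibble::tibble(
        key = names(unclass(config)),
        value = vapply(unclass(config), function(v) format(v, digits = 15), "")
      )
      readr::write_tsv(cfg, file.path(out_dir, "config.tsv"), progress = FALSE)
    }
    say("done; outputs in %s", out_dir)
    writeLines(log_lines, file.path(out_dir, "run.log"))
    ok <- TRUE
  }

  run
}

#' @export
print.ase_run <- function(x, ...) {
  cat("<ase_run>\n")
  cat(sprintf(
    "  %d genes, %d contrasts tested, %d genes classified\n",
    nrow(x$genes), sum(x$contrasts$testable), nrow(x$calls)
  ))
  invisible(x)
}
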