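# Allele assignment: sequence rules, the LDA fallback and consensus logic.

seq_fixture <- function(ste, line_base, pm1 = "A", pm2 = "G") {
  probes <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"), probeset_id = "ps1", module = "SNP",
    role = c("PM1", "PM2", "MM"), target_base = c(pm1, pm2, NA),
    gc_count = 10L, offset = 0L, strand = "+", gene_id = "g1"
  )
  snps <- tibble::tibble(
    probeset_id = "ps1", line = c("ste", "L1"),
    allele_base = c(ste, line_base)
  )
  assign_from_sequence(snps, probes)
}

test_that("sequence assignment maps matching parental bases", {
  a <- seq_fixture(ste = "A", line_base = "G")
  expect_equal(a$status, "ASSIGNED_SEQ")
  expect_equal(a$ste_probe, "PM1")

  a2 <- seq_fixture(ste = "G", line_base = "A")
  expect_equal(a2$ste_probe, "PM2")
})

test_that("monomorphic crosses are dropped as uninformative", {
  a <- seq_fixture(ste = "A", line_base = "A")
  expect_equal(a$status, "DROPPED")
  expect_equal(a$drop_reason, "NO_POLYMORPHISM")
})

test_that("alleles not represented on the array are dropped", {
  a <- seq_fixture(ste = "C", line_base = "G")
  expect_equal(a$drop_reason, "STE_MATCHES_NEITHER")
  # line allele off-array drops the same way
  a2 <- seq_fixture(ste = "A", line_base = "T")
  expect_equal(a2$status, "DROPPED")
})

test_that("missing parental bases are deferred, not decided", {
  a <- seq_fixture(ste = "MISSING", line_base = "G")
  expect_equal(nrow(a), 0)
})

lda_train <- function(d_ste, d_sub, n = 3, spread = 0.01, seed = 1) {
  # parents separated along the pm1 - pm2 contrast
  withr::with_seed(seed, tibble::tibble(
    parent = rep(c("ste", "sub"), each = n),
    pm1 = c(
      rnorm(n, d_ste / 2, spread), rnorm(n, d_sub / 2, spread)
    ),
    pm2 = c(
      rnorm(n, -d_ste / 2, spread), rnorm(n, -d_sub / 2, spread)
    )
  ))
}

test_that("well-separated parents with an intermediate F1 are retained", {
  train <- lda_train(d_ste = 1, d_sub = -1)
  f1 <- tibble::tibble(pm1 = c(0.01, -0.02, 0), pm2 = c(0, 0.01, -0.01))
  a <- assign_by_lda(train, f1, ste_parent = "ste")
  expect_equal(a$status, "ASSIGNED_LDA")
  expect_equal(a$ste_probe, "PM1")
  expect_equal(a$cv_accuracy, 1)
  expect_true(a$f1_in_band)

  # mirrored geometry flips the st e probe
  a2 <- assign_by_lda(lda_train(d_ste = -1, d_sub = 1), f1, ste_parent = "ste")
  expect_equal(a2$ste_probe, "PM2")
})

test_that("indistinguishable parents are dropped as unresolved", {
  withr::with_seed(2, {
    train <- tibble::tibble(
      parent = rep(c("ste", "sub"), each = 4),
      pm1 = rnorm(8), pm2 = rnorm(8)
    )
  })
  f1 <- tibble::tibble(pm1 = 0, pm2 = 0)
  a <- assign_by_lda(train, f1, ste_parent = "ste")
  expect_equal(a$status, "DROPPED")
  expect_equal(a$drop_reason, "LDA_UNRESOLVED")
})

test_that("insufficient parental replication is MISSING_DATA_UNRESOLVED", {
  train <- lda_train(d_ste = 1, d_sub = -1, n = 1)
  a <- assign_by_lda(train, tibble::tibble(pm1 = 0, pm2 = 0), "ste")
  expect_equal(a$drop_reason, "MISSING_DATA_UNRESOLVED")
})

test_that("LDA retention is sensitive and rarely keeps monomorphic sets", {
  # generator-backed Monte Carlo: X-linked probe sets, defaults of the
  # emulated design, all sequence data masked so every pair goes through LDA
  cfg <- sim_config(
    n_genes_x = 40, n_genes_auto = 0, n_lines = 2, seed = 61,
    frac_missing_seq = 1, frac_monomorphic = 0.5,
    affinity_sd = 0.3, noise_sd_rna = 0.1,
    frac_cis = 0, frac_trans = 0, frac_cistrans = 0,
    frac_female_bias = 0, frac_male_bias = 0
  )
  sim <- simulate_experiment(cfg)
  asg <- assign_alleles(
    sim$signals, sim$design$probes, sim$design$samples, sim$design$snps,
    sim$design$genes
  )
  truth <- sim$design$snps_truth |>
    tidyr::pivot_wider(names_from = line, values_from = allele_base)
  j <- asg |>
    dplyr::left_join(truth, by = "probeset_id") |>
    dplyr::mutate(poly = (line == "L1" & L1 != ste) | (line == "L2" & L2 != ste))
  retained_poly <- mean(j$status[j$poly] != "DROPPED")
  false_retained <- mean(j$status[!j$poly] != "DROPPED")
  expect_gte(retained_poly, 0.9)
  expect_lte(false_retained, 0.1)

  # retained sets carry the correct st e probe
  sets <- asecis:::probeset_bases(sim$design$probes)
  chk <- j |>
    dplyr::filter(status == "ASSIGNED_LDA", poly) |>
    dplyr::inner_join(sets, by = "probeset_id") |>
    dplyr::mutate(true_ste = ifelse(ste == pm1_base, "PM1", "PM2"))
  expect_gte(mean(chk$ste_probe == chk$true_ste), 0.95)
})

test_that("sequence and LDA assignments agree where both paths apply", {
  cfg <- sim_config(
    n_genes_x = 25, n_genes_auto = 0, n_lines = 2, seed = 62,
    frac_missing_seq = 0, frac_monomorphic = 0,
    frac_cis = 0, frac_trans = 0, frac_cistrans = 0,
    frac_female_bias = 0, frac_male_bias = 0
  )
  sim <- simulate_experiment(cfg)
  seq_a <- assign_from_sequence(sim$design$snps, sim$design$probes)
  # mask all sequence data to force LDA on identical signals
  masked <- dplyr::mutate(sim$design$snps, allele_base = "MISSING")
  lda_a <- assign_alleles(
    sim$signals, sim$design$probes, sim$design$samples, masked,
    sim$design$genes
  )
  j <- dplyr::inner_join(
    dplyr::filter(seq_a, status == "ASSIGNED_SEQ"),
    dplyr::filter(lda_a, status == "ASSIGNED_LDA"),
    by = c("probeset_id", "line"), suffix = c("_seq", "_lda")
  )
  # nearly all sequence-assigned pairs are recovered with the same mapping
  expect_gte(nrow(j) / sum(seq_a$status == "ASSIGNED_SEQ"), 0.9)
  expect_true(all(j$ste_probe_seq == j$ste_probe_lda))
})

test_that("autosomal missing-sequence pairs cannot use the LDA fallback", {
  cfg <- sim_config(
    n_genes_x = 0, n_genes_auto = 6, n_lines = 2, seed = 63,
    frac_missing_seq = 1, frac_monomorphic = 0
  )
  sim <- simulate_experiment(cfg)
  asg <- assign_alleles(
    sim$signals, sim$design$probes, sim$design$samples, sim$design$snps,
    sim$design$genes
  )
  expect_true(all(asg$status == "DROPPED"))
  expect_true(all(asg$drop_reason == "MISSING_DATA_UNRESOLVED"))
})

test_that("consensus resolves probe sets and demotes conflicting lines", {
  asg <- tibble::tibble(
    probeset_id = c("ps1", "ps1", "ps1", "ps2", "ps2"),
    line = c("L1", "L2", "L3", "L1", "L2"),
    status = c("ASSIGNED_SEQ", "ASSIGNED_LDA", "ASSIGNED_LDA",
      "ASSIGNED_LDA", "ASSIGNED_LDA"),
    ste_probe = c("PM1", "PM2", "PM1", "PM2", "PM2"),
    drop_reason = "none"
  )
  cons <- consensus_ste_probe(asg)
  # sequence dominates for ps1; LDA majority for ps2
  expect_equal(cons$ste_probe[cons$probeset_id == "ps1"], "PM1")
  expect_equal(cons$ste_probe[cons$probeset_id == "ps2"], "PM2")

  h <- harmonize_assignments(asg)
  demoted <- h[h$probeset_id == "ps1" & h$line == "L2", ]
  expect_equal(demoted$status, "DROPPED")
  expect_equal(demoted$drop_reason, "LDA_UNRESOLVED")
  kept <- h[h$probeset_id == "ps1" & h$line == "L3", ]
  expect_equal(kept$status, "ASSIGNED_LDA")
})

test_that("dropped probe-set/line pairs never reach the model cells", {
  run <- cached_run()
  dropped <- run$assignments |>
    dplyr::filter(status == "DROPPED")
  probe_gene <- run$probes |>
    dplyr::filter(module == "SNP") |>
    dplyr::distinct(probeset_id, gene_id)
  # a line dropped on every probe set of a gene must have no line-specific
  # cells for that gene
  gene_line_dropped <- dropped |>
    dplyr::inner_join(probe_gene, by = "probeset_id") |>
    dplyr::group_by(gene_id, line) |>
    dplyr::summarise(n_drop = dplyr::n(), .groups = "drop") |>
    dplyr::inner_join(
      dplyr::count(probe_gene, gene_id, name = "n_sets"), by = "gene_id"
    ) |>
    dplyr::filter(n_drop == n_sets)
  cells <- run$fit$cells |>
    dplyr::filter(cross_type %in% c("F1", "XHET", "HOMO_SUB"))
  bad <- dplyr::inner_join(cells, gene_line_dropped, by = c("gene_id", "line"))
  expect_equal(nrow(bad), 0)
})
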