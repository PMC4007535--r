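# Contrast construction, the heteroscedastic F-test against independent
# oracles, and the grouped FDR adjustment.

test_that("every contrast's coefficients sum to zero", {
  specs <- build_contrasts(paste0("L", 1:5))
  sums <- specs |>
    dplyr::group_by(family, line, sex, chromosome) |>
    dplyr::summarise(s = sum(coef), n = dplyr::n(), .groups = "drop")
  expect_true(all(sums$s == 0))
  expect_true(all(sums$n == 4))
})

test_that("contrast scoping matches the design's testability", {
  specs <- build_contrasts(c("L1", "L2")) |>
    dplyr::distinct(family, chromosome, sex)
  # C1/C3 for autosomal genes in both sexes, X genes females only
  expect_setequal(
    specs$sex[specs$family == "C1_CIS_F1" & specs$chromosome == "A"],
    c("F", "M")
  )
  expect_equal(
    specs$sex[specs$family == "C1_CIS_F1" & specs$chromosome == "X"], "F"
  )
  # X-het-based and interaction families exist for X females only
  for (fam in c("C2_CIS_XHET", "C4_TRANS_XHET_STE", "C5_TRANS_XHET_SUB",
    "C6_CIS_BY_TRANS")) {
    sc <- specs[specs$family == fam, ]
    expect_equal(sc$chromosome, "X")
    expect_equal(sc$sex, "F")
  }
  expect_error(build_contrasts("L1", families = "C7_NOPE"),
    class = "asecis_scope_error")
})

test_that("a pure cis signal lands in C1/C2 and leaves C3 empty", {
  delta <- 0.5
  cfg <- sim_config(
    n_genes_x = 4, n_genes_auto = 4, seed = 43,
    frac_cis = 1, effect_mean_cis = delta, effect_sd_cis = 0,
    frac_sex_limited = 0, frac_trans = 0, frac_cistrans = 0,
    frac_female_bias = 0, frac_male_bias = 0,
    frac_missing_seq = 0, frac_monomorphic = 0,
    cross_hyb = 0, background_frac = 0,
    noise_sd_rna = 1e-6, noise_sd_dna = 1e-6
  )
  run <- run_ase_pipeline(cfg, out_dir = NULL)
  r <- dplyr::filter(run$contrasts, testable)
  cis <- dplyr::filter(r, family %in% c("C1_CIS_F1", "C2_CIS_XHET"))
  expect_equal(cis$estimate, rep(delta, nrow(cis)), tolerance = 1e-4)
  oth <- dplyr::filter(r, family %in% c("C3_TRANS_F1", "C4_TRANS_XHET_STE",
    "C5_TRANS_XHET_SUB", "C6_CIS_BY_TRANS"))
  expect_equal(oth$estimate, rep(0, nrow(oth)), tolerance = 1e-4)
})

test_that("trans and interaction effects land in their own families", {
  cfg <- sim_config(
    n_genes_x = 5, n_genes_auto = 0, seed = 44,
    frac_cis = 0, frac_trans = 1, effect_sd_trans = 0.001,
    frac_cistrans = 1, effect_sd_cistrans = 0.001,
    frac_sex_limited = 0,
    frac_female_bias = 0, frac_male_bias = 0,
    frac_missing_seq = 0, frac_monomorphic = 0,
    cross_hyb = 0, background_frac = 0,
    noise_sd_rna = 1e-7, noise_sd_dna = 1e-7, x_trans_frac = 0.2
  )
  sim <- simulate_experiment(cfg)
  run <- run_ase_pipeline(cfg, out_dir = NULL)
  r <- run$contrasts |>
    dplyr::filter(testable) |>
    dplyr::inner_join(
      dplyr::select(run$truth, gene_id, line, trans_effect_f, cistrans_effect),
      by = c("gene_id", "line")
    )
  c3 <- dplyr::filter(r, family == "C3_TRANS_F1")
  expect_equal(c3$estimate, c3$trans_effect_f, tolerance = 1e-4)
  # X-het carries the X's share of the trans dose
  c4 <- dplyr::filter(r, family == "C4_TRANS_XHET_STE")
  expect_equal(c4$estimate, 0.2 * c4$trans_effect_f, tolerance = 1e-4)
  c5 <- dplyr::filter(r, family == "C5_TRANS_XHET_SUB")
  expect_equal(c5$estimate, -0.2 * c5$trans_effect_f, tolerance = 1e-4)
  # interaction: allelic-imbalance difference between F1 and X-het
  c6 <- dplyr::filter(r, family == "C6_CIS_BY_TRANS")
  expect_equal(c6$estimate, c6$cistrans_effect, tolerance = 1e-4)
})

test_that("equal cell means give a zero statistic and p = 1", {
  cells <- dplyr::bind_rows(
    cell_row("STE", "F1", "L1", "RNA", "ALL", 1.5, 3),
    cell_row("ALLELE2", "F1", "L1", "RNA", "ALL", 1.5, 3),
    cell_row("STE", "F1", "L1", "DNA", "ALL", 1.5, 2),
    cell_row("ALLELE2", "F1", "L1", "DNA", "ALL", 1.5, 2)
  )
  fit <- manual_fit(cells, var_rna = 0.2, df_rna = 8, var_dna = 0.1, df_dna = 2)
  res <- test_contrasts(fit, build_contrasts("L1", families = "C1_CIS_F1"))
  expect_equal(res$estimate, 0)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
})

test_that("degenerate zero variance is handled as specified", {
  cells <- dplyr::bind_rows(
    cell_row("STE", "F1", "L1", "RNA", "ALL", 2, 3),
    cell_row("ALLELE2", "F1", "L1", "RNA", "ALL", 1, 3),
    cell_row("STE", "F1", "L1", "DNA", "ALL", 0, 2),
    cell_row("ALLELE2", "F1", "L1", "DNA", "ALL", 0, 2)
  )
  fit <- manual_fit(cells, var_rna = 0, df_rna = 8, var_dna = 0, df_dna = 2)
  expect_warning(
    res <- test_contrasts(fit, build_contrasts("L1", families = "C1_CIS_F1")),
    "degenerate"
  )
  expect_equal(res$p, 0)
})

test_that("F and p match an OLS contrast oracle on RNA-only instances", {
  skip_if_not_installed("emmeans")
  withr::with_seed(51, {
    for (i in 1:20) {
      n1 <- sample(2:4, 1)
      n2 <- sample(2:4, 1)
      y1 <- rnorm(n1)
      y2 <- rnorm(n2)
      cells <- dplyr::bind_rows(
        cell_row("STE", "F1", "L1", "RNA", "ALL", mean(y1), n1),
        cell_row("ALLELE2", "F1", "L1", "RNA", "ALL", mean(y2), n2)
      )
      ss <- sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)
      df <- n1 + n2 - 2
      fit <- manual_fit(cells, var_rna = ss / df, df_rna = df)
      spec <- tibble::tibble(
        family = "AI", line = "L1", sex = "F", chromosome = "X",
        allele_class = c("STE", "ALLELE2"), cross_type = "F1",
        cell_line = "L1", nucleic_acid = "RNA", cell_sex = "ALL",
        coef = c(1, -1)
      )
      res <- test_contrasts(fit, spec)

      d <- data.frame(
        y = c(y1, y2),
        cell = factor(rep(c("a", "b"), c(n1, n2)))
      )
      lmfit <- lm(y ~ 0 + cell, data = d)
      or <- as.data.frame(emmeans::contrast(
        emmeans::emmeans(lmfit, "cell"), list(ai = c(1, -1))
      ))
      expect_equal(res$estimate, or$estimate, tolerance = 1e-10)
      expect_equal(res$F, or$t.ratio^2, tolerance = 1e-10)
      expect_equal(res$p, or$p.value, tolerance = 1e-10)
    }
  })
})

test_that("mixed RNA/DNA tests match a hand-rolled Satterthwaite oracle", {
  withr::with_seed(52, {
    for (i in 1:20) {
      reps <- sample(2:3, 4, replace = TRUE)
      ys <- lapply(reps, function(n) rnorm(n, sd = sample(c(0.5, 1), 1)))
      acid <- c("RNA", "RNA", "DNA", "DNA")
      cells <- dplyr::bind_rows(
        cell_row("STE", "F1", "L1", "RNA", "ALL", mean(ys[[1]]), reps[1]),
        cell_row("ALLELE2", "F1", "L1", "RNA", "ALL", mean(ys[[2]]), reps[2]),
        cell_row("STE", "F1", "L1", "DNA", "ALL", mean(ys[[3]]), reps[3]),
        cell_row("ALLELE2", "F1", "L1", "DNA", "ALL", mean(ys[[4]]), reps[4])
      )
      ssr <- sum(vapply(ys[1:2], function(y) sum((y - mean(y))^2), 1))
      ssd <- sum(vapply(ys[3:4], function(y) sum((y - mean(y))^2), 1))
      dfr <- sum(reps[1:2] - 1)
      dfd <- sum(reps[3:4] - 1)
      fit <- manual_fit(cells, var_rna = ssr / dfr, df_rna = dfr,
        var_dna = ssd / dfd, df_dna = dfd)
      res <- test_contrasts(fit, build_contrasts("L1", families = "C1_CIS_F1"))

      # oracle written straight from the two-variance contrast formulas
      est <- (mean(ys[[1]]) - mean(ys[[2]])) - (mean(ys[[3]]) - mean(ys[[4]]))
      vr <- (ssr / dfr) * (1 / reps[1] + 1 / reps[2])
      vd <- (ssd / dfd) * (1 / reps[3] + 1 / reps[4])
      se2 <- vr + vd
      f <- est^2 / se2
      nu <- se2^2 / (vr^2 / dfr + vd^2 / dfd)
      p <- pf(f, 1, nu, lower.tail = FALSE)
      expect_equal(res$estimate, est, tolerance = 1e-10)
      expect_equal(res$F, f, tolerance = 1e-10)
      expect_equal(res$df_den, nu, tolerance = 1e-10)
      expect_equal(res$p, p, tolerance = 1e-10)
    }
  })
})

test_that("the standardized effect uses the RNA residual scale", {
  cells <- dplyr::bind_rows(
    cell_row("STE", "F1", "L1", "RNA", "ALL", 2, 3),
    cell_row("ALLELE2", "F1", "L1", "RNA", "ALL", 1, 3),
    cell_row("STE", "F1", "L1", "DNA", "ALL", 0.2, 2),
    cell_row("ALLELE2", "F1", "L1", "DNA", "ALL", 0.1, 2)
  )
  fit <- manual_fit(cells, var_rna = 0.25, df_rna = 8, var_dna = 0.04,
    df_dna = 2)
  res <- test_contrasts(fit, build_contrasts("L1", families = "C1_CIS_F1"))
  expect_equal(res$effect_size, res$estimate / 0.5)
})

test_that("affinity-like class offsets cancel in all six families", {
  run <- cached_run()
  res0 <- test_contrasts(run$fit, build_contrasts(paste0("L", 1:5)))
  shifted <- run$allele_signal |>
    dplyr::mutate(value = value + ifelse(allele_class == "STE", 0.73, 0))
  fit1 <- fit_cell_means(shifted, run$samples, run$probes, run$genes,
    run$assignments, center = "none")
  fit0 <- fit_cell_means(run$allele_signal, run$samples, run$probes,
    run$genes, run$assignments, center = "none")
  r1 <- test_contrasts(fit1, build_contrasts(paste0("L", 1:5)))
  r0 <- test_contrasts(fit0, build_contrasts(paste0("L", 1:5)))
  j <- dplyr::inner_join(
    dplyr::filter(r0, testable), dplyr::filter(r1, testable),
    by = c("gene_id", "family", "line", "sex")
  )
  expect_equal(j$estimate.x, j$estimate.y, tolerance = 1e-10)
})

test_that("Benjamini-Hochberg is applied within families, by hand", {
  res <- tibble::tibble(
    family = rep(c("A", "B"), c(4, 1)),
    p = c(0.01, 0.02, 0.03, 0.04, 0.2),
    testable = TRUE
  )
  out <- adjust_fdr(res)
  expect_equal(out$q[out$family == "A"], rep(0.04, 4))
  expect_equal(out$q[out$family == "B"], 0.2)

  # permuting another family's p-values leaves this family's q unchanged
  res2 <- res
  res2$p[res2$family == "B"] <- 0.9
  out2 <- adjust_fdr(res2)
  expect_equal(out$q[out$family == "A"], out2$q[out2$family == "A"])

  # q is monotone in p within a family and never below p
  withr::with_seed(53, {
    r <- tibble::tibble(family = "A", p = runif(50), testable = TRUE)
  })
  o <- adjust_fdr(r) |> dplyr::arrange(p)
  expect_true(all(diff(o$q) >= -1e-12))
  expect_true(all(o$q >= o$p - 1e-12))
  expect_equal(adjust_fdr(tibble::tibble(family = "A", p = 0.17,
    testable = TRUE))$q, 0.17)
})

test_that("the significance flag follows the configured FDR level", {
  res <- tibble::tibble(family = "A", p = c(0.001, 0.5), testable = TRUE)
  expect_equal(adjust_fdr(res, fdr_level = 0.2)$significant, c(TRUE, FALSE))
  expect_equal(adjust_fdr(res, fdr_level = 0.0005)$significant, c(FALSE, FALSE))
})
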