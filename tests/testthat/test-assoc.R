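# Contingency statistics: expected counts, the four tests, and agreement
# with independent references.

table2 <- rbind(X = c(386, 913, 208), Autosome = c(3058, 4467, 1390))
table3a <- rbind(
  no_bias = c(709, 55, 127, 499),
  female_bias = c(2298, 367, 396, 1405),
  male_bias = c(1477, 227, 489, 864)
)
table3b <- rbind(
  no_bias = c(1103, 79, 97, 111),
  female_bias = c(3201, 131, 726, 409),
  male_bias = c(2355, 379, 134, 190)
)
colnames(table3a) <- colnames(table3b) <-
  c("NONE", "MALE_ONLY", "FEMALE_ONLY", "BOTH_SEXES")

test_that("expected counts reproduce the published contingency arithmetic", {
  r <- chi2_independence(table2)
  expect_equal(
    unname(r$expected_rounded),
    rbind(c(498, 778, 231), c(2946, 4602, 1367))
  )
  expect_lt(r$p.value, 1e-4)

  ra <- chi2_independence(table3a)
  expect_equal(ra$expected_rounded["female_bias", "FEMALE_ONLY"], 507)
  rb <- chi2_independence(table3b)
  expect_equal(rb$expected_rounded["no_bias", "NONE"], 1038)
  # marginals derive from the cells: expected sums to observed
  expect_equal(sum(ra$expected), sum(table3a))
})

test_that("a table at independence gives chi-square 0 and p 1", {
  r <- chi2_independence(rbind(c(10, 10), c(10, 10)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  expect_error(chi2_independence(rbind(c(0, 0), c(3, 4))),
    class = "asecis_format_error")
})

test_that("chi-square matches stats::chisq.test on random tables", {
  withr::with_seed(81, {
    for (i in 1:25) {
      nr <- sample(2:4, 1)
      nc <- sample(2:4, 1)
      tab <- matrix(rpois(nr * nc, 30) + 1, nr, nc)
      r <- chi2_independence(tab)
      ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
      expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-8)
      expect_equal(r$p.value, ref$p.value, tolerance = 1e-8)
      expect_equal(r$df, unname(ref$parameter))
      expect_equal(unname(r$expected), unname(ref$expected), tolerance = 1e-8)
    }
  })
})

test_that("cis and trans regulation positively covary in the printed 2x2", {
  r <- fisher_exact_2x2(rbind(c(1770, 3577), c(1009, 4937)))
  expect_equal(r$odds_ratio, (1770 * 4937) / (3577 * 1009), tolerance = 1e-12)
  expect_gt(r$odds_ratio, 2.4)
  expect_lt(r$p.value, 1e-4)
})

test_that("a flat 2x2 gives odds ratio 1 and p 1; zero margins degenerate", {
  r <- fisher_exact_2x2(rbind(c(5, 5), c(5, 5)))
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p.value, 1)
  z <- fisher_exact_2x2(rbind(c(0, 0), c(3, 4)))
  expect_equal(z$p.value, 1)
  expect_true(z$degenerate)
})

test_that("Fisher p agrees with margin-preserving enumeration for n <= 40", {
  # enumeration oracle: sum the hypergeometric probabilities of all tables
  # with the observed margins whose probability does not exceed the
  # observed table's
  enum_p <- function(tab) {
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    a_range <- max(0, r1 + c1 - n):min(r1, c1)
    probs <- dhyper(a_range, c1, n - c1, r1)
    p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  withr::with_seed(82, {
    for (i in 1:25) {
      tab <- matrix(sample(0:10, 4, replace = TRUE), 2, 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      r <- fisher_exact_2x2(tab)
      expect_equal(r$p.value, enum_p(tab), tolerance = 1e-8)
    }
  })
})

test_that("McNemar reproduces the printed sex-limited asymmetry", {
  r <- mcnemar_asym(131, 726)
  expect_equal(r$statistic, (131 - 726)^2 / 857, tolerance = 1e-12)
  expect_equal(round(r$statistic, 1), 413.1)
  expect_lt(r$p.value, 1e-4)
})

test_that("symmetric discordance gives statistic 0 and p 1", {
  r <- mcnemar_asym(40, 40)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  z <- mcnemar_asym(0, 0)
  expect_equal(z$p.value, 1)
})

test_that("McNemar agrees with stats::mcnemar.test and the sign test", {
  ps <- sign_ps <- numeric()
  withr::with_seed(83, {
    for (i in 1:20) {
      b <- sample(0:15, 1)
      c_ <- sample(0:15, 1)
      if (b + c_ == 0) next
      r <- mcnemar_asym(b, c_)
      tab <- rbind(c(3, b), c(c_, 7))
      ref <- mcnemar.test(tab, correct = FALSE)
      expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-8)
      expect_equal(r$p.value, ref$p.value, tolerance = 1e-8)
      ps <- c(ps, r$p.value)
      sign_ps <- c(sign_ps, binom.test(b, b + c_, 0.5)$p.value)
    }
  })
  # the asymptotic p ranks discordance the same way as the exact binomial
  # sign test over all b + c <= 30 instances drawn above
  expect_gt(cor(ps, sign_ps, method = "spearman"), 0.95)
})

test_that("identical strata are homogeneous; the printed strata are not", {
  same <- replicate(3, rbind(c(30, 20), c(10, 40)), simplify = FALSE)
  r <- breslow_day(same)
  expect_lt(r$statistic, 1e-8)
  expect_gt(r$p.value, 0.999)

  cis_strata <- sex_limited_strata(asecis:::contingency_long(table3a))
  rc <- breslow_day(cis_strata)
  expect_equal(rc$df, 2)
  expect_lt(rc$p.value, 1e-4)
})

test_that("Breslow-Day rejects clearly heterogeneous odds ratios", {
  # OR 1 versus OR 9 at n = 400 per stratum
  s1 <- rbind(c(100, 100), c(100, 100))
  s2 <- rbind(c(180, 20), c(100, 100))
  r <- breslow_day(list(s1, s2))
  expect_lt(r$p.value, 0.01)
})

test_that("Tarone's adjustment never increases the statistic", {
  withr::with_seed(84, {
    for (i in 1:10) {
      strata <- replicate(3, matrix(rpois(4, 40) + 1, 2, 2), simplify = FALSE)
      a <- breslow_day(strata, tarone = TRUE)
      b <- breslow_day(strata, tarone = FALSE)
      expect_lte(a$statistic, b$statistic + 1e-12)
    }
  })
})

test_that("degenerate strata are excluded with a warning", {
  strata <- list(
    rbind(c(30, 20), c(10, 40)),
    rbind(c(25, 25), c(15, 35)),
    rbind(c(0, 0), c(5, 5))
  )
  expect_warning(r <- breslow_day(strata), "degenerate")
  expect_equal(r$df, 1)
  expect_error(
    suppressWarnings(breslow_day(list(rbind(c(0, 0), c(5, 5)),
      rbind(c(1, 1), c(1, 1))))),
    class = "asecis_format_error"
  )
})

test_that("test reports tidy into one-row tibbles", {
  td <- tidy(chi2_independence(table2))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_true(all(c("statistic", "p.value") %in% names(td)))
  tf <- tidy(fisher_exact_2x2(rbind(c(5, 1), c(2, 7))))
  expect_false(is.na(tf$odds_ratio))
})
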