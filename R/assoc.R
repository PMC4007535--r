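# Contingency-table association tests used to relate regulatory variation to
# sex bias and chromosomal location.

as_count_matrix <- function(x) {
  if (is.data.frame(x)) {
    rn <- NULL
    if (!is.null(x[[1]]) && is.character(x[[1]])) {
      rn <- x[[1]]
      x <- x[-1]
    }
    x <- as.matrix(x)
    if (!is.null(rn)) rownames(x) <- rn
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("a contingency table must be a numeric matrix or data frame of counts.",
      class = "asecis_format_error")
  }
  if (any(x < 0) || any(x != floor(x))) {
    abort("contingency counts must be non-negative integers.",
      class = "asecis_format_error")
  }
  x
}

#' Expected counts under independence
#'
#' `expected(r, c) = rowtotal(r) * coltotal(c) / grandtotal`. Returned
#' unrounded; displays round half-up to integers as the source tables do.
#'
#' @param observed A numeric matrix (or data frame) of counts.
#' @return A matrix of expected counts with the same dimnames.
#' @export
expected_counts <- function(observed) {
  obs <- as_count_matrix(observed)
  outer(rowSums(obs), colSums(obs)) / sum(obs)
}

new_test_report <- function(test, statistic, df, p, ...) {
  structure(
    c(list(test = test, statistic = statistic, df = df, p.value = p), list(...)),
    class = "asecis_test"
  )
}

#' @export
print.asecis_test <- function(x, ...) {
  cat(sprintf("%s\n", x$test))
  if (!is.null(x$df) && !is.na(x$df)) {
    cat(sprintf("  statistic = %.4g, df = %s, p = %.4g\n", x$statistic,
      format(x$df), x$p.value))
  } else {
    cat(sprintf("  p = %.4g\n", x$p.value))
  }
  if (!is.null(x$odds_ratio)) {
    cat(sprintf("  odds ratio = %.4g\n", x$odds_ratio))
  }
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Computes `X^2 = sum((O - E)^2 / E)` on `(r - 1)(c - 1)` df with the
#' upper-tail chi-square p-value, returning the unrounded expected counts and
#' an integer-rounded copy for display.
#'
#' @param observed A matrix (or data frame) of observed counts; all row and
#'   column totals must be positive.
#' @return An `asecis_test` with `expected` and `expected_rounded` matrices.
#' @export
#' @examples
#' tab <- rbind(X = c(386, 913, 208), Autosome = c(3058, 4467, 1390))
#' chi2_independence(tab)$expected_rounded
chi2_independence <- function(observed) {
  obs <- as_count_matrix(observed)
  if (any(rowSums(obs) == 0) || any(colSums(obs) == 0)) {
    abort("chi-square test requires positive row and column totals.",
      class = "asecis_format_error")
  }
  expected <- expected_counts(obs)
  stat <- sum((obs - expected)^2 / expected)
  df <- (nrow(obs) - 1) * (ncol(obs) - 1)
  new_test_report(
    "Pearson chi-square test of independence",
    statistic = stat, df = df,
    p = pchisq(stat, df, lower.tail = FALSE),
    expected = expected,
    expected_rounded = round_half_up(expected)
  )
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p-value from the hypergeometric distribution (via
#' [stats::fisher.test()]) together with the sample odds ratio `ad / bc`
#' (not the conditional MLE).
#'
#' @param observed A 2x2 matrix (or data frame) of counts.
#' @return An `asecis_test` with `odds_ratio`; a zero row or column margin
#'   gives `p = 1` with `odds_ratio = NA` and `degenerate = TRUE`.
#' @export
fisher_exact_2x2 <- function(observed) {
  obs <- as_count_matrix(observed)
  if (!all(dim(obs) == c(2, 2))) {
    abort("fisher_exact_2x2 requires a 2x2 table.", class = "asecis_format_error")
  }
  if (any(rowSums(obs) == 0) || any(colSums(obs) == 0)) {
    return(new_test_report(
      "Fisher's exact test (2x2, two-sided)",
      statistic = NA_real_, df = NA_real_, p = 1,
      odds_ratio = NA_real_, degenerate = TRUE
    ))
  }
  p <- stats::fisher.test(obs, alternative = "two.sided")$p.value
  or <- (obs[1, 1] * obs[2, 2]) / (obs[1, 2] * obs[2, 1])
  new_test_report(
    "Fisher's exact test (2x2, two-sided)",
    statistic = NA_real_, df = NA_real_, p = p,
    odds_ratio = or, degenerate = FALSE
  )
}

#' McNemar's test for discordant counts
#'
#' Tests symmetry of the two discordant cells of a paired design --- here the
#' male-only and female-only counts of a sex-limited regulatory class ---
#' with `X^2 = (b - c)^2 / (b + c)` on 1 df (no continuity correction by
#' default: the discordant counts this test is used on are large).
#'
#' @param discordant_b,discordant_c The two discordant counts.
#' @param correct Apply the continuity correction `(|b - c| - 1)^2 / (b + c)`.
#' @return An `asecis_test`; `b = c = 0` gives statistic 0, `p = 1`.
#' @export
#' @examples
#' mcnemar_asym(131, 726)
mcnemar_asym <- function(discordant_b, discordant_c, correct = FALSE) {
  b <- discordant_b
  c <- discordant_c
  if (b < 0 || c < 0 || b != floor(b) || c != floor(c)) {
    abort("discordant counts must be non-negative integers.",
      class = "asecis_format_error")
  }
  if (b + c == 0) {
    return(new_test_report("McNemar's test", statistic = 0, df = 1, p = 1))
  }
  num <- if (correct) (abs(b - c) - 1)^2 else (b - c)^2
  stat <- num / (b + c)
  new_test_report(
    "McNemar's test",
    statistic = stat, df = 1, p = pchisq(stat, 1, lower.tail = FALSE)
  )
}

#' Breslow-Day test for homogeneity of odds ratios
#'
#' Tests whether the odds ratio is common across `K` strata of 2x2 tables.
#' For each stratum the expected count in cell (1,1) under the
#' Mantel-Haenszel common odds ratio is found (the admissible root of the
#' defining quadratic), and the statistic sums
#' `(a_k - E_k)^2 / Var_k` over strata, on `K - 1` df. Tarone's correction
#' (default on) subtracts `(sum(a_k - E_k))^2 / sum(Var_k)`, which never
#' increases the statistic. Degenerate strata (a zero margin) are excluded
#' with a warning.
#'
#' @param strata A list of 2x2 count matrices.
#' @param tarone Apply Tarone's adjustment (default `TRUE`).
#' @return An `asecis_test` with per-stratum odds ratios (`strata_or`) and
#'   the Mantel-Haenszel common odds ratio (`common_or`).
#' @export
breslow_day <- function(strata, tarone = TRUE) {
  strata <- lapply(strata, as_count_matrix)
  ok <- vapply(strata, function(t) {
    all(dim(t) == c(2, 2)) && all(rowSums(t) > 0) && all(colSums(t) > 0)
  }, logical(1))
  if (any(!ok)) {
    warn(sprintf("excluding %d degenerate stratum/strata with zero margins",
      sum(!ok)))
    strata <- strata[ok]
  }
  k <- length(strata)
  if (k < 2) {
    abort("Breslow-Day requires at least two non-degenerate strata.",
      class = "asecis_format_error")
  }

  a <- vapply(strata, function(t) t[1, 1], numeric(1))
  b <- vapply(strata, function(t) t[1, 2], numeric(1))
  c_ <- vapply(strata, function(t) t[2, 1], numeric(1))
  d <- vapply(strata, function(t) t[2, 2], numeric(1))
  n <- a + b + c_ + d

  or_mh <- sum(a * d / n) / sum(b * c_ / n)

  expected_a <- function(a, b, c_, d, psi) {
    r1 <- a + b
    c1 <- a + c_
    n <- a + b + c_ + d
    if (psi == 1) {
      return(r1 * c1 / n)
    }
    # psi = A(n - r1 - c1 + A) / ((r1 - A)(c1 - A)); admissible root in
    # (max(0, r1 + c1 - n), min(r1, c1))
    qa <- psi - 1
    qb <- -((r1 + c1) * psi + (n - r1 - c1))
    qc <- psi * r1 * c1
    disc <- sqrt(qb^2 - 4 * qa * qc)
    roots <- c((-qb + disc) / (2 * qa), (-qb - disc) / (2 * qa))
    lo <- max(0, r1 + c1 - n)
    hi <- min(r1, c1)
    roots[roots > lo - 1e-9 & roots < hi + 1e-9][1]
  }

  e <- mapply(expected_a, a, b, c_, d, MoreArgs = list(psi = or_mh))
  r1 <- a + b
  c1 <- a + c_
  v <- 1 / (1 / e + 1 / (r1 - e) + 1 / (c1 - e) + 1 / (n - r1 - c1 + e))

  stat <- sum((a - e)^2 / v)
  if (tarone) stat <- stat - sum(a - e)^2 / sum(v)
  df <- k - 1
  new_test_report(
    if (tarone) "Breslow-Day test (Tarone adjusted)" else "Breslow-Day test",
    statistic = stat, df = df,
    p = pchisq(stat, df, lower.tail = FALSE),
    strata_or = (a * d) / (b * c_), common_or = or_mh
  )
}
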