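#' Summarize 3' expression probe sets with GC-binned background correction
#'
#' Implements the overall-expression normalization: for every perfect-match
#' probe the 5th percentile of the mismatch/background probes sharing its GC
#' count on the same array is subtracted, the corrected probe values are
#' averaged within the probe set, and the estimate of expression is the
#' natural log of that mean plus 100. The +100 guard tolerates moderately
#' negative background-corrected probes; a probe set whose corrected mean
#' still falls at or below -100 is an error (it would have no finite log).
#'
#' GC binning matches probes on exact `gc_count`, per sample. The 5th
#' percentile uses linear interpolation between order statistics
#' (`stats::quantile()` type 7), pinned here so results are bit-reproducible.
#'
#' @param signals A signal table (see [read_signal_table()]).
#' @param probes Probe annotation; `module == "EXPR3P"` rows are used, with
#'   `role == "PM"` probes summarized against `role == "MM"` background
#'   probes in the same GC bin.
#' @param samples Optional sample metadata; when given, only listed samples
#'   are summarized.
#' @return A tibble (`NormalizedExpression`): `probeset_id`, `sample_id`,
#'   `value` (natural-log scale).
#' @export
#' @examples
#' probes <- tibble::tibble(
#'   probe_id = c("p1", "p2", "p3", "m1", "m2"),
#'   probeset_id = c("ps1", "ps1", "ps1", "bg", "bg"),
#'   module = "EXPR3P", role = c("PM", "PM", "PM", "MM", "MM"),
#'   gc_count = 10L
#' )
#' signals <- tibble::tibble(
#'   probe_id = c("p1", "p2", "p3", "m1", "m2"), sample_id = "s1",
#'   intensity = c(250, 350, 450, 50, 50), slide_id = "s1"
#' )
#' summarize_expression(signals, probes) # ln(300 + 100) = 5.9915
summarize_expression <- function(signals, probes, samples = NULL) {
  assert_columns(signals, c("probe_id", "sample_id", "intensity"))
  assert_columns(probes, c("probe_id", "probeset_id", "module", "role", "gc_count"))
  if (!is.null(samples)) {
    signals <- dplyr::semi_join(signals, samples, by = "sample_id")
  }

  oe <- probes |>
    dplyr::filter(.data$module == "EXPR3P") |>
    dplyr::select("probe_id", "probeset_id", "role", "gc_count") |>
    dplyr::inner_join(signals, by = "probe_id")

  bg5 <- oe |>
    dplyr::filter(.data$role == "MM") |>
    dplyr::group_by(.data$sample_id, .data$gc_count) |>
    dplyr::summarise(
      bg5 = quantile(.data$intensity, 0.05, type = 7, names = FALSE),
      .groups = "drop"
    )

  pm <- oe |>
    dplyr::filter(.data$role == "PM") |>
    dplyr::left_join(bg5, by = c("sample_id", "gc_count"))

  if (anyNA(pm$bg5)) {
    bad <- pm[is.na(pm$bg5), ]
    format_error(sprintf(
      "no background (MM) probes in GC bin %d for sample %s (probe %s)",
      bad$gc_count[1], bad$sample_id[1], bad$probe_id[1]
    ))
  }

  out <- pm |>
    dplyr::group_by(.data$probeset_id, .data$sample_id) |>
    dplyr::summarise(
      mean_corrected = mean(.data$intensity - .data$bg5),
      .groups = "drop"
    )

  guard <- out$mean_corrected + 100
  if (any(guard <= 0)) {
    bad <- out[which(guard <= 0)[1], ]
    format_error(sprintf(
      "probe set %s in sample %s has corrected mean + 100 <= 0 (%.4g); no finite log exists",
      bad$probeset_id, bad$sample_id, bad$mean_corrected + 100
    ))
  }

  out |>
    dplyr::mutate(value = log(.data$mean_corrected + 100)) |>
    dplyr::select("probeset_id", "sample_id", "value") |>
    dplyr::arrange(.data$probeset_id, .data$sample_id)
}

# ln of the per-class mean intensity for every SNP probe set x sample, before
# any slide centering; classes are probe roles (PM1/PM2/MM). Also the feature
# source for the LDA allele-assignment fallback.
snp_class_means <- function(signals, probes) {
  assert_columns(probes, c("probe_id", "probeset_id", "module", "role"))
  snp <- probes |>
    dplyr::filter(.data$module == "SNP") |>
    dplyr::select("probe_id", "probeset_id", "role") |>
    dplyr::inner_join(signals, by = "probe_id")

  snp |>
    dplyr::group_by(
      .data$probeset_id, .data$sample_id, .data$slide_id, .data$role
    ) |>
    dplyr::summarise(ln_mean = log(mean(.data$intensity)), .groups = "drop")
}

#' Normalize SNP probe sets to allele-specific log signals
#'
#' For each SNP probe set and hybridization, the mean intensity of the
#' reference-allele (st e), alternate-allele and mismatch probe classes is
#' taken, log-transformed (natural log), and centered by subtracting the
#' median over all SNP probe-set class values on that slide. Median centering
#' removes per-slide scale so slides are comparable; it leaves within-slide
#' allele ratios untouched.
#'
#' The slide median is taken, by default, over one value per SNP probe set:
#' the log of the probe set's mean intensity over all of its probes. Because
#' the total target quantity hybridizing to a probe set does not depend on
#' zygosity (a homozygote's two identical copies light one PM class up as
#' much as a heterozygote's two alleles light two), this median is invariant
#' to the allele composition of the genotype on the slide. Pooling the three
#' class values instead (`slide_median = "classes"`) makes the median track
#' how many classes carry signal, which differs between homozygous and
#' heterozygous hybridizations and would shift every cross-slide contrast;
#' it is provided for comparison only.
#'
#' The PM1/PM2 probe classes are mapped to `STE`/`ALLELE2` through the
#' per-probe-set consensus of an allele assignment table (see
#' [assign_alleles()] and [consensus_ste_probe()]); probe sets without a
#' consensus assignment are omitted.
#'
#' @param signals A signal table.
#' @param probes Probe annotation (SNP module rows are used).
#' @param samples Optional sample metadata to restrict samples.
#' @param assignments An allele assignment table, or a consensus map with
#'   columns `probeset_id`, `ste_probe`.
#' @param slide_median Source of the per-slide centering value:
#'   `"probeset"` (default; median over probe-set mean signals) or
#'   `"classes"` (median over all class values pooled).
#' @return A tibble (`AlleleSignal`): `probeset_id`, `sample_id`,
#'   `allele_class` in `STE`/`ALLELE2`/`MM`, `value` (centered natural-log
#'   scale).
#' @export
normalize_snp_probesets <- function(signals, probes, samples = NULL,
                                    assignments = NULL,
                                    slide_median = c("probeset", "classes")) {
  slide_median <- match.arg(slide_median)
  if (!is.null(samples)) {
    signals <- dplyr::semi_join(signals, samples, by = "sample_id")
  }
  cm <- snp_class_means(signals, probes)

  # every probe set must contribute all three classes on every array it is on
  n_class <- cm |>
    dplyr::count(.data$probeset_id, .data$sample_id)
  if (any(n_class$n < 3)) {
    bad <- n_class[n_class$n < 3, ][1, ]
    format_error(sprintf(
      "SNP probe set %s has a probe class with zero probes in sample %s",
      bad$probeset_id, bad$sample_id
    ))
  }

  med <- if (slide_median == "probeset") {
    probes |>
      dplyr::filter(.data$module == "SNP") |>
      dplyr::select("probe_id", "probeset_id") |>
      dplyr::inner_join(signals, by = "probe_id") |>
      dplyr::group_by(.data$slide_id, .data$probeset_id) |>
      dplyr::summarise(ln_mean = log(mean(.data$intensity)), .groups = "drop") |>
      dplyr::group_by(.data$slide_id) |>
      dplyr::summarise(m_slide = median(.data$ln_mean), .groups = "drop")
  } else {
    cm |>
      dplyr::group_by(.data$slide_id) |>
      dplyr::summarise(m_slide = median(.data$ln_mean), .groups = "drop")
  }

  centered <- cm |>
    dplyr::left_join(med, by = "slide_id") |>
    dplyr::mutate(value = .data$ln_mean - .data$m_slide)

  if (!is.null(assignments)) {
    cons <- if ("status" %in% names(assignments)) {
      consensus_ste_probe(assignments)
    } else {
      assignments
    }
    assert_columns(cons, c("probeset_id", "ste_probe"))
    centered <- centered |>
      dplyr::inner_join(cons, by = "probeset_id") |>
      dplyr::mutate(
        allele_class = dplyr::case_when(
          .data$role == "MM" ~ "MM",
          .data$role == .data$ste_probe ~ "STE",
          TRUE ~ "ALLELE2"
        )
      )
  } else {
    # unmapped classes keep their probe roles; downstream modelling requires
    # mapped classes, but the LDA path consumes this form
    centered <- dplyr::mutate(centered, allele_class = .data$role)
  }

  centered |>
    dplyr::select("probeset_id", "sample_id", "allele_class", "value") |>
    dplyr::arrange(.data$probeset_id, .data$sample_id, .data$allele_class)
}
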