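#' Assign SNP probes to parental alleles from sequence data
#'
#' For every cross (substitution line against the reference) and SNP probe
#' set where both parental bases are known, decides whether the probe set is
#' informative and which perfect-match probe interrogates the reference
#' (st e) allele:
#'
#' * parental bases identical: the cross is monomorphic at this SNP and the
#'   probe set is dropped (`NO_POLYMORPHISM`);
#' * the st e base matches one PM target and the line's base the other:
#'   assigned, with `ste_probe` recording the st e-matching probe;
#' * the st e base (or the line's base) matches no PM target -- the alleles
#'   are not represented on the array -- the probe set is dropped
#'   (`STE_MATCHES_NEITHER`).
#'
#' Pairs where either parental base is `"MISSING"` are not decidable from
#' sequence and are omitted here; [assign_alleles()] routes them to the
#' discriminant-analysis fallback.
#'
#' @param snps SNP genotype records: `probeset_id`, `line`, `allele_base`
#'   (with the reference line's rows under line `"ste"`).
#' @param probes Probe annotation; PM1/PM2 `target_base` defines each probe
#'   set's interrogated bases.
#' @return An assignment tibble: `probeset_id`, `line`, `status`
#'   (`ASSIGNED_SEQ`/`DROPPED`), `ste_probe` (`PM1`/`PM2` or `NA`),
#'   `drop_reason`.
#' @export
assign_from_sequence <- function(snps, probes) {
  assert_columns(snps, c("probeset_id", "line", "allele_base"))
  sets <- probeset_bases(probes)

  ste <- snps |>
    dplyr::filter(.data$line == ref_line) |>
    dplyr::select("probeset_id", ste_base = "allele_base")

  d <- snps |>
    dplyr::filter(.data$line != ref_line) |>
    dplyr::inner_join(ste, by = "probeset_id") |>
    dplyr::inner_join(sets, by = "probeset_id") |>
    dplyr::filter(.data$allele_base != "MISSING", .data$ste_base != "MISSING")

  ste_probe <- dplyr::case_when(
    d$ste_base == d$pm1_base & d$allele_base == d$pm2_base ~ "PM1",
    d$ste_base == d$pm2_base & d$allele_base == d$pm1_base ~ "PM2",
    TRUE ~ NA_character_
  )
  drop_reason <- dplyr::case_when(
    d$allele_base == d$ste_base ~ "NO_POLYMORPHISM",
    !is.na(ste_probe) ~ "none",
    TRUE ~ "STE_MATCHES_NEITHER"
  )

  tibble::tibble(
    probeset_id = d$probeset_id,
    line = d$line,
    status = as.character(ifelse(drop_reason == "none", "ASSIGNED_SEQ", "DROPPED")),
    ste_probe = as.character(ifelse(drop_reason == "none", ste_probe, NA_character_)),
    drop_reason = as.character(drop_reason)
  )
}

#' Infer probe-set informativeness by linear discriminant analysis
#'
#' Fallback for crosses lacking sequence data: a two-class linear discriminant
#' (equal priors, pooled covariance) is trained on the two parental
#' homozygotes' per-sample `(PM1, PM2)` log class means, and the probe set is
#' retained when the parents separate cleanly and the F1 behaves as a
#' heterozygote. Concretely the probe set is retained when leave-one-out
#' parental accuracy is 100% and either (a) the majority of F1 samples
#' project into the central band between the parental centroids
#' (`|projection - midpoint| <= 0.5 * band_factor * centroid distance`), or
#' (b) the parental projections are disjoint (both parents unambiguously
#' different homozygotes). The st e probe is the PM class with the larger
#' `PM1 - PM2` contrast in the st e parent relative to the other parent; an
#' exact tie is unresolvable and drops the probe set.
#'
#' @param train Parental training data: tibble with columns `parent` (two
#'   levels, one equal to `ste_parent`), `pm1`, `pm2` (log class means, one
#'   row per sample).
#' @param f1 F1 data: tibble with columns `pm1`, `pm2`.
#' @param ste_parent The `parent` level corresponding to the reference
#'   homozygote.
#' @param band_factor Width of the heterozygote band as a fraction of the
#'   inter-centroid distance (default 0.6).
#' @return A one-row assignment tibble (`status`, `ste_probe`,
#'   `drop_reason`) plus diagnostics `cv_accuracy` and `f1_in_band`.
#' @export
assign_by_lda <- function(train, f1, ste_parent, band_factor = 0.6) {
  assert_columns(train, c("parent", "pm1", "pm2"))
  assert_columns(f1, c("pm1", "pm2"))
  lv <- unique(train$parent)

  result <- function(status, ste_probe = NA_character_, drop_reason = "none",
                     cv_accuracy = NA_real_, f1_in_band = NA) {
    tibble::tibble(
      status = status, ste_probe = ste_probe, drop_reason = drop_reason,
      cv_accuracy = cv_accuracy, f1_in_band = f1_in_band
    )
  }

  if (length(lv) != 2 || !ste_parent %in% lv ||
    min(table(train$parent)) < 2) {
    return(result("DROPPED", drop_reason = "MISSING_DATA_UNRESOLVED"))
  }

  x <- as.matrix(train[, c("pm1", "pm2")])
  grp <- factor(train$parent, levels = lv)

  fit <- tryCatch(
    MASS::lda(x, grouping = grp, prior = c(0.5, 0.5)),
    error = function(e) NULL
  )
  cv <- tryCatch(
    MASS::lda(x, grouping = grp, prior = c(0.5, 0.5), CV = TRUE),
    error = function(e) NULL
  )
  if (is.null(fit) || is.null(cv)) {
    return(result("DROPPED", drop_reason = "LDA_UNRESOLVED"))
  }

  acc <- mean(cv$class == grp)
  proj <- drop(predict(fit)$x)
  centroids <- tapply(proj, grp, mean)
  ranges <- tapply(proj, grp, range)
  disjoint <- max(ranges[[1]]) < min(ranges[[2]]) ||
    max(ranges[[2]]) < min(ranges[[1]])

  f1_proj <- drop(predict(fit, as.matrix(f1[, c("pm1", "pm2")]))$x)
  mid <- mean(centroids)
  halfband <- 0.5 * abs(diff(centroids)) * band_factor
  f1_in_band <- length(f1_proj) > 0 &&
    mean(abs(f1_proj - mid) <= halfband) > 0.5

  retained <- acc == 1 && (f1_in_band || disjoint)
  if (!retained) {
    return(result("DROPPED",
      drop_reason = "LDA_UNRESOLVED",
      cv_accuracy = acc, f1_in_band = f1_in_band
    ))
  }

  # the st e-matching PM class shows the larger PM1 - PM2 contrast in the
  # st e parent than in the alternate parent
  d_contrast <- tapply(train$pm1 - train$pm2, grp, mean)
  d_ste <- d_contrast[[ste_parent]]
  d_other <- d_contrast[[setdiff(lv, ste_parent)]]
  if (d_ste == d_other) {
    return(result("DROPPED",
      drop_reason = "LDA_UNRESOLVED",
      cv_accuracy = acc, f1_in_band = f1_in_band
    ))
  }
  result(
    "ASSIGNED_LDA", ste_probe = if (d_ste > d_other) "PM1" else "PM2",
    cv_accuracy = acc, f1_in_band = f1_in_band
  )
}

#' Assign alleles for every cross and SNP probe set
#'
#' Orchestrates allele assignment: crosses with both parental bases in the
#' SNP table are decided from sequence ([assign_from_sequence()]); the rest
#' fall back to linear discriminant analysis on the parental homozygote RNA
#' hybridizations ([assign_by_lda()]), with the reference homozygote and the
#' line's X-substitution homozygote as training classes and the cross's F1
#' females as the putative heterozygotes.
#'
#' The substitution homozygote carries the line's allele only on the X, so
#' the LDA fallback is trainable for X-linked probe sets only: an autosomal
#' probe set with missing sequence has no allele2 homozygote anywhere in the
#' design, and both "parents" would present the identical reference profile.
#' When gene annotation is supplied (recommended), autosomal
#' missing-sequence pairs are therefore dropped as
#' `MISSING_DATA_UNRESOLVED` rather than handed to a discriminant that could
#' only separate the classes by noise. Pairs with insufficient parental
#' replication are likewise dropped as `MISSING_DATA_UNRESOLVED`.
#'
#' @param signals A signal table (needed for the LDA path; may be `NULL` if
#'   all pairs are sequence-decidable).
#' @param probes Probe annotation.
#' @param samples Sample metadata.
#' @param snps SNP genotype records.
#' @param genes Optional gene annotation (`gene_id`, `chromosome`); gates the
#'   LDA fallback to X-linked probe sets.
#' @param band_factor Heterozygote band width for the LDA rule.
#' @return The assignment tibble for all probe set-by-line pairs:
#'   `probeset_id`, `line`, `status`, `ste_probe`, `drop_reason`, and LDA
#'   diagnostics where applicable.
#' @export
assign_alleles <- function(signals, probes, samples, snps, genes = NULL,
                           band_factor = 0.6) {
  seq_assign <- assign_from_sequence(snps, probes)

  all_pairs <- tidyr::expand_grid(
    probeset_id = unique(probeset_bases(probes)$probeset_id),
    line = setdiff(unique(snps$line), ref_line)
  )
  pending <- dplyr::anti_join(
    all_pairs, seq_assign,
    by = c("probeset_id", "line")
  )

  unresolved <- function(pairs) {
    dplyr::mutate(
      pairs,
      status = "DROPPED", ste_probe = NA_character_,
      drop_reason = "MISSING_DATA_UNRESOLVED"
    )
  }

  dropped_auto <- NULL
  if (!is.null(genes) && nrow(pending) > 0) {
    x_sets <- probes |>
      dplyr::filter(.data$module == "SNP") |>
      dplyr::distinct(.data$probeset_id, .data$gene_id) |>
      dplyr::inner_join(genes, by = "gene_id") |>
      dplyr::filter(.data$chromosome == "X") |>
      dplyr::pull(.data$probeset_id)
    is_x <- pending$probeset_id %in% x_sets
    dropped_auto <- unresolved(pending[!is_x, ])
    pending <- pending[is_x, ]
  }

  if (nrow(pending) == 0) {
    return(
      dplyr::bind_rows(seq_assign, dropped_auto) |>
        dplyr::arrange(.data$probeset_id, .data$line)
    )
  }
  if (is.null(signals)) {
    return(
      dplyr::bind_rows(seq_assign, dropped_auto, unresolved(pending)) |>
        dplyr::arrange(.data$probeset_id, .data$line)
    )
  }

  # features: per-sample ln class means of the PM probes, for the relevant
  # RNA hybridizations only
  feat_samples <- samples |>
    dplyr::filter(
      .data$nucleic_acid == "RNA", .data$sex == "F",
      .data$cross_type %in% c("HOMO_STE", "HOMO_SUB", "F1")
    )
  cm <- snp_class_means(
    dplyr::semi_join(signals, feat_samples, by = "sample_id"), probes
  ) |>
    dplyr::filter(.data$role != "MM") |>
    dplyr::filter(.data$probeset_id %in% unique(pending$probeset_id)) |>
    tidyr::pivot_wider(
      id_cols = c("probeset_id", "sample_id"),
      names_from = "role", values_from = "ln_mean"
    ) |>
    dplyr::rename(pm1 = "PM1", pm2 = "PM2") |>
    dplyr::left_join(
      dplyr::select(feat_samples, "sample_id", "line", "cross_type"),
      by = "sample_id"
    )

  cm_split <- split(cm, cm$probeset_id)
  lda_one <- function(ps, ln) {
    rows <- cm_split[[ps]]
    if (is.null(rows)) {
      return(tibble::tibble(
        status = "DROPPED", ste_probe = NA_character_,
        drop_reason = "MISSING_DATA_UNRESOLVED",
        cv_accuracy = NA_real_, f1_in_band = NA
      ))
    }
    train <- rows |>
      dplyr::filter(
        (.data$cross_type == "HOMO_STE") |
          (.data$cross_type == "HOMO_SUB" & .data$line == ln)
      ) |>
      dplyr::mutate(parent = ifelse(.data$cross_type == "HOMO_STE", "ste", "sub"))
    f1 <- rows[rows$cross_type == "F1" & rows$line == ln, ]
    assign_by_lda(train, f1, ste_parent = "ste", band_factor = band_factor)
  }

  lda_assign <- pending |>
    dplyr::mutate(
      res = purrr::map2(.data$probeset_id, .data$line, lda_one)
    ) |>
    tidyr::unnest("res")

  dplyr::bind_rows(seq_assign, dropped_auto, lda_assign) |>
    dplyr::arrange(.data$probeset_id, .data$line)
}

#' Consensus st e probe per probe set
#'
#' Collapses an assignment table to a single st e-probe label per probe set:
#' sequence-based assignments dominate (the reference base is a fixed
#' property of the reference line, so they cannot disagree unless annotation
#' is inconsistent); otherwise the majority LDA assignment wins, with exact
#' ties dropping the probe set. Assigned lines whose label conflicts with the
#' consensus are demoted to `DROPPED`/`LDA_UNRESOLVED` in the companion
#' [harmonize_assignments()] view.
#'
#' @param assignments An assignment table from [assign_alleles()].
#' @return A tibble `probeset_id`, `ste_probe` for probe sets with a
#'   consensus.
#' @export
consensus_ste_probe <- function(assignments) {
  assigned <- assignments |>
    dplyr::filter(.data$status != "DROPPED", !is.na(.data$ste_probe))
  if (nrow(assigned) == 0) {
    return(tibble::tibble(probeset_id = character(), ste_probe = character()))
  }
  assigned |>
    dplyr::group_by(.data$probeset_id) |>
    dplyr::summarise(
      ste_probe = {
        seq_based <- .data$ste_probe[.data$status == "ASSIGNED_SEQ"]
        pool <- if (length(seq_based) > 0) seq_based else .data$ste_probe
        n1 <- sum(pool == "PM1")
        n2 <- sum(pool == "PM2")
        if (n1 == n2) NA_character_ else if (n1 > n2) "PM1" else "PM2"
      },
      .groups = "drop"
    ) |>
    dplyr::filter(!is.na(.data$ste_probe))
}

#' @rdname consensus_ste_probe
#' @export
harmonize_assignments <- function(assignments) {
  cons <- consensus_ste_probe(assignments)
  assignments |>
    dplyr::left_join(cons, by = "probeset_id", suffix = c("", "_consensus")) |>
    dplyr::mutate(
      conflict = .data$status != "DROPPED" &
        (is.na(.data$ste_probe_consensus) |
          .data$ste_probe != .data$ste_probe_consensus),
      status = ifelse(.data$conflict, "DROPPED", .data$status),
      drop_reason = ifelse(.data$conflict, "LDA_UNRESOLVED", .data$drop_reason),
      ste_probe = ifelse(.data$conflict, NA_character_, .data$ste_probe)
    ) |>
    dplyr::select(-"conflict", -"ste_probe_consensus")
}
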