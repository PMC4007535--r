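# Strict TSV readers/writers for the pipeline's interchange tables. All files
# are plain TSV with a header row; natural-log values throughout.

table_specs <- list(
  signals = list(
    cols = c(
      probe_id = "c", sample_id = "c", intensity = "d", slide_id = "c"
    ),
    key = c("probe_id", "sample_id")
  ),
  samples = list(
    cols = c(
      sample_id = "c", line = "c", cross_type = "c", sex = "c",
      nucleic_acid = "c", replicate = "i", slide_id = "c"
    ),
    key = "sample_id",
    enums = list(
      cross_type = c("F1", "XHET", "HOMO_SUB", "HOMO_STE"),
      sex = c("F", "M"), nucleic_acid = c("RNA", "DNA")
    )
  ),
  probes = list(
    cols = c(
      probe_id = "c", probeset_id = "c", gene_id = "c", module = "c",
      role = "c", gc_count = "i", offset = "i", strand = "c", target_base = "c"
    ),
    key = "probe_id",
    enums = list(
      module = c("EXPR3P", "SNP"), role = c("PM", "MM", "PM1", "PM2"),
      offset = c(-4L, 0L, 4L)
    )
  ),
  genes = list(
    cols = c(gene_id = "c", chromosome = "c"),
    key = "gene_id",
    enums = list(chromosome = c("X", "A"))
  ),
  snps = list(
    cols = c(probeset_id = "c", line = "c", allele_base = "c"),
    key = c("probeset_id", "line")
  ),
  truth = list(
    cols = c(
      gene_id = "c", line = "c", chromosome = "c", cis_effect_f = "d",
      cis_effect_m = "d", trans_effect_f = "d", trans_effect_m = "d",
      cistrans_effect = "d", sex_effect = "d", base_log = "d",
      testable_male_ase = "l"
    ),
    key = c("gene_id", "line")
  ),
  allele_signal = list(
    cols = c(
      probeset_id = "c", sample_id = "c", allele_class = "c", value = "d"
    ),
    key = c("probeset_id", "sample_id", "allele_class"),
    enums = list(allele_class = c("STE", "ALLELE2", "MM"))
  ),
  normalized_expression = list(
    cols = c(probeset_id = "c", sample_id = "c", value = "d"),
    key = c("probeset_id", "sample_id")
  ),
  assignments = list(
    cols = c(
      probeset_id = "c", line = "c", status = "c", ste_probe = "c",
      drop_reason = "c"
    ),
    key = c("probeset_id", "line"),
    enums = list(status = c("ASSIGNED_SEQ", "ASSIGNED_LDA", "DROPPED"))
  )
)

format_error <- function(msg, path = NULL) {
  if (!is.null(path)) msg <- sprintf("%s [file: %s]", msg, path)
  abort(msg, class = "asecis_format_error")
}

validate_table <- function(df, what, path = NULL) {
  spec <- table_specs[[what]]
  if (is.null(spec)) abort(sprintf("unknown table type '%s'", what))

  missing <- setdiff(names(spec$cols), names(df))
  if (length(missing) > 0) {
    format_error(sprintf(
      "%s table is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "",
      paste(missing, collapse = ", ")
    ), path)
  }
  df <- df[names(spec$cols)]

  if (!is.null(spec$key)) {
    dup <- duplicated(df[spec$key])
    if (any(dup)) {
      format_error(sprintf(
        "%s table has a duplicate (%s) key at row %d",
        what, paste(spec$key, collapse = ", "), which(dup)[1]
      ), path)
    }
  }
  for (col in names(spec$enums %||% list())) {
    bad <- !is.na(df[[col]]) & !(df[[col]] %in% spec$enums[[col]])
    if (any(bad)) {
      format_error(sprintf(
        "%s table has invalid %s '%s' at row %d",
        what, col, df[[col]][which(bad)[1]], which(bad)[1]
      ), path)
    }
  }
  if (what == "signals") {
    bad <- !is.finite(df$intensity) | df$intensity <= 0
    if (any(bad)) {
      format_error(sprintf(
        "signals table has non-positive intensity at row %d",
        which(bad)[1]
      ), path)
    }
  }
  if (what %in% c("allele_signal", "normalized_expression")) {
    bad <- !is.finite(df$value)
    if (any(bad)) {
      format_error(sprintf(
        "%s table has a non-finite value at row %d", what, which(bad)[1]
      ), path)
    }
  }
  tibble::as_tibble(df)
}

read_ase_table <- function(path, what) {
  if (!file.exists(path)) {
    format_error(sprintf("input file does not exist: %s", path))
  }
  spec <- table_specs[[what]]
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_guess()),
    progress = FALSE, show_col_types = FALSE, comment = "#"
  )
  # coerce declared types after presence check so the error names the column
  missing <- setdiff(names(spec$cols), names(df))
  if (length(missing) > 0) {
    format_error(sprintf(
      "%s table is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "",
      paste(missing, collapse = ", ")
    ), path)
  }
  for (nm in names(spec$cols)) {
    df[[nm]] <- switch(spec$cols[[nm]],
      c = as.character(df[[nm]]),
      d = as.numeric(df[[nm]]),
      i = as.integer(df[[nm]]),
      l = as.logical(df[[nm]])
    )
  }
  validate_table(df, what, path)
}

write_ase_table <- function(x, path, what) {
  x <- validate_table(x, what)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read and write the pipeline's TSV interchange tables
#'
#' Typed, strictly validated readers and writers for the tables the pipeline
#' exchanges: probe-level signals, sample metadata, probe and gene annotation,
#' per-line SNP genotypes, simulation truth, normalized allele-specific
#' signals, summarized 3' expression values, and allele assignments. A
#' malformed file (missing column, duplicate key, non-positive intensity,
#' out-of-vocabulary factor level) raises an `asecis_format_error` naming the
#' offending column or row.
#'
#' @param path Path to a TSV file.
#' @param x A tibble to write (validated against the same rules).
#' @return Readers return a validated tibble; writers return `path`
#'   invisibly.
#' @name ase_io
NULL

#' @rdname ase_io
#' @export
read_signal_table <- function(path) read_ase_table(path, "signals")
#' @rdname ase_io
#' @export
write_signal_table <- function(x, path) write_ase_table(x, path, "signals")
#' @rdname ase_io
#' @export
read_sample_table <- function(path) read_ase_table(path, "samples")
#' @rdname ase_io
#' @export
write_sample_table <- function(x, path) write_ase_table(x, path, "samples")
#' @rdname ase_io
#' @export
read_probe_table <- function(path) read_ase_table(path, "probes")
#' @rdname ase_io
#' @export
write_probe_table <- function(x, path) write_ase_table(x, path, "probes")
#' @rdname ase_io
#' @export
read_gene_table <- function(path) read_ase_table(path, "genes")
#' @rdname ase_io
#' @export
write_gene_table <- function(x, path) write_ase_table(x, path, "genes")
#' @rdname ase_io
#' @export
read_snp_table <- function(path) read_ase_table(path, "snps")
#' @rdname ase_io
#' @export
write_snp_table <- function(x, path) write_ase_table(x, path, "snps")
#' @rdname ase_io
#' @export
read_truth_table <- function(path) read_ase_table(path, "truth")
#' @rdname ase_io
#' @export
write_truth_table <- function(x, path) write_ase_table(x, path, "truth")
#' @rdname ase_io
#' @export
read_allele_signal <- function(path) read_ase_table(path, "allele_signal")
#' @rdname ase_io
#' @export
write_allele_signal <- function(x, path) write_ase_table(x, path, "allele_signal")
#' @rdname ase_io
#' @export
read_normalized_expression <- function(path) {
  read_ase_table(path, "normalized_expression")
}
#' @rdname ase_io
#' @export
write_normalized_expression <- function(x, path) {
  write_ase_table(x, path, "normalized_expression")
}
#' @rdname ase_io
#' @export
read_assignment_table <- function(path) read_ase_table(path, "assignments")
#' @rdname ase_io
#' @export
write_assignment_table <- function(x, path) {
  write_ase_table(x[names(table_specs$assignments$cols)], path, "assignments")
}
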