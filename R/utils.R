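# Internal helpers shared across modules.

#' @importFrom rlang .data abort warn .env
#' @importFrom stats quantile median rnorm runif pf pchisq p.adjust setNames
#' @importFrom utils head
NULL

# Round half away from zero (the convention used for displayed percentages and
# expected counts; base round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive a per-stage RNG seed from the global one so partial reruns of a stage
# reproduce the same draws. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  stages <- c(
    design = 11L, truth = 23L, signals = 37L, analysis = 53L,
    assignment = 71L
  )
  off <- stages[[stage]]
  (as.integer(seed) %% 1000003L) * 1009L + off
}

with_stage_seed <- function(seed, stage, code) {
  old <- get0(".Random.seed", globalenv(), mode = "integer", inherits = FALSE)
  set.seed(stage_seed(seed, stage))
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ), class = "asecis_format_error")
  }
  invisible(df)
}
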