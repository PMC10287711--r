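# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. `seed = NULL` evaluates as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_ <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_("'%s' must be a single finite number", name)
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    stop_("'%s' = %g is outside its allowed range", name, x)
  invisible(x)
}

# Validate a log2 intensity / expression matrix: numeric, unique non-empty
# row and column names. NA encodes a missing measurement (never zero).
validate_intensity_matrix <- function(m, what = "intensity matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop_("%s must be a numeric matrix", what)
  rn <- rownames(m); cn <- colnames(m)
  if (is.null(rn) || is.null(cn) || any(rn == "") || any(cn == ""))
    stop_("%s must have non-empty row (feature) and column (sample) names", what)
  if (anyDuplicated(rn))
    stop_("duplicate feature id(s) in %s: %s", what,
          paste(unique(rn[duplicated(rn)]), collapse = ", "))
  if (anyDuplicated(cn))
    stop_("duplicate sample id(s) in %s: %s", what,
          paste(unique(cn[duplicated(cn)]), collapse = ", "))
  invisible(m)
}

# Validate a sample design against an intensity matrix: one row per matrix
# column, keyed by `sample_id`.
validate_sample_design <- function(design, m = NULL) {
  if (!is.data.frame(design) || !"sample_id" %in% names(design))
    stop_("design must be a data.frame with a 'sample_id' column")
  if (anyDuplicated(design$sample_id))
    stop_("duplicate sample id(s) in design: %s",
          paste(unique(design$sample_id[duplicated(design$sample_id)]),
                collapse = ", "))
  if (!is.null(m)) {
    missing_in_matrix <- setdiff(design$sample_id, colnames(m))
    if (length(missing_in_matrix))
      stop_("design sample(s) absent from matrix: %s",
            paste(missing_in_matrix, collapse = ", "))
    missing_in_design <- setdiff(colnames(m), design$sample_id)
    if (length(missing_in_design))
      stop_("matrix sample(s) absent from design: %s",
            paste(missing_in_design, collapse = ", "))
  }
  invisible(design)
}
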