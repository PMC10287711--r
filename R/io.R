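# Readers and writers for the tabular formats the pipeline exchanges:
# tab-separated intensity/expression matrices, sample-design and clinical
# tables, GMT gene sets, and a YAML column-role configuration. One dialect
# throughout: tab delimiter, "." decimal point, "NA" as the missing token.

#' Construct a signature set
#'
#' An ordered set of unique gene/protein identifiers with a name, the object
#' that is derived, scored, permuted and reduced.
#'
#' @param name Single non-empty string.
#' @param members Character vector of unique identifiers. Identifiers are
#'   case-sensitive and matched exactly throughout the package.
#' @param description Optional free-text description (second GMT field).
#' @param allow_empty Permit an empty member list. Derivation operations can
#'   legitimately produce an empty set (e.g. an empty intersection); writing
#'   an empty set to GMT is still an error.
#' @return An object of class `signature_set`.
#' @export
signature_set <- function(name, members, description = "", allow_empty = FALSE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_("signature set name must be a single non-empty string")
  members <- as.character(members)
  if (!allow_empty && length(members) == 0L)
    stop_("signature set '%s' has no members", name)
  if (anyDuplicated(members))
    stop_("duplicate member(s) in signature set '%s': %s", name,
          paste(unique(members[duplicated(members)]), collapse = ", "))
  if (any(!nzchar(members)))
    stop_("signature set '%s' contains an empty member id", name)
  structure(list(name = name, description = description, members = members),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("Signature set '%s': %d member(s)\n", x$name, length(x$members)))
  if (length(x$members))
    cat(" ", paste(utils::head(x$members, 12L), collapse = ", "),
        if (length(x$members) > 12L) "..." else "", "\n")
  invisible(x)
}

#' @export
length.signature_set <- function(x) length(x$members)

#' Read an intensity matrix and its sample design
#'
#' The matrix file is tab-delimited text with the protein id in the first
#' column and sample ids in the header. Cells equal to `NA`, the empty string,
#' or anything non-numeric become missing values (an explicit state, distinct
#' from zero). The design file maps each sample id to factor levels
#' (subtype, oxygen, compartment, patient_id, replicate — whichever apply).
#'
#' @param matrix_path Path to the intensity TSV.
#' @param design_path Path to the design TSV (must contain `sample_id`).
#' @return A list with elements `matrix` (numeric matrix, proteins x samples)
#'   and `design` (data.frame).
#' @export
read_intensity_bundle <- function(matrix_path, design_path) {
  m <- read_matrix_tsv(matrix_path, what = "intensity matrix")
  design <- read.delim(design_path, sep = "\t", stringsAsFactors = FALSE,
                       check.names = FALSE, na.strings = c("NA", ""))
  design$sample_id <- as.character(design$sample_id)
  validate_sample_design(design, m)
  list(matrix = m, design = design)
}

# Shared matrix reader: first column = feature id, header = sample ids.
read_matrix_tsv <- function(path, what = "matrix") {
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L)
    stop_("%s file '%s' needs an id column plus at least one sample", what, path)
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop_("duplicate feature id(s) in '%s': %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- vapply(raw[-1L], function(col) {
    col[col %in% c("NA", "")] <- NA_character_
    suppressWarnings(as.numeric(col))
  }, numeric(nrow(raw)))
  if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, names(raw)[-1L]))
  rownames(vals) <- ids
  validate_intensity_matrix(vals, what = what)
  vals
}

#' Write an intensity matrix and sample design as TSV
#'
#' @param m Numeric matrix with feature row names and sample column names.
#' @param design Sample design data.frame (or `NULL` to skip).
#' @param matrix_path,design_path Output paths.
#' @param id_column Header name of the feature-id column.
#' @return Invisibly, `matrix_path`.
#' @export
write_intensity_bundle <- function(m, design = NULL, matrix_path,
                                   design_path = NULL, id_column = "protein_id") {
  validate_intensity_matrix(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  if (!is.null(design)) {
    if (is.null(design_path)) stop_("design given but no design_path")
    validate_sample_design(design)
    write.table(design, design_path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
  }
  invisible(matrix_path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Member order is
#' preserved; duplicate members within a line are rejected.
#'
#' @param path Path to the GMT file.
#' @return A list of [signature_set] objects, named by set name.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop_("GMT line %d has %d field(s); need name, description and >=1 member",
            i, length(fields))
    signature_set(fields[1L], fields[-(1:2)], description = fields[2L])
  })
  names(sets) <- vapply(sets, `[[`, character(1L), "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' Bit-exact round trip with [read_gmt()]: tab-separated, member order kept.
#'
#' @param sets A [signature_set] or a list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "signature_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    if (!inherits(s, "signature_set")) stop_("write_gmt expects signature_set objects")
    if (length(s$members) == 0L)
      stop_("cannot write empty signature set '%s' to GMT", s$name)
    if (anyDuplicated(s$members))
      stop_("duplicate member(s) in signature set '%s'", s$name)
    paste(c(s$name, if (nzchar(s$description)) s$description else "na",
            s$members), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a cohort for scoring and survival analysis
#'
#' Bundles a complete gene-level expression matrix (genes x patients) with
#' clinical covariates and the survival outcome. Expression must be complete
#' (collapse probes and handle missingness upstream); follow-up time must be
#' strictly positive and the event indicator 0/1 (1 = death from disease,
#' 0 = censored, including deaths from other causes).
#'
#' @param expression Numeric matrix, genes x patients, no missing values.
#' @param clinical Data.frame with one row per patient, containing the columns
#'   named by `id`, `time` and `event` plus any covariate/treatment columns.
#' @param id,time,event Column names in `clinical` holding the patient id,
#'   follow-up time (months) and event indicator.
#' @param covariates,treatments Character vectors naming clinical columns that
#'   play those roles (declared explicitly; no column-name guessing).
#' @return An object of class `cohort_data` with elements `expression`,
#'   `clinical`, `time`, `event`, `patient_ids`, `covariates`, `treatments`.
#' @export
cohort_data <- function(expression, clinical, id = "patient_id",
                        time = "time", event = "event",
                        covariates = character(), treatments = character()) {
  validate_intensity_matrix(expression, what = "expression matrix")
  if (anyNA(expression))
    stop_("cohort expression must be complete (no missing values)")
  for (col in c(id, time, event, covariates, treatments))
    if (!col %in% names(clinical))
      stop_("clinical table lacks declared column '%s'", col)
  pid <- as.character(clinical[[id]])
  if (anyDuplicated(pid))
    stop_("duplicate patient id(s): %s",
          paste(unique(pid[duplicated(pid)]), collapse = ", "))
  if (!setequal(pid, colnames(expression)))
    stop_("clinical patients and expression columns do not match")
  clinical <- clinical[match(colnames(expression), pid), , drop = FALSE]
  rownames(clinical) <- colnames(expression)
  tt <- as.numeric(clinical[[time]])
  ev <- as.numeric(clinical[[event]])
  if (anyNA(tt) || any(!is.finite(tt)) || any(tt <= 0))
    stop_("survival time must be finite and strictly positive")
  if (anyNA(ev) || !all(ev %in% c(0, 1)))
    stop_("event indicator must be 0/1")
  structure(list(expression = expression, clinical = clinical,
                 time = tt, event = as.integer(ev),
                 patient_ids = colnames(expression),
                 covariates = covariates, treatments = treatments),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("Cohort: %d patients, %d genes, %d events (%.1f%%)\n",
              ncol(x$expression), nrow(x$expression), sum(x$event),
              100 * mean(x$event)))
  if (length(x$covariates))
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  if (length(x$treatments))
    cat("  treatments:", paste(x$treatments, collapse = ", "), "\n")
  invisible(x)
}

#' Read a cohort bundle from TSV files plus a column-role configuration
#'
#' The configuration (YAML file or equivalent list) declares which clinical
#' columns hold the patient id, time and event, and which are covariates or
#' treatment flags; columns are never guessed from their names. An optional
#' probe map collapses probe-level expression to gene level by max probe
#' before assembly.
#'
#' @param expression_path Expression TSV (genes or probes x patients).
#' @param clinical_path Clinical TSV, one row per patient.
#' @param config Path to a YAML file, or a list, with entries
#'   `id`, `time`, `event` and optional `covariates`, `treatments`.
#' @param probe_map Optional data.frame with columns `probe_id`, `gene_id`
#'   passed to [collapse_probes_max()].
#' @return A [cohort_data] object.
#' @export
read_cohort_bundle <- function(expression_path, clinical_path, config,
                               probe_map = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("id", "time", "event"))
    if (is.null(config[[field]]))
      stop_("cohort config lacks required field '%s'", field)
  expr <- read_matrix_tsv(expression_path, what = "expression matrix")
  if (!is.null(probe_map)) expr <- collapse_probes_max(expr, probe_map)
  clinical <- read.delim(clinical_path, sep = "\t", stringsAsFactors = FALSE,
                         check.names = FALSE, na.strings = c("NA", ""))
  cohort_data(expr, clinical, id = config$id, time = config$time,
              event = config$event,
              covariates = as.character(config$covariates %||% character()),
              treatments = as.character(config$treatments %||% character()))
}

#' Write a cohort bundle as TSV files
#'
#' @param cohort A [cohort_data] object.
#' @param expression_path,clinical_path Output paths.
#' @return Invisibly, `expression_path`.
#' @export
write_cohort_bundle <- function(cohort, expression_path, clinical_path) {
  stopifnot(inherits(cohort, "cohort_data"))
  write_intensity_bundle(cohort$expression, matrix_path = expression_path,
                         id_column = "gene_id")
  write.table(cohort$clinical, clinical_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(expression_path)
}
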