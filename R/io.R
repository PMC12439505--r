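# Reading, cohort filtering and trace preprocessing.
#
# The canonical on-disk layout is a UTF-8 CSV with a header row and one row
# per recording: participant_id, visit, eye, diagnosis, age, sex, va_logmar,
# then the sample columns s0..s(n-1). A schema object declares the native
# sample count (255 for raw 150-ms traces at 1700 Hz, 256 once padded) and
# can remap metadata column names for externally produced files.

#' CSV schema for PERG cohort files
#'
#' @param n_samples Number of sample columns the file carries (255 raw or
#'   256 padded).
#' @param columns Named character vector mapping the canonical metadata
#'   fields to the file's column names; override entries to adapt foreign
#'   layouts.
#' @return Object of class `cohort_schema`.
#' @export
cohort_schema <- function(n_samples = 256L, columns = NULL) {
  canonical <- c(participant_id = "participant_id", visit = "visit",
                 eye = "eye", diagnosis = "diagnosis", age = "age",
                 sex = "sex", va_logmar = "va_logmar")
  if (!is.null(columns)) canonical[names(columns)] <- columns
  stopifnot(n_samples %in% c(255L, 256L))
  structure(list(n_samples = as.integer(n_samples), columns = canonical),
            class = "cohort_schema")
}

#' Read a cohort CSV
#'
#' Parses the canonical layout into a `perg_cohort`. Missing visual acuity
#' is preserved as `NA` (an empty field; zero is a valid logMAR value).
#' Traces are returned as stored -- apply [preprocess_cohort()] before
#' analysis.
#'
#' @param path CSV file.
#' @param schema A [cohort_schema()].
#' @return A `perg_cohort` whose sample matrix has `schema$n_samples`
#'   columns.
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  stopifnot(inherits(schema, "cohort_schema"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "", check.names = FALSE)
  for (field in names(schema$columns)) {
    col <- schema$columns[[field]]
    if (!col %in% names(raw)) {
      stop("cohort file is missing required column '", col, "'")
    }
  }
  sample_cols <- paste0("s", seq_len(schema$n_samples) - 1L)
  missing_s <- setdiff(sample_cols, names(raw))
  if (length(missing_s)) {
    stop("cohort file is missing sample column(s) ",
         paste(utils::head(missing_s, 3L), collapse = ", "),
         if (length(missing_s) > 3L) ", ..." else "",
         " (schema expects ", schema$n_samples, " samples)")
  }
  samples <- matrix(NA_real_, nrow(raw), schema$n_samples)
  for (j in seq_along(sample_cols)) {
    v <- raw[[sample_cols[j]]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad)) {
      stop("non-numeric sample value in column ", sample_cols[j],
           ", row ", bad[1L])
    }
    if (anyNA(num)) stop("missing sample value in column ", sample_cols[j])
    samples[, j] <- num
  }
  meta <- data.frame(
    participant_id = as.character(raw[[schema$columns[["participant_id"]]]]),
    visit = as.integer(raw[[schema$columns[["visit"]]]]),
    eye = as.character(raw[[schema$columns[["eye"]]]]),
    diagnosis = as.character(raw[[schema$columns[["diagnosis"]]]]),
    age = as.numeric(raw[[schema$columns[["age"]]]]),
    sex = as.character(raw[[schema$columns[["sex"]]]]),
    va_logmar = as.numeric(raw[[schema$columns[["va_logmar"]]]]))
  perg_cohort(meta, samples)
}

#' Cohort filtering rules
#'
#' Expresses the analytic-cohort restrictions: keep only the allowed
#' diagnosis labels, optionally drop recordings without a visual-acuity
#' measure, and optionally keep only each participant's first (minimum)
#' visit so samples stay independent.
#'
#' @param allowed_diagnoses Non-empty label set; default the analysis
#'   cohort: normal plus the macular-predominant IRDs.
#' @param first_visit_only,require_va Flags; both default `TRUE`.
#' @return Object of class `cohort_filter_rules`.
#' @export
cohort_filter_rules <- function(allowed_diagnoses = c("normal", "CRD", "MD",
                                                      "STGD"),
                                first_visit_only = TRUE, require_va = TRUE) {
  if (!length(allowed_diagnoses)) stop("allowed_diagnoses must be non-empty")
  structure(list(allowed_diagnoses = allowed_diagnoses,
                 first_visit_only = isTRUE(first_visit_only),
                 require_va = isTRUE(require_va)),
            class = "cohort_filter_rules")
}

#' Apply cohort filters
#'
#' @param cohort A `perg_cohort`.
#' @param rules A [cohort_filter_rules()].
#' @return The filtered `perg_cohort` (a subset of the input; applying the
#'   same rules twice is a no-op). An empty result triggers a warning, not
#'   an error.
#' @export
filter_cohort <- function(cohort, rules = cohort_filter_rules()) {
  stopifnot(inherits(cohort, "perg_cohort"),
            inherits(rules, "cohort_filter_rules"))
  keep <- cohort$meta$diagnosis %in% rules$allowed_diagnoses
  if (rules$require_va) keep <- keep & !is.na(cohort$meta$va_logmar)
  if (rules$first_visit_only) {
    first <- tapply(cohort$meta$visit, cohort$meta$participant_id, min)
    keep <- keep &
      cohort$meta$visit == first[cohort$meta$participant_id]
  }
  if (!any(keep)) warning("cohort filter removed every recording")
  perg_cohort(cohort$meta[keep, , drop = FALSE],
              cohort$samples[keep, , drop = FALSE],
              fs = cohort$fs, duration_ms = cohort$duration_ms)
}

#' Preprocess one raw trace to the 256-sample analysis form
#'
#' Subtracts the trace mean (zero-order detrend: DC offset only, no slope
#' is fitted or removed), then -- for native 255-sample traces (150 ms at
#' 1700 Hz) -- repeats the final detrended sample once so every trace has
#' dyadic length 256.
#'
#' @param x Numeric vector of raw samples.
#' @param native_length Declared raw length, 255 or 256; defaults to
#'   `length(x)`.
#' @return Numeric vector of exactly 256 samples.
#' @export
preprocess_trace <- function(x, native_length = length(x)) {
  if (length(x) != native_length) {
    stop("trace has ", length(x), " samples but native_length is ",
         native_length)
  }
  if (!native_length %in% c(255L, 256L)) {
    stop("native trace length must be 255 or 256, got ", native_length)
  }
  if (!all(is.finite(x))) stop("trace contains non-finite samples")
  x <- x - mean(x)
  if (native_length == 255L) x <- c(x, x[255L])
  x
}

#' Preprocess every trace in a cohort
#'
#' @param cohort A `perg_cohort` whose sample matrix has 255 or 256 columns.
#' @return The cohort with a detrended, padded 256-column sample matrix.
#' @export
preprocess_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "perg_cohort"))
  out <- t(apply(cohort$samples, 1L, preprocess_trace,
                 native_length = ncol(cohort$samples)))
  perg_cohort(cohort$meta, out, fs = cohort$fs,
              duration_ms = cohort$duration_ms)
}
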