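# Cohort data model: a validated patient-level table plus CSV I/O and
# stratification. All downstream stages consume this model.

.menopausal_levels <- c("pre", "post")
.diagnosis_levels  <- c("benign", "malignant")
.benign_histologies <- c("cystadenoma_fibroma", "endometriosis", "mature_teratoma",
                         "fibroma_thecoma", "functional_cyst", "other_benign")
.malignant_histologies <- c("eoc", "neoc", "metastatic")
.figo_levels  <- c("I", "II", "III", "IV", "not_applicable")
.grade_levels <- c("borderline", "g1", "g2", "g3", "not_applicable")

# canonical column order of the cohort CSV schema (documented in README)
.cohort_columns <- c("id", "age", "menopausal_status", "ca125_u_ml", "he4_pm",
                     "diagnosis", "histology_group", "figo_stage", "grade",
                     "subtype_tag", "haemolysis", "freeze_delay_gt_4h",
                     "fh_breast", "fh_ovarian", "smoking")
.flag_columns <- c("haemolysis", "freeze_delay_gt_4h", "fh_breast",
                   "fh_ovarian", "smoking")

#' Construct and validate a cohort
#'
#' A cohort is a `data.frame` (class `roma_cohort`) with one row per subject
#' and a fixed column schema: `id`, `age` (years), `menopausal_status`
#' (`"pre"`/`"post"`), `ca125_u_ml` (U/ml, equivalently kU/l), `he4_pm` (pM),
#' `diagnosis` (`"benign"`/`"malignant"`), `histology_group`, `figo_stage`,
#' `grade`, `subtype_tag`, and five optional 0/1 flags (`haemolysis`,
#' `freeze_delay_gt_4h`, `fh_breast`, `fh_ovarian`, `smoking`).
#'
#' Marker values, age, menopausal status and diagnosis are mandatory and
#' strictly validated (markers must be positive so their logarithms are
#' finite); the boolean covariates may be `NA`. FIGO stage and grade must be
#' `"not_applicable"` for every subject whose histology group is not `"eoc"`,
#' mirroring study tables that report stage and grade for epithelial ovarian
#' cancer only. Benign subjects must carry a benign histology group and
#' malignant subjects one of `eoc`, `neoc`, `metastatic`; borderline tumours
#' are represented as malignant with `grade = "borderline"`.
#'
#' @param df a data.frame with the schema columns (extra columns are dropped;
#'   missing flag columns are filled with `NA`).
#' @return a validated `roma_cohort` data.frame in canonical column order.
#' @export
as_cohort <- function(df) {
  stopifnot(is.data.frame(df))
  required <- setdiff(.cohort_columns, c(.flag_columns, "subtype_tag"))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  if (!("subtype_tag" %in% names(df))) df$subtype_tag <- NA_character_
  for (fc in .flag_columns) if (!(fc %in% names(df))) df[[fc]] <- NA_integer_
  df <- df[, .cohort_columns, drop = FALSE]

  df$id <- as.character(df$id)
  df$subtype_tag <- as.character(df$subtype_tag)
  for (col in c("age", "ca125_u_ml", "he4_pm")) df[[col]] <- as.numeric(df[[col]])
  for (fc in .flag_columns) df[[fc]] <- as.integer(df[[fc]])

  .validate_cohort(df)
  rownames(df) <- NULL
  class(df) <- c("roma_cohort", "data.frame")
  df
}

.fail_rows <- function(bad, what, df) {
  if (any(bad, na.rm = TRUE)) {
    idx <- which(bad)
    stop(sprintf("cohort validation error: %s for id(s) %s (row %s)", what,
                 paste(df$id[idx], collapse = ", "),
                 paste(idx, collapse = ", ")))
  }
}

.validate_cohort <- function(df) {
  if (anyDuplicated(df$id)) {
    stop("cohort validation error: duplicated id(s) ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  .fail_rows(is.na(df$age) | df$age <= 0, "age must be a positive number", df)
  .fail_rows(is.na(df$ca125_u_ml) | df$ca125_u_ml <= 0,
             "ca125_u_ml must be > 0", df)
  .fail_rows(is.na(df$he4_pm) | df$he4_pm <= 0, "he4_pm must be > 0", df)
  .fail_rows(!(df$menopausal_status %in% .menopausal_levels),
             "menopausal_status must be 'pre' or 'post'", df)
  .fail_rows(!(df$diagnosis %in% .diagnosis_levels),
             "diagnosis must be 'benign' or 'malignant'", df)
  .fail_rows(!(df$histology_group %in% c(.benign_histologies, .malignant_histologies)),
             "unknown histology_group", df)
  .fail_rows(df$diagnosis == "benign" & !(df$histology_group %in% .benign_histologies),
             "benign diagnosis requires a benign histology_group", df)
  .fail_rows(df$diagnosis == "malignant" & !(df$histology_group %in% .malignant_histologies),
             "malignant diagnosis requires histology_group eoc/neoc/metastatic", df)
  .fail_rows(!(df$figo_stage %in% .figo_levels), "unknown figo_stage", df)
  .fail_rows(!(df$grade %in% .grade_levels), "unknown grade", df)
  .fail_rows(df$histology_group != "eoc" &
               (df$figo_stage != "not_applicable" | df$grade != "not_applicable"),
             "figo_stage/grade must be not_applicable unless histology_group is eoc", df)
  for (fc in .flag_columns) {
    .fail_rows(!is.na(df[[fc]]) & !(df[[fc]] %in% c(0L, 1L)),
               sprintf("%s must be 0, 1 or NA", fc), df)
  }
  invisible(df)
}

#' Read a cohort from CSV
#'
#' Reads a comma-separated, UTF-8, headered file in the documented cohort
#' schema and returns a validated [as_cohort()] object. `figo_stage` and
#' `grade` use the token `"NA"` on disk for subjects where they do not apply;
#' this is mapped to `"not_applicable"` internally. Row order is preserved;
#' validation failures name the offending id and row.
#'
#' @param path path to an existing CSV file.
#' @param schema_version schema identifier; only `"1"` is defined.
#' @return a `roma_cohort` data.frame.
#' @seealso [write_cohort_csv()] for the lossless inverse.
#' @export
read_cohort_csv <- function(path, schema_version = "1") {
  if (!identical(schema_version, "1")) {
    stop("unknown cohort schema_version: ", schema_version)
  }
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = "character")
  for (col in c("figo_stage", "grade")) {
    if (col %in% names(df)) {
      df[[col]][is.na(df[[col]]) | df[[col]] == "NA"] <- "not_applicable"
    }
  }
  for (fc in .flag_columns) {
    if (fc %in% names(df)) df[[fc]] <- suppressWarnings(as.integer(df[[fc]]))
  }
  as_cohort(df)
}

#' Write a cohort to CSV
#'
#' Writes the canonical column order with deterministic formatting so that
#' `read_cohort_csv(write_cohort_csv(x))` is lossless. `"not_applicable"`
#' stage/grade values are rendered as the token `"NA"`; missing flags as
#' empty fields.
#'
#' @param cohort a validated `roma_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "roma_cohort"))
  out <- as.data.frame(cohort)
  for (col in c("figo_stage", "grade")) {
    out[[col]][out[[col]] == "not_applicable"] <- "NA"
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Stratify a cohort by a categorical key
#'
#' Partitions the cohort by one of `menopausal_status`, `diagnosis`,
#' `histology_group`, `figo_stage` or `grade`. The sub-cohorts are disjoint
#' and their union is the input (the partition property used throughout the
#' analysis pipeline, e.g. when sensitivity and specificity are computed in
#' pre- and post-menopausal women separately).
#'
#' @param cohort a `roma_cohort`.
#' @param key stratification column name.
#' @return a named list of `roma_cohort` objects, one per observed key level.
#' @export
stratify <- function(cohort, key = c("menopausal_status", "diagnosis",
                                     "histology_group", "figo_stage", "grade")) {
  key <- match.arg(key)
  stopifnot(inherits(cohort, "roma_cohort"))
  values <- unique(cohort[[key]])
  out <- lapply(values, function(v) {
    sub <- cohort[cohort[[key]] == v, , drop = FALSE]
    rownames(sub) <- NULL
    class(sub) <- c("roma_cohort", "data.frame")
    sub
  })
  stats::setNames(out, values)
}

#' @export
print.roma_cohort <- function(x, n = 6L, ...) {
  n_b <- sum(x$diagnosis == "benign")
  n_m <- sum(x$diagnosis == "malignant")
  cat(sprintf("<roma_cohort> %d subjects (%d benign, %d malignant)\n",
              nrow(x), n_b, n_m))
  print(utils::head(as.data.frame(x), n), ...)
  if (nrow(x) > n) cat(sprintf("# ... %d more subjects\n", nrow(x) - n))
  invisible(x)
}
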