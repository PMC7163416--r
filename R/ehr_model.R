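#' @useDynLib ldltraj, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

lab_analytes <- function() c("TC", "HDL", "TG", "LDL_direct", "eGFR")

ehr_table_names <- function() {
  c("patients", "labs", "diagnoses", "prescriptions", "bp", "smoking")
}

# column types per table, used both for reading and validation
ehr_schemas <- function() {
  list(
    patients = list(
      required = c("patient_id", "sex", "birth_date"),
      cols = readr::cols(
        patient_id = readr::col_character(),
        sex = readr::col_character(),
        birth_date = readr::col_date()
      )
    ),
    labs = list(
      required = c("patient_id", "date", "analyte", "value"),
      cols = readr::cols(
        patient_id = readr::col_character(),
        date = readr::col_date(),
        analyte = readr::col_character(),
        value = readr::col_double()
      )
    ),
    diagnoses = list(
      required = c("patient_id", "date", "code", "category"),
      cols = readr::cols(
        patient_id = readr::col_character(),
        date = readr::col_date(),
        code = readr::col_character(),
        category = readr::col_character()
      )
    ),
    prescriptions = list(
      required = c("patient_id", "registration_date", "atc_code",
                   "drug_name", "daily_dose_mg"),
      cols = readr::cols(
        patient_id = readr::col_character(),
        registration_date = readr::col_date(),
        atc_code = readr::col_character(),
        drug_name = readr::col_character(),
        daily_dose_mg = readr::col_double()
      )
    ),
    bp = list(
      required = c("patient_id", "date", "systolic", "diastolic"),
      cols = readr::cols(
        patient_id = readr::col_character(),
        date = readr::col_date(),
        systolic = readr::col_double(),
        diastolic = readr::col_double()
      )
    ),
    smoking = list(
      required = c("patient_id", "date", "smoking_current"),
      cols = readr::cols(
        patient_id = readr::col_character(),
        date = readr::col_date(),
        smoking_current = readr::col_logical()
      )
    )
  )
}

# row-level checks; each returns the reason for the FIRST rule a row violates,
# so every rejected row carries exactly one reason
ehr_row_checks <- function(name, df, code_map) {
  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    ifelse(is.na(reason) & bad, why, reason)
  }
  if (name == "patients") {
    reason <- flag(is.na(df$patient_id) | df$patient_id == "",
                   "missing patient_id")
    reason <- flag(!df$sex %in% c("female", "male"), "sex not female/male")
    reason <- flag(is.na(df$birth_date), "unparseable birth_date")
    dup <- duplicated(df$patient_id)
    reason <- ifelse(is.na(reason) & dup, "duplicate patient_id", reason)
  } else if (name == "labs") {
    reason <- flag(is.na(df$patient_id) | df$patient_id == "",
                   "missing patient_id")
    reason <- flag(is.na(df$date), "unparseable date")
    if (any(!df$analyte %in% lab_analytes())) {
      bad <- unique(df$analyte[!df$analyte %in% lab_analytes()])
      stop("labs: unknown analyte(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    reason <- flag(is.na(df$value) | df$value < 0, "negative or missing value")
  } else if (name == "diagnoses") {
    reason <- flag(is.na(df$patient_id) | df$patient_id == "",
                   "missing patient_id")
    reason <- flag(is.na(df$date), "unparseable date")
    reason <- flag(!df$category %in% diagnosis_categories(),
                   "unknown category")
    if (!is.null(code_map)) {
      mapped <- code_map$category[match(df$code, code_map$code)]
      reason <- ifelse(is.na(reason) & !is.na(mapped) &
                         mapped != df$category,
                       "code/category disagree with code map", reason)
    }
  } else if (name == "prescriptions") {
    reason <- flag(is.na(df$patient_id) | df$patient_id == "",
                   "missing patient_id")
    reason <- flag(is.na(df$registration_date),
                   "unparseable registration_date")
    reason <- flag(is.na(df$atc_code) | df$atc_code == "", "empty atc_code")
    statin <- startsWith(df$atc_code, "C10AA")
    bad_dose <- statin & (is.na(df$daily_dose_mg) | df$daily_dose_mg <= 0)
    bad_dose[is.na(bad_dose)] <- FALSE
    reason <- ifelse(is.na(reason) & bad_dose,
                     "statin row without positive daily_dose_mg", reason)
    nonpos <- !is.na(df$daily_dose_mg) & df$daily_dose_mg <= 0
    reason <- ifelse(is.na(reason) & nonpos,
                     "non-positive daily_dose_mg", reason)
  } else if (name == "bp") {
    reason <- flag(is.na(df$patient_id) | df$patient_id == "",
                   "missing patient_id")
    reason <- flag(is.na(df$date), "unparseable date")
    reason <- flag(is.na(df$systolic) | is.na(df$diastolic) |
                     df$diastolic <= 0 | df$systolic <= df$diastolic,
                   "requires systolic > diastolic > 0")
  } else if (name == "smoking") {
    reason <- flag(is.na(df$patient_id) | df$patient_id == "",
                   "missing patient_id")
    reason <- flag(is.na(df$date), "unparseable date")
    reason <- flag(is.na(df$smoking_current), "missing smoking_current")
  }
  reason
}

#' Validate one EHR table against its schema
#'
#' @param df Data frame to validate.
#' @param name Table name, one of [ehr_table_names()].
#' @param code_map Optional diagnosis code map ([cvd_code_map()]) used to
#'   cross-check diagnosis rows.
#' @return The validated tibble (invisibly unchanged).
#' @export
validate_table <- function(df, name, code_map = NULL) {
  name <- match.arg(name, ehr_table_names())
  schema <- ehr_schemas()[[name]]
  missing_cols <- setdiff(schema$required, names(df))
  if (length(missing_cols) > 0) {
    stop(name, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)[schema$required]
  if (nrow(df) == 0) return(df)
  reason <- ehr_row_checks(name, df, code_map)
  if (any(!is.na(reason))) {
    bad <- which(!is.na(reason))
    # +1 for the header row: report file line numbers
    msg <- paste0("line ", bad[seq_len(min(5, length(bad)))] + 1L, ": ",
                  reason[bad[seq_len(min(5, length(bad)))]])
    stop(name, ": ", length(bad), " invalid row(s)\n  ",
         paste(msg, collapse = "\n  "), call. = FALSE)
  }
  df
}

#' Read and validate the EHR input tables
#'
#' Expects one CSV per entity (comma-delimited, header row, ISO-8601 dates):
#' `patients.csv`, `labs.csv`, `diagnoses.csv`, `prescriptions.csv`, and
#' optionally `bp.csv` and `smoking.csv`. Labs are long format; a lipid panel
#' is assembled later by grouping on (patient_id, date).
#'
#' @param dir Directory containing the CSV files, or a named list/vector of
#'   explicit per-table paths.
#' @param code_map Diagnosis code map used for cross-checks
#'   (default [cvd_code_map()]).
#' @return Named list of validated tibbles with a `row_counts` attribute.
#' @export
read_tables <- function(dir, code_map = cvd_code_map()) {
  if (is.list(dir) || (is.character(dir) && !is.null(names(dir)))) {
    paths <- dir
  } else {
    paths <- file.path(dir, paste0(ehr_table_names(), ".csv"))
    names(paths) <- ehr_table_names()
    paths <- paths[file.exists(unlist(paths))]
  }
  required <- c("patients", "labs", "diagnoses", "prescriptions")
  missing <- setdiff(required, names(paths))
  if (length(missing) > 0) {
    stop("Missing input table(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tables <- lapply(names(paths), function(nm) {
    schema <- ehr_schemas()[[nm]]
    # col_types mismatches surface below as schema errors; readr's own
    # warning about them is redundant
    df <- suppressWarnings(readr::read_csv(paths[[nm]],
                                           col_types = schema$cols,
                                           progress = FALSE))
    probs <- readr::problems(df)
    if (nrow(probs) > 0) {
      stop(nm, ": unparseable field(s), first at line ", probs$row[1] + 1L,
           " (", probs$col[1], ")", call. = FALSE)
    }
    validate_table(df, nm, code_map = code_map)
  })
  names(tables) <- names(paths)
  attr(tables, "row_counts") <- vapply(tables, nrow, integer(1))
  tables
}

#' Write EHR tables as canonical CSV
#'
#' Columns follow the schema order; rows are sorted by patient_id, then date
#' (then remaining columns for full determinism), and dates serialize as
#' ISO 8601 so that write -> read -> write is byte-identical.
#'
#' @param tables Named list of tables (any subset of [ehr_table_names()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the vector of files written.
#' @export
write_tables <- function(tables, out_dir) {
  stopifnot(all(names(tables) %in% ehr_table_names()))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("Cannot create ", out_dir, call. = FALSE)
  written <- character(0)
  for (nm in intersect(ehr_table_names(), names(tables))) {
    schema <- ehr_schemas()[[nm]]
    df <- tibble::as_tibble(tables[[nm]])[schema$required]
    df <- dplyr::arrange(df, dplyr::across(dplyr::everything()))
    path <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(df, path, progress = FALSE)
    written <- c(written, path)
  }
  invisible(written)
}
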