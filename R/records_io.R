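# Admission-record data model: CSV reading/writing, validation, and the
# packaged worked-example class counts.

#' Canonical admission-record columns
#'
#' Every admission record is one hospitalization: identifiers, admission and
#' discharge dates, the casemix variables a national in-hospital mortality
#' model adjusts for (age, sex, admission type, length of stay, discharge
#' year, socio-economic deprivation, comorbidity band, diagnostic group), and
#' the in-hospital death flag.
#'
#' @format A character vector of column names, in CSV order.
#' @export
admission_columns <- c(
  "record_id", "patient_id", "hospital_id", "admission_date",
  "discharge_date", "age_years", "sex", "emergency", "los_days",
  "discharge_year", "deprivation", "charlson_band", "ccs_group", "died"
)

#' Category levels used throughout the package
#'
#' `charlson_levels` are the banded Charlson comorbidity categories;
#' `ccs_levels` the default diagnostic (CCS-style) groups; `freq_levels` the
#' admission-frequency class labels shared by the patient view P(m) and the
#' admission view A(n).
#'
#' @name category-levels
#' @export
charlson_levels <- c("0", "1", "2-3", "4-6")

#' @rdname category-levels
#' @export
ccs_levels <- c(
  "neoplasms", "metabolic & shock", "heart disease",
  "respiratory disease", "gastro-intestinal disease", "other"
)

#' @rdname category-levels
#' @export
freq_levels <- c("1", "2", "3", "4", "5,6", "7-9", "10-20", ">20")

#' Read admission records from CSV
#'
#' Reads the flat admission-record table (header row with the columns of
#' [admission_columns], booleans coded 0/1, ISO-8601 dates) and validates it.
#' In strict mode (default) any invariant violation aborts with the offending
#' `record_id`; in lenient mode violating rows are dropped and a summary of
#' the drops is attached as attribute `"dropped"` and reported via a message.
#'
#' @param path path to a CSV file.
#' @param strict abort on the first invariant violation (`TRUE`, default) or
#'   drop violating rows (`FALSE`).
#' @return A `data.frame` of validated admission records with typed columns
#'   (`Date` dates, logical `emergency`/`died`, factor `sex`, `charlson_band`,
#'   `ccs_group`).
#' @seealso [write_admissions()], [validate_admissions()]
#' @export
read_admissions <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(admission_columns, names(raw))
  if (length(missing)) {
    abort("missing column(s): ", paste(missing, collapse = ", "))
  }
  raw <- raw[admission_columns]
  if (nrow(raw) == 0) {
    return(validate_admissions(coerce_admissions(raw), strict = strict))
  }
  rec <- coerce_admissions(raw)
  validate_admissions(rec, strict = strict)
}

# Zero-row admission-record frame with the canonical column types.
empty_admissions <- function() {
  data.frame(
    record_id = character(0), patient_id = character(0),
    hospital_id = character(0),
    admission_date = as.Date(character(0)),
    discharge_date = as.Date(character(0)),
    age_years = integer(0),
    sex = factor(character(0), levels = c("male", "female")),
    emergency = logical(0), los_days = integer(0),
    discharge_year = integer(0), deprivation = integer(0),
    charlson_band = factor(character(0), levels = charlson_levels),
    ccs_group = factor(character(0)), died = logical(0),
    stringsAsFactors = FALSE
  )
}

# Type the character columns read from CSV; unparseable dates abort.
coerce_admissions <- function(raw) {
  parse_date <- function(x, what) {
    d <- as.Date(x, format = "%Y-%m-%d")
    bad <- is.na(d) & !is.na(x) & nzchar(x)
    if (any(bad)) {
      abort("unparseable ", what, " for record_id ",
            paste(utils::head(raw$record_id[bad], 3), collapse = ", "))
    }
    d
  }
  data.frame(
    record_id = raw$record_id,
    patient_id = raw$patient_id,
    hospital_id = raw$hospital_id,
    admission_date = parse_date(raw$admission_date, "admission_date"),
    discharge_date = parse_date(raw$discharge_date, "discharge_date"),
    age_years = as.integer(raw$age_years),
    sex = factor(raw$sex, levels = c("male", "female")),
    emergency = as.integer(raw$emergency) == 1L,
    los_days = as.integer(raw$los_days),
    discharge_year = as.integer(raw$discharge_year),
    deprivation = as.integer(raw$deprivation),
    charlson_band = factor(raw$charlson_band, levels = charlson_levels),
    ccs_group = factor(raw$ccs_group),
    died = as.integer(raw$died) == 1L,
    stringsAsFactors = FALSE
  )
}

#' Validate admission records
#'
#' Checks the record invariants: unique `record_id`; `discharge_date >=
#' admission_date`; `los_days <= (discharge - admission) + 1` with `los_days
#' = 0` permitted only for same-day stays (day cases); `discharge_year`
#' consistent with `discharge_date`; non-negative age; deprivation in 1..5;
#' known sex and Charlson band; no missing death flag.
#'
#' @param records a data.frame of admission records.
#' @param strict abort on violation (`TRUE`) or drop violating rows (`FALSE`).
#' @return The validated (possibly filtered) records. In lenient mode the
#'   attribute `"dropped"` holds a data.frame of `record_id` and reason.
#' @export
validate_admissions <- function(records, strict = TRUE) {
  n <- nrow(records)
  if (n == 0) return(records)
  bad <- character(0); why <- character(0)
  flag <- function(idx, reason) {
    if (any(idx, na.rm = TRUE)) {
      idx[is.na(idx)] <- TRUE
      bad <<- c(bad, records$record_id[idx])
      why <<- c(why, rep(reason, sum(idx)))
    }
  }
  dup <- duplicated(records$record_id)
  flag(dup, "duplicate record_id")
  flag(records$discharge_date < records$admission_date,
       "discharge_date before admission_date")
  span <- as.integer(records$discharge_date - records$admission_date)
  flag(records$los_days < 0 | records$los_days > span + 1L,
       "los_days inconsistent with dates")
  flag(records$los_days == 0L & span > 0L,
       "los_days = 0 on a multi-day stay")
  flag(records$discharge_year !=
         as.integer(format(records$discharge_date, "%Y")),
       "discharge_year does not match discharge_date")
  flag(records$age_years < 0L, "negative age_years")
  flag(!(records$deprivation %in% 1:5), "deprivation outside 1..5")
  flag(is.na(records$sex), "unknown sex")
  flag(is.na(records$charlson_band), "unknown charlson_band")
  flag(is.na(records$ccs_group) | !nzchar(as.character(records$ccs_group)),
       "missing ccs_group")
  flag(is.na(records$died), "missing died flag")

  if (!length(bad)) return(records)
  if (strict) {
    abort("invalid admission record(s): ",
          paste(unique(paste0(bad, " (", why, ")"))[
            seq_len(min(5, length(unique(bad))))], collapse = "; "))
  }
  drop <- records$record_id %in% bad
  reasons <- tapply(why, bad, function(r) paste(unique(r), collapse = "; "))
  report <- data.frame(record_id = names(reasons),
                       reason = as.character(reasons),
                       stringsAsFactors = FALSE)
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- report
  message(sum(drop), " invalid record(s) dropped (see attr 'dropped')")
  out
}

#' Write admission records to CSV
#'
#' Inverse of [read_admissions()]: ISO dates, 0/1 booleans, header row. A
#' write/read round trip is the identity on valid records, and writing the
#' same records twice is byte-stable.
#'
#' @param records validated admission records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_admissions <- function(records, path) {
  out <- records
  out$admission_date <- format(out$admission_date, "%Y-%m-%d")
  out$discharge_date <- format(out$discharge_date, "%Y-%m-%d")
  out$sex <- as.character(out$sex)
  out$emergency <- as.integer(out$emergency)
  out$charlson_band <- as.character(out$charlson_band)
  out$ccs_group <- as.character(out$ccs_group)
  out$died <- as.integer(out$died)
  ok <- tryCatch({
    utils::write.csv(out[admission_columns], path, row.names = FALSE,
                     quote = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort("cannot write to ", path)
  invisible(path)
}

#' Worked-example class counts
#'
#' Per-class counts transcribed from the published five-year cohort of six
#' Dutch teaching hospitals (240662 patients, 418566 admissions, 15227
#' observed and 16379 model-predicted deaths): number of patients (patient
#' view only), admissions, observed in-hospital deaths and casemix-model
#' predicted deaths for each admission-frequency class, plus a Total row.
#' These counts drive the worked-example replay ([run_worked_example()]).
#'
#' @param view `"patient"` for the mutually exclusive P(m) classes or
#'   `"admission"` for the overlapping A(n) classes.
#' @return A data.frame with columns `class`, `n_patients` (`NA` in the
#'   admission view), `n_admissions`, `observed_deaths`, `predicted_deaths`;
#'   the final row is the Total row. The `view` is attached as an attribute.
#' @export
worked_example_counts <- function(view = c("patient", "admission")) {
  view <- match.arg(view)
  file <- system.file("extdata",
                      paste0("worked_example_", view, "_view.csv"),
                      package = "hsmradjust", mustWork = TRUE)
  tab <- utils::read.csv(file, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!"n_patients" %in% names(tab)) tab$n_patients <- NA_integer_
  tab <- tab[c("class", "n_patients", "n_admissions", "observed_deaths",
               "predicted_deaths")]
  body <- tab[tab$class != "Total", ]
  tot <- tab[tab$class == "Total", ]
  if (nrow(tot) != 1 || !setequal(body$class, freq_levels)) {
    abort("worked-example fixture corrupt: unexpected class labels")
  }
  # printed totals must agree with the column sums up to printing rounding
  for (col in c("n_patients", "n_admissions", "observed_deaths",
                "predicted_deaths")) {
    s <- sum(body[[col]]); t <- tot[[col]]
    if (!is.na(t) && !is.na(s) && abs(s - t) > nrow(body) / 2) {
      abort("worked-example fixture corrupt: ", col,
            " total inconsistent with column sum")
    }
  }
  structure(tab, view = view)
}

#' Worked-example published SMR table
#'
#' Transcription of the per-class standardised mortality ratios and 95%
#' confidence limits printed for the same cohort as
#' [worked_example_counts()], used for the per-cell comparison in
#' [run_worked_example()].
#'
#' @return A data.frame with columns `view`, `class`, `smr`, `ci_low`,
#'   `ci_high`.
#' @export
worked_example_smr_reference <- function() {
  file <- system.file("extdata", "worked_example_smr_reference.csv",
                      package = "hsmradjust", mustWork = TRUE)
  utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
}
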