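# Linking admissions into per-patient histories, numbering the n-th
# admission, and building the patient-view / admission-view class tables.

#' Admission-frequency class of a count
#'
#' Bins an admission count into the fixed frequency classes used by both the
#' patient view P(m) and the admission view A(n): 1, 2, 3, 4 singly, then
#' 5-6, 7-9, 10-20 and >20 grouped to preserve power in the tails.
#'
#' @param n integer vector of admission counts (or ordinals), all >= 1.
#' @return A factor with levels [freq_levels].
#' @examples
#' freq_class(c(1, 8, 20, 21))
#' @export
freq_class <- function(n) {
  if (any(is.na(n)) || any(n < 1) || any(n != floor(n))) {
    abort("admission counts must be integers >= 1")
  }
  lab <- ifelse(n <= 4, as.character(n),
         ifelse(n <= 6, "5,6",
         ifelse(n <= 9, "7-9",
         ifelse(n <= 20, "10-20", ">20"))))
  factor(lab, levels = freq_levels)
}

#' Link admissions into patient histories and number the n-th admission
#'
#' Orders each patient's records by (discharge date, admission date,
#' record id) — discharge date is the primary key, the remaining components
#' only break exact ties deterministically — then assigns the ordinal `nth`
#' (1..m) and the admission frequency `m` (total in-window admissions of the
#' patient). `patient_id` is taken as a global identifier.
#'
#' A record following an in-hospital death of the same patient is impossible
#' under in-hospital-death semantics and raises an error (`strict = TRUE`) or
#' a warning; exact ordering-key ties within a patient are treated the same
#' way since numbering would be arbitrary.
#'
#' @param records validated admission records.
#' @param strict error (default) or warn on post-mortem admissions and exact
#'   within-patient ordering ties.
#' @return The records, re-ordered by patient and discharge, with columns
#'   `nth`, `m` and `freq_class` (class of `m`) appended.
#' @seealso [patient_histories()], [class_table()]
#' @export
link_admissions <- function(records, strict = TRUE) {
  n <- nrow(records)
  if (n == 0) {
    records$nth <- integer(0); records$m <- integer(0)
    records$freq_class <- factor(character(0), levels = freq_levels)
    return(records)
  }
  ord <- order(records$patient_id, records$discharge_date,
               records$admission_date, records$record_id, method = "radix")
  rec <- records[ord, , drop = FALSE]
  pid <- rec$patient_id
  new_pat <- c(TRUE, pid[-1] != pid[-n])
  sizes <- diff(c(which(new_pat), n + 1L))
  rec$nth <- sequence(sizes)
  rec$m <- rep(sizes, sizes)

  key_tie <- c(FALSE, !new_pat[-1] &
                 rec$discharge_date[-1] == rec$discharge_date[-n] &
                 rec$admission_date[-1] == rec$admission_date[-n] &
                 rec$record_id[-1] == rec$record_id[-n])
  notify <- if (strict) abort else warning
  if (any(key_tie)) {
    notify("exact ordering-key tie within patient ",
           paste(unique(pid[key_tie])[1:min(3, sum(key_tie))],
                 collapse = ", "))
  }
  postmortem <- rec$died & rec$nth < rec$m
  if (any(postmortem)) {
    notify("admission after in-hospital death for patient ",
           paste(unique(pid[postmortem])[
             seq_len(min(3, length(unique(pid[postmortem]))))],
             collapse = ", "))
  }
  rec$freq_class <- freq_class(rec$m)
  rownames(rec) <- NULL
  rec
}

#' Summarise linked records into one row per patient
#'
#' @param linked records carrying `nth`/`m` from [link_admissions()].
#' @return A data.frame with one row per patient: `patient_id`,
#'   `hospital_id` (of the last admission), `m`, `freq_class`,
#'   `first_discharge`, `last_discharge` and `died` (in-window death flag).
#' @export
patient_histories <- function(linked) {
  last <- linked[linked$nth == linked$m, , drop = FALSE]
  first <- linked[linked$nth == 1L, , drop = FALSE]
  first <- first[match(last$patient_id, first$patient_id), , drop = FALSE]
  out <- data.frame(
    patient_id = last$patient_id,
    hospital_id = last$hospital_id,
    m = last$m,
    freq_class = last$freq_class,
    first_discharge = first$discharge_date,
    last_discharge = last$discharge_date,
    died = last$died,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Per-class count table for the patient or admission view
#'
#' Patient view: class of `m` partitions patients; all m admissions of a
#' patient fall in the class of m. Admission view: class of the ordinal `nth`;
#' a patient with m admissions contributes one record to every A(n) with
#' n <= m. If a per-record predicted risk column is present its per-class sums
#' are reported as `expected_deaths`.
#'
#' @param linked records carrying `nth`/`m` from [link_admissions()].
#' @param view `"patient"` or `"admission"`.
#' @param risk_col name of an optional per-record predicted-risk column.
#' @return A data.frame with one row per class (all eight classes always
#'   present): `class`, `n_patients` (`NA` for the admission view),
#'   `n_admissions`, `observed_deaths`, and `expected_deaths` when available.
#' @export
class_table <- function(linked, view = c("patient", "admission"),
                        risk_col = "risk") {
  view <- match.arg(view)
  cls <- if (view == "patient") freq_class(pmax(linked$m, 1L))
         else freq_class(pmax(linked$nth, 1L))
  if (nrow(linked) == 0) cls <- factor(character(0), levels = freq_levels)
  n_adm <- as.integer(table(cls))
  obs <- as.integer(tapply(linked$died, cls, sum, default = 0L))
  out <- data.frame(
    class = factor(freq_levels, levels = freq_levels),
    n_patients = NA_integer_,
    n_admissions = n_adm,
    observed_deaths = obs,
    stringsAsFactors = FALSE
  )
  if (view == "patient") {
    lastrec <- linked$nth == linked$m
    out$n_patients <- as.integer(table(cls[lastrec]))
  }
  if (risk_col %in% names(linked)) {
    out$expected_deaths <-
      as.numeric(tapply(linked[[risk_col]], cls, sum, default = 0))
  }
  attr(out, "view") <- view
  out
}

#' Elapsed time between first and last discharge of readmitted patients
#'
#' For patients admitted at least twice, the shares whose first-to-last
#' discharge span is below one and below three years: a diagnostic for how
#' much of the patient view a fixed study window captures (histories
#' straddling the window are truncated, never corrected).
#'
#' @param histories per-patient summaries from [patient_histories()].
#' @return A list with `n_multi` (patients with m >= 2), `share_lt_1y` and
#'   `share_lt_3y` (both `NA` when `n_multi` is 0).
#' @export
elapsed_time_summary <- function(histories) {
  multi <- histories[histories$m >= 2L, , drop = FALSE]
  if (nrow(multi) == 0) {
    return(list(n_multi = 0L, share_lt_1y = NA_real_,
                share_lt_3y = NA_real_))
  }
  span <- as.numeric(multi$last_discharge - multi$first_discharge)
  list(
    n_multi = nrow(multi),
    share_lt_1y = mean(span < 365),
    share_lt_3y = mean(span < 3 * 365)
  )
}
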