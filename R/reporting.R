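# Report generation: the fixture-driven worked example and the end-to-end
# pipeline runner.

#' Replay the published worked example
#'
#' Computes per-class SMRs with confidence limits from the packaged
#' worked-example class counts ([worked_example_counts()]) for both views,
#' along with crude mortality per patient and per admission, and compares
#' every computed SMR/CI cell against the transcribed published table.
#'
#' Recomputation uses the *printed* (rounded) expected-death integers, which
#' reproduces the published patient-view SMRs exactly at one decimal except
#' the sparsest class (>20), where the printed 34.9 reflects unrounded
#' denominators (recomputation gives 35.0); admission-view cells can deviate
#' by a few tenths for the same reason. The comparison tolerances encode
#' this: 0.05 for patient-view SMRs (0.2 for the >20 class) and 0.5
#' elsewhere.
#'
#' @param level confidence level.
#' @param method CI method (the default Byar limits reproduce the published
#'   intervals).
#' @return An object of class `worked_example`: `patient` and `admission`
#'   SMR tables, `crude` rates per class, `overall` HSMR, and `comparison`
#'   (per-cell computed vs published values with pass flags).
#' @export
run_worked_example <- function(level = 0.95, method = "byar") {
  pt_counts <- worked_example_counts("patient")
  at_counts <- worked_example_counts("admission")
  pt <- class_smr_table(pt_counts, level, method)
  at <- class_smr_table(at_counts, level, method)

  body <- pt_counts[pt_counts$class != "Total", ]
  crude <- data.frame(
    class = body$class,
    per_patient = 100 * body$observed_deaths / body$n_patients,
    per_admission = 100 * body$observed_deaths / body$n_admissions,
    stringsAsFactors = FALSE
  )
  tot <- pt_counts[pt_counts$class == "Total", ]
  crude <- rbind(crude, data.frame(
    class = "Total",
    per_patient = 100 * tot$observed_deaths / tot$n_patients,
    per_admission = 100 * tot$observed_deaths / tot$n_admissions))

  ref <- worked_example_smr_reference()
  comp <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i) {
    r <- ref[i, ]
    tab <- if (r$view == "patient") pt else at
    row <- tab[tab$group == r$class, ]
    tol_smr <- if (r$view == "patient") {
      if (r$class == ">20") 0.2 else 0.05
    } else 0.5
    data.frame(
      view = r$view, class = r$class,
      smr = round_half_up(row$smr, 1), smr_published = r$smr,
      ci_low = round_half_up(row$ci_low, 1), ci_low_published = r$ci_low,
      ci_high = round_half_up(row$ci_high, 1), ci_high_published = r$ci_high,
      pass = abs(round_half_up(row$smr, 1) - r$smr) <= tol_smr &
        abs(round_half_up(row$ci_low, 1) - r$ci_low) <= 0.5 &
        abs(round_half_up(row$ci_high, 1) - r$ci_high) <= 0.5,
      stringsAsFactors = FALSE)
  }))
  structure(list(
    patient = pt, admission = at, crude = crude,
    overall = pt$smr[pt$group == "Overall"],
    comparison = comp
  ), class = "worked_example")
}

#' @export
print.worked_example <- function(x, ...) {
  cat(sprintf("Worked example: overall HSMR %.1f\n\n",
              round_half_up(x$overall, 1)))
  cat("Patient view:\n"); print(x$patient)
  cat("\nAdmission view:\n"); print(x$admission)
  cat("\nCrude mortality (%):\n")
  y <- x$crude
  y$per_patient <- round_half_up(y$per_patient, 1)
  y$per_admission <- round_half_up(y$per_admission, 2)
  print(y, row.names = FALSE)
  cat(sprintf("\nComparison against the published table: %d/%d cells pass\n",
              sum(x$comparison$pass), nrow(x$comparison)))
  invisible(x)
}

#' Run the full synthetic pipeline and write a report bundle
#'
#' generate -> link -> fit -> SMR by both views -> frequency adjustment ->
#' audit, writing every intermediate artifact as CSV (full precision, with a
#' Total row on count tables) plus a short text summary. Byte-identical for
#' a fixed configuration and seed.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @param seed generator seed.
#' @param level,method CI level and method.
#' @return Invisibly, a list with the [fallacy_demo()] report, the audit and
#'   the paths written.
#' @export
run_pipeline <- function(config, out_dir, seed = config$seed,
                         level = 0.95, method = "byar") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  cohort <- generate_cohort(config, seed = seed)
  write_admissions(cohort, path("admissions.csv"))
  if (!nrow(cohort)) {
    writeLines("empty cohort: no records inside the study window",
               path("report.txt"))
    return(invisible(list(empty = TRUE,
                          paths = path(c("admissions.csv", "report.txt")))))
  }
  linked <- link_admissions(cohort)
  histories <- patient_histories(linked)
  utils::write.csv(histories, path("histories.csv"), row.names = FALSE)

  report <- fallacy_demo(config, seed = seed, level = level, method = method)
  linked$risk <- predict(report$base_model, linked)

  write_tab <- function(tab, file) {
    utils::write.csv(as.data.frame(tab), path(file), row.names = FALSE)
  }
  ct_p <- class_table(linked, "patient")
  ct_a <- class_table(linked, "admission")
  write_tab(with_total(ct_p, c("n_patients", "n_admissions",
                               "observed_deaths", "expected_deaths")),
            "class_table_patient.csv")
  write_tab(with_total(ct_a, c("n_admissions", "observed_deaths",
                               "expected_deaths")),
            "class_table_admission.csv")
  write_tab(report$patient_unadjusted, "smr_patient.csv")
  write_tab(report$admission_unadjusted, "smr_admission.csv")
  write_tab(report$patient_adjusted, "smr_patient_adjusted.csv")

  audit <- frequency_overcount_audit(linked)
  write_tab(audit$exceeders, "overcount_exceeders.csv")

  et <- elapsed_time_summary(histories)
  g <- report$gradient
  summary_lines <- c(
    sprintf("patients: %d, admissions: %d, deaths: %d",
            report$n_patients, report$n_records, sum(linked$died)),
    sprintf("overall HSMR: unadjusted %.1f, adjusted %.1f",
            report$overall["unadjusted"], report$overall["adjusted"]),
    sprintf("patient-view gradient: rho %.2f p %.4f (unadjusted) -> rho %.2f p %.4f (adjusted)",
            g$patient_unadjusted$rho, g$patient_unadjusted$p_value,
            g$patient_adjusted$rho, g$patient_adjusted$p_value),
    sprintf("gradient flags: unadjusted %s, adjusted %s",
            g$patient_unadjusted$p_value < 0.05,
            g$patient_adjusted$p_value < 0.05),
    sprintf("multi-admission patients: %d; span < 1y: %.3f, < 3y: %.3f",
            et$n_multi, et$share_lt_1y, et$share_lt_3y),
    sprintf("patients contributing > 1 expected death: %d (%.1f expected vs %d observed)",
            audit$n_exceeders, audit$expected_total, audit$observed_total)
  )
  writeLines(summary_lines, path("report.txt"))
  invisible(list(report = report, audit = audit, elapsed = et,
                 paths = path(c("admissions.csv", "histories.csv",
                                "class_table_patient.csv",
                                "class_table_admission.csv",
                                "smr_patient.csv", "smr_admission.csv",
                                "smr_patient_adjusted.csv",
                                "overcount_exceeders.csv", "report.txt"))))
}
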