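# Shared fixture builders: hand-made admission records and degenerate
# generator configurations with a single casemix cell, used to test the
# mechanism knobs one at a time.

make_record <- function(record_id, patient_id, admission, discharge,
                        died = FALSE, hospital_id = "H1", age = 70,
                        sex = "male", emergency = FALSE, los = NULL,
                        deprivation = 3L, charlson = "0", ccs = "other") {
  adm <- as.Date(admission); dis <- as.Date(discharge)
  if (is.null(los)) los <- as.integer(dis - adm)
  data.frame(
    record_id = record_id, patient_id = patient_id,
    hospital_id = hospital_id,
    admission_date = adm, discharge_date = dis,
    age_years = as.integer(age),
    sex = factor(sex, levels = c("male", "female")),
    emergency = emergency, los_days = as.integer(los),
    discharge_year = as.integer(format(dis, "%Y")),
    deprivation = as.integer(deprivation),
    charlson_band = factor(charlson, levels = charlson_levels),
    ccs_group = factor(ccs, levels = ccs_levels),
    died = died,
    stringsAsFactors = FALSE
  )
}

make_records <- function(...) do.call(rbind, list(...))

# A hospital whose casemix is one single cell (fixed age, no emergency, one
# diagnostic group, Charlson 0), so per-admission risk is exactly the
# baseline logit.
flat_profile <- function(n_patients, class_weights = c(1, rep(0, 7)),
                         gap_mean_days = c(0, 470, 200, 130, 88, 55, 30, 29)) {
  one_ccs <- matrix(0, 6, 8, dimnames = list(ccs_levels, NULL))
  one_ccs["other", ] <- 1
  one_charlson <- matrix(0, 4, 8, dimnames = list(charlson_levels, NULL))
  one_charlson["0", ] <- 1
  hospital_profile(
    "flat", n_patients, freq_class_weights = class_weights,
    gap_mean_days = gap_mean_days,
    casemix = list(
      age_mean = rep(65, 8), age_sd = 0,
      ccs_probs = one_ccs, charlson_probs = one_charlson,
      emergency_frac = rep(0, 8), los_mean = rep(3, 8),
      primary_ccs_mix = 1
    )
  )
}

flat_config <- function(n_patients, p = 0.054, theta = 0,
                        class_weights = c(1, rep(0, 7)),
                        margin_years = 0, ...) {
  cohort_config(
    list(flat_profile(n_patients, class_weights)),
    margin_years = margin_years, frailty_theta = theta,
    baseline_logit = qlogis(p),
    covariate_effects = list(
      age_per_decade = 0, female = 0, emergency = 0, deprivation = 0,
      charlson = c("0" = 0, "1" = 0, "2-3" = 0, "4-6" = 0)
    ),
    ...
  )
}

# The generator's true per-record model, for parameter-recovery checks: the
# exact functional form sim risk is computed from.
generator_truth_formula <- function() {
  died ~ ccs_group + I((age_years - 65) / 10) + sex + emergency +
    I(deprivation - 3) + charlson_band
}

generator_truth_coef <- function(config) {
  bl <- config$baseline_logit
  eff <- config$covariate_effects
  ccs <- names(bl)
  c(
    "(Intercept)" = unname(bl[ccs[1]]),
    stats::setNames(unname(bl[ccs[-1]] - bl[ccs[1]]),
                    paste0("ccs_group", ccs[-1])),
    "I((age_years - 65)/10)" = eff$age_per_decade,
    "sexfemale" = eff$female,
    "emergencyTRUE" = eff$emergency,
    "I(deprivation - 3)" = eff$deprivation,
    stats::setNames(unname(eff$charlson[-1] - eff$charlson[1]),
                    paste0("charlson_band", names(eff$charlson)[-1]))
  )
}
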