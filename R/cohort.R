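# Synthetic admission-record cohorts with the statistical structure the
# readmission-bias analysis assumes: per-hospital admission-frequency
# distributions, casemix drift across the n-th admission, in-hospital death
# terminating a patient's admission sequence, and a tunable latent
# per-admission risk reduction for frequently admitted patients that the
# casemix variables do not fully capture.

# m-class internals ---------------------------------------------------------

class_index <- function(n) as.integer(freq_class(n))

# Candidate admission frequencies per class. Composite classes draw uniformly;
# the open-ended class draws from a geometric tail truncated to 21..60 so
# extreme frequencies exist but stay bounded (mean ~ 33).
freq_class_values <- function(tail_rate = 0.06) {
  vals <- list(1L, 2L, 3L, 4L, 5:6, 7:9, 10:20, 21:60)
  w <- lapply(vals, function(v) rep(1 / length(v), length(v)))
  g <- (1 - tail_rate)^(seq_along(vals[[8]]) - 1)
  w[[8]] <- g / sum(g)
  list(values = vals, within = w,
       mean_m = vapply(seq_along(vals),
                       function(i) sum(vals[[i]] * w[[i]]), numeric(1)))
}

# Default casemix trajectory over the eight ordinal (n-th admission) classes:
# average age, Charlson-band mix, diagnostic-group mix, emergency fraction and
# mean length of stay, shaped like the published six-hospital profile (age
# peaking around the 4th admission, comorbidity rising, heart disease giving
# way to neoplasms, emergency share and length of stay falling).
default_casemix_trajectory <- function() {
  ccs <- rbind(
    neoplasms                    = c(13, 20, 25, 31, 40, 52, 65, 72),
    `metabolic & shock`          = c( 4,  5,  6,  7,  8,  9, 12, 14),
    `heart disease`              = c(40, 34, 29, 25, 20, 13,  7,  2),
    `respiratory disease`        = c(11, 11, 12, 12, 11,  9,  6,  3),
    `gastro-intestinal disease`  = c(13, 10,  9,  8,  6,  4,  3,  2),
    other                        = c(21, 19, 19, 17, 15, 12,  8,  6)
  ) / 100
  charlson <- rbind(
    `0`   = c(68, 65, 60, 55, 49, 42, 37, 31),
    `1`   = c(20, 17, 16, 15, 13, 10,  6,  4),
    `2-3` = c(10, 17, 22, 27, 35, 45, 54, 60),
    `4-6` = c( 2,  2,  2,  3,  3,  3,  4,  5)
  ) / 100
  list(
    age_mean = c(61.2, 64.7, 65.5, 65.5, 64.8, 63.7, 62.4, 59.0),
    age_sd = 16,
    ccs_probs = ccs,
    charlson_probs = charlson,
    emergency_frac = c(0.43, 0.37, 0.39, 0.37, 0.34, 0.28, 0.18, 0.07),
    los_mean = c(6.8, 7.2, 7.0, 6.5, 6.0, 5.0, 3.4, 1.8),
    primary_ccs_mix = 0.7
  )
}

#' Hospital generator profile
#'
#' Describes one hospital's synthetic population: number of patients, the
#' distribution of *admissions* over the eight frequency classes (shares of a
#' hospital's admissions, as registry profiles are printed, not shares of
#' patients), inter-admission gap scales, and the casemix trajectory over the
#' n-th admission.
#'
#' The default class weights are the pooled six-hospital admission shares
#' (39.4, 20.0, 11.0, 6.8, 7.8, 5.5, 6.3, 3.3 percent for classes
#' 1, 2, 3, 4, 5-6, 7-9, 10-20, >20).
#'
#' @param hospital_id label.
#' @param n_patients number of patients to simulate.
#' @param freq_class_weights admission shares over the eight classes; need not
#'   be normalised, must be non-negative.
#' @param gap_mean_days mean inter-admission gap (days) per frequency class of
#'   the patient; defaults place high-frequency patients plausibly inside a
#'   five-year window (mean first-to-last span about 2.5 years for m > 20).
#' @param casemix list of trajectory overrides (see
#'   `default_casemix_trajectory` entries: `age_mean`, `age_sd`, `ccs_probs`,
#'   `charlson_probs`, `emergency_frac`, `los_mean`, `primary_ccs_mix`).
#' @param freq_tail_rate geometric decay rate of the >20-class tail.
#' @return An object of class `hospital_profile`.
#' @export
hospital_profile <- function(hospital_id, n_patients,
                             freq_class_weights = c(39.4, 20.0, 11.0, 6.8,
                                                    7.8, 5.5, 6.3, 3.3),
                             gap_mean_days = c(0, 470, 200, 130, 88,
                                               55, 30, 29),
                             casemix = list(),
                             freq_tail_rate = 0.06) {
  if (length(freq_class_weights) != 8 || any(freq_class_weights < 0) ||
      sum(freq_class_weights) <= 0) {
    abort("freq_class_weights must be 8 non-negative shares")
  }
  if (n_patients < 0) abort("n_patients must be >= 0")
  cm <- utils::modifyList(default_casemix_trajectory(), casemix)
  stopifnot(length(cm$age_mean) == 8, length(cm$emergency_frac) == 8,
            length(cm$los_mean) == 8, ncol(cm$ccs_probs) == 8,
            ncol(cm$charlson_probs) == 8)
  structure(list(
    hospital_id = hospital_id,
    n_patients = as.integer(n_patients),
    freq_class_weights = freq_class_weights / sum(freq_class_weights),
    gap_mean_days = gap_mean_days,
    casemix = cm,
    classes = freq_class_values(freq_tail_rate)
  ), class = "hospital_profile")
}

#' Cohort generator configuration
#'
#' Bundles the hospitals, the study window, the truncation margin, the
#' per-admission risk model the generator simulates from, and the strength of
#' the latent frailty/selection mechanism.
#'
#' The generator's per-admission death probability is
#' `plogis(lp - frailty_theta * log(m))` where `lp` is the casemix linear
#' predictor (diagnostic-group intercept plus covariate effects) and `m` the
#' patient's total planned admission frequency. `frailty_theta = 0` gives a
#' cohort whose per-admission risk depends on casemix only; positive values
#' encode mechanisms (split admissions, chemotherapy schedules, referrals)
#' that lower the real per-admission risk of frequently admitted patients
#' without being visible to the casemix model. An in-hospital death always
#' ends the patient's admission sequence.
#'
#' @param hospitals list of [hospital_profile()] objects.
#' @param window_start,window_end study window (ISO dates); records are kept
#'   by discharge date.
#' @param margin_years horizon padding on each side of the window; histories
#'   are placed on the padded horizon and records discharged outside the
#'   window are dropped, emulating registry truncation. `0` disables
#'   truncation entirely.
#' @param frailty_theta latent risk-reduction strength per unit `log(m)`;
#'   `>= 0`.
#' @param baseline_logit named per-diagnostic-group intercepts (logit of the
#'   death probability at the reference casemix: age 65, male, non-emergency,
#'   deprivation 3, Charlson band 0), or a single number recycled to all
#'   groups.
#' @param covariate_effects list of logit-scale effects: `age_per_decade`,
#'   `female`, `emergency`, `deprivation` (per category above 3), `charlson`
#'   (named vector over [charlson_levels]).
#' @param seed default seed used by [generate_cohort()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(hospitals = list(hospital_profile("A", 10000L)),
                          window_start = "2003-01-01",
                          window_end = "2007-12-31",
                          margin_years = 1,
                          frailty_theta = 0.1,
                          baseline_logit = c(
                            "neoplasms" = -4.00,
                            "metabolic & shock" = -3.55,
                            "heart disease" = -3.75,
                            "respiratory disease" = -3.65,
                            "gastro-intestinal disease" = -4.00,
                            "other" = -4.50),
                          covariate_effects = list(),
                          seed = 1L) {
  if (inherits(hospitals, "hospital_profile")) hospitals <- list(hospitals)
  ws <- as.Date(window_start); we <- as.Date(window_end)
  if (!(ws < we)) abort("window_start must precede window_end")
  if (frailty_theta < 0) abort("frailty_theta must be >= 0")
  if (margin_years < 0) abort("margin_years must be >= 0")
  eff <- utils::modifyList(list(
    age_per_decade = 0.5,
    female = -0.1,
    emergency = 0.8,
    deprivation = 0.05,
    charlson = c("0" = 0, "1" = 0.3, "2-3" = 0.7, "4-6" = 1.2)
  ), covariate_effects)
  ccs_names <- rownames(hospitals[[1]]$casemix$ccs_probs)
  if (length(baseline_logit) == 1 && is.null(names(baseline_logit))) {
    baseline_logit <- stats::setNames(rep(baseline_logit, length(ccs_names)),
                                      ccs_names)
  }
  if (!all(ccs_names %in% names(baseline_logit))) {
    abort("baseline_logit must name every diagnostic group")
  }
  structure(list(
    hospitals = hospitals, window_start = ws, window_end = we,
    margin_years = margin_years, frailty_theta = frailty_theta,
    baseline_logit = baseline_logit, covariate_effects = eff,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Sample planned admission frequencies
#'
#' Draws per-patient admission frequencies m so that the induced distribution
#' of *admissions* over the eight frequency classes matches the profile's
#' class weights in expectation: patient-level class probabilities are the
#' admission shares divided by the class mean frequency, renormalised. Within
#' a composite class the frequency is uniform (5-6, 7-9, 10-20) or
#' truncated-geometric (>20).
#'
#' Uses the current RNG stream; seed with `set.seed()` for reproducibility.
#'
#' @param profile a [hospital_profile()].
#' @param n number of patients to draw.
#' @return Integer vector of length `n`, all values >= 1.
#' @export
sample_admission_frequency <- function(profile, n = 1L) {
  cl <- profile$classes
  pat_w <- profile$freq_class_weights / cl$mean_m
  pat_w <- pat_w / sum(pat_w)
  ci <- sample.int(8L, n, replace = TRUE, prob = pat_w)
  out <- integer(n)
  for (k in seq_len(8L)) {
    sel <- ci == k
    if (!any(sel)) next
    v <- cl$values[[k]]
    out[sel] <- if (length(v) == 1L) v else
      v[sample.int(length(v), sum(sel), replace = TRUE,
                   prob = cl$within[[k]])]
  }
  out
}

# Vectorised simulation of complete (pre-truncation) histories for patients
# with planned frequencies M. Returns per-record columns plus day offsets
# relative to an arbitrary origin. A death draw at any admission ends the
# history there, so the realised frequency can fall short of the planned one.
sim_histories <- function(M, profile, config, first_offset = NULL,
                          id_prefix = profile$hospital_id) {
  N <- length(M)
  cm <- profile$casemix
  eff <- config$covariate_effects
  ci <- class_index(M)
  if (is.null(first_offset)) first_offset <- rep(0, N)

  sex <- factor(ifelse(stats::runif(N) < 0.5, "female", "male"),
                levels = c("male", "female"))
  deprivation <- sample.int(5L, N, replace = TRUE)
  base_age <- pmin(100L, pmax(18L, as.integer(round(
    stats::rnorm(N, cm$age_mean[ci], cm$age_sd)))))
  ccs_lv <- rownames(cm$ccs_probs)
  primary_ccs <- integer(N)
  for (k in seq_len(8L)) {
    sel <- ci == k
    if (any(sel)) {
      primary_ccs[sel] <- sample.int(length(ccs_lv), sum(sel),
                                     replace = TRUE,
                                     prob = cm$ccs_probs[, k])
    }
  }

  idx <- rep.int(seq_len(N), M)
  total <- length(idx)
  nth <- sequence(M)
  oc <- class_index(nth)
  first_idx <- which(nth == 1L)

  los <- stats::rpois(total, cm$los_mean[oc])
  gap <- ifelse(nth == 1L, 0,
                pmax(1, round(stats::rexp(total) *
                                profile$gap_mean_days[ci[idx]])))
  los_prev <- c(0L, los[-total]); los_prev[nth == 1L] <- 0L
  step <- ifelse(nth == 1L, 0, gap + los_prev + 1)
  tcum <- cumsum(step)
  adm_off <- tcum - rep(tcum[first_idx], M) + first_offset[idx]
  dis_off <- adm_off + los

  draw_by_class <- function(probs, levels_out) {
    out <- integer(total)
    for (k in seq_len(8L)) {
      sel <- oc == k
      if (any(sel)) {
        out[sel] <- sample.int(nrow(probs), sum(sel), replace = TRUE,
                               prob = probs[, k])
      }
    }
    factor(levels_out[out], levels = levels_out)
  }
  charlson <- draw_by_class(cm$charlson_probs, rownames(cm$charlson_probs))
  ccs_draw <- draw_by_class(cm$ccs_probs, ccs_lv)
  use_primary <- stats::runif(total) < cm$primary_ccs_mix
  ccs <- ifelse(use_primary, ccs_lv[primary_ccs[idx]],
                as.character(ccs_draw))
  ccs <- factor(ccs, levels = ccs_lv)
  emergency <- stats::runif(total) < cm$emergency_frac[oc]
  age <- pmin(100L, base_age[idx] +
                as.integer((adm_off - first_offset[idx]) %/% 365))

  lp <- config$baseline_logit[as.character(ccs)] +
    eff$age_per_decade * (age - 65) / 10 +
    eff$female * (sex[idx] == "female") +
    eff$emergency * emergency +
    eff$deprivation * (deprivation[idx] - 3) +
    eff$charlson[as.character(charlson)] -
    config$frailty_theta * log(M[idx])
  death <- stats::runif(total) < stats::plogis(unname(lp))

  # terminate each history at its first death (a patient cannot be
  # readmitted after dying in hospital)
  dcum <- cumsum(death)
  prior_deaths <- (dcum - rep(dcum[first_idx] - death[first_idx], M)) - death
  keep <- prior_deaths == 0L

  data.frame(
    record_id = sprintf("%s-%07d-%03d", id_prefix, idx, nth),
    patient_id = sprintf("%s-P%07d", id_prefix, idx),
    hospital_id = profile$hospital_id,
    adm_off = adm_off, dis_off = dis_off,
    age_years = age, sex = sex[idx], emergency = emergency,
    los_days = as.integer(los),
    deprivation = deprivation[idx],
    charlson_band = charlson, ccs_group = ccs,
    died = death,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
}

#' Simulate a single patient's admission history
#'
#' Generates the admission sequence of one patient with planned admission
#' frequency `m`, casemix drifting with the ordinal position as configured,
#' strictly increasing discharge dates, and per-admission death probability
#' `plogis(lp - frailty_theta * log(m))`. A death ends the sequence, so the
#' returned history can be shorter than `m`; when a death occurs it is always
#' on the last record.
#'
#' @param m planned admission frequency (>= 1).
#' @param profile a [hospital_profile()].
#' @param config a [cohort_config()].
#' @param seed optional seed (RNG state is restored afterwards).
#' @return Admission records (up to `m` rows) with calendar dates anchored at
#'   the window start.
#' @export
simulate_patient_history <- function(m, profile = hospital_profile("A", 1L),
                                     config = cohort_config(list(profile)),
                                     seed = NULL) {
  if (m < 1) abort("m must be >= 1")
  with_seed(seed, {
    rec <- sim_histories(as.integer(m), profile, config)
    finish_records(rec, config)
  })
}

# Convert day offsets into calendar dates and finalise column order.
finish_records <- function(rec, config) {
  rec$admission_date <- config$window_start + rec$adm_off
  rec$discharge_date <- config$window_start + rec$dis_off
  rec$discharge_year <- as.integer(format(rec$discharge_date, "%Y"))
  rec$adm_off <- NULL; rec$dis_off <- NULL
  rownames(rec) <- NULL
  rec[admission_columns]
}

#' Generate a synthetic admission-record cohort
#'
#' Draws each hospital's patients (planned frequencies per
#' [sample_admission_frequency()]), simulates their full histories on the
#' horizon `[window_start - margin, window_end + margin]`, then keeps the
#' records discharged inside the study window — so histories straddling the
#' window are truncated exactly as registry extracts truncate them. With
#' `margin_years = 0` no truncation is applied.
#'
#' Deterministic for a given configuration and seed.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return Admission records for all hospitals (validated, ordered by
#'   hospital, patient and date).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  if (!inherits(config, "cohort_config")) abort("config must be a cohort_config")
  with_seed(seed, {
    horizon <- as.numeric(config$window_end - config$window_start)
    pad <- round(config$margin_years * 365)
    parts <- list()
    for (h in config$hospitals) {
      if (h$n_patients == 0L) next
      M <- sample_admission_frequency(h, h$n_patients)
      first <- floor(stats::runif(h$n_patients, -pad, horizon + pad + 1))
      rec <- sim_histories(M, h, config, first_offset = first)
      if (config$margin_years > 0) {
        keep <- rec$dis_off >= 0 & rec$dis_off <= horizon
        rec <- rec[keep, , drop = FALSE]
      }
      parts[[h$hospital_id]] <- finish_records(rec, config)
    }
    if (!length(parts)) return(empty_admissions())
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  })
}
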