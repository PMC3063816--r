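# Synthetic-cohort generator: frequency sampling, casemix drift, the death
# mechanism and window truncation.

test_that("cohorts are reproducible for a fixed config and seed", {
  cfg <- cohort_config(list(hospital_profile("A", 500)))
  a <- generate_cohort(cfg, seed = 42)
  b <- generate_cohort(cfg, seed = 42)
  expect_identical(a, b)
  c <- generate_cohort(cfg, seed = 43)
  expect_false(identical(a, c))
})

test_that("a degenerate profile with all weight on m = 1 always draws 1", {
  prof <- hospital_profile("A", 1, freq_class_weights = c(1, rep(0, 7)))
  set.seed(1)
  expect_identical(sample_admission_frequency(prof, 50), rep(1L, 50))
})

test_that("admission shares over classes match the profile weights", {
  prof <- hospital_profile("A", 1)
  set.seed(2024)
  m <- sample_admission_frequency(prof, 1e5)
  share_m1 <- sum(m == 1) / sum(m)
  expect_lt(abs(share_m1 - 0.394), 0.01)
  shares <- tapply(m, freq_class(m), sum) / sum(m)
  expect_true(all(abs(shares -
                        c(0.394, 0.20, 0.11, 0.068, 0.078, 0.055,
                          0.063, 0.033)) < 0.012))
})

test_that("composite classes draw uniformly; the open class has mean near 33", {
  prof1020 <- hospital_profile("A", 1,
                               freq_class_weights = c(0, 0, 0, 0, 0, 0, 1, 0))
  set.seed(7)
  m <- sample_admission_frequency(prof1020, 2e4)
  expect_true(all(m >= 10 & m <= 20))
  expect_lt(abs(mean(m) - 15), 0.1)
  chisq <- stats::chisq.test(table(m))$p.value
  expect_gt(chisq, 0.01)

  prof20 <- hospital_profile("A", 1,
                             freq_class_weights = c(0, 0, 0, 0, 0, 0, 0, 1))
  set.seed(8)
  m2 <- sample_admission_frequency(prof20, 2e4)
  expect_true(all(m2 >= 21 & m2 <= 60))
  expect_lt(abs(mean(m2) - 33), 1.5)
})

test_that("single-cell casemix at reference gives the configured death rate", {
  cfg <- flat_config(4e4, p = 0.054)
  co <- generate_cohort(cfg, seed = 10)
  expect_identical(nrow(co), 4e4L)          # all m = 1, margin 0
  expect_lt(abs(mean(co$died) - 0.054), 0.004)
})

test_that("the latent frailty lowers per-admission risk at identical casemix", {
  base <- flat_config(4000, p = 0.08, theta = 0.5)
  high <- flat_config(4000, p = 0.08, theta = 0.5,
                      class_weights = c(0, 0, 0, 0, 0, 0, 1, 0))
  co1 <- generate_cohort(base, seed = 3)    # all m = 1
  co10 <- generate_cohort(high, seed = 3)   # m uniform on 10..20
  r1 <- mean(co1$died)
  r10 <- sum(co10$died) / nrow(co10)
  expect_gt(r1, r10)                        # ~ 0.08 vs ~ 0.08 * m^-0.5
  expect_lt(r10, 0.05)
})

test_that("margin 0 disables truncation: in-window m equals the sampled m", {
  cfg <- flat_config(300, p = 1e-9,
                     class_weights = c(0, 0, 1, 0, 0, 0, 0, 0))
  lk <- link_admissions(generate_cohort(cfg, seed = 4))
  expect_identical(nrow(lk), 900L)
  expect_true(all(lk$m == 3L))
})

test_that("death, if it occurs, is only on a patient's last record", {
  cfg <- cohort_config(list(hospital_profile("A", 3000)),
                       frailty_theta = 0.1)
  lk <- link_admissions(generate_cohort(cfg, seed = 6))
  expect_true(all(lk$nth[lk$died] == lk$m[lk$died]))
  # and discharge dates strictly increase within a patient
  by_pat <- split(lk$discharge_date, lk$patient_id)
  expect_true(all(vapply(by_pat,
                         function(d) all(diff(as.numeric(d)) > 0),
                         logical(1))))
})

test_that("generated records satisfy the record invariants", {
  cfg <- cohort_config(list(hospital_profile("A", 1500)))
  co <- generate_cohort(cfg, seed = 9)
  expect_silent(validate_admissions(co, strict = TRUE))
  expect_true(all(co$discharge_date >= co$admission_date))
  expect_true(all(co$discharge_date >= as.Date("2003-01-01") &
                    co$discharge_date <= as.Date("2007-12-31")))
})

test_that("multi-admission spans reflect the tuned elapsed-time profile", {
  cfg <- cohort_config(list(hospital_profile("A", 3e4)))
  h <- patient_histories(link_admissions(generate_cohort(cfg, seed = 1)))
  et <- elapsed_time_summary(h)
  expect_gt(et$n_multi, 5000)
  expect_lt(abs(et$share_lt_1y - 0.63), 0.05)
  # mean first-to-last span of the most frequently admitted patients is a
  # couple of years: the effect needs a prolonged window to become visible
  span20 <- mean(as.numeric(h$last_discharge - h$first_discharge)[h$m > 20])
  expect_gt(span20 / 365, 1.8)
  expect_lt(span20 / 365, 3.2)
})

test_that("simulate_patient_history honours m and the death placement", {
  prof <- flat_profile(1, class_weights = c(0, 0, 0, 0, 0, 0, 1, 0))
  cfg <- flat_config(1, p = 1e-9)
  h <- simulate_patient_history(5, prof, cfg, seed = 2)
  expect_identical(nrow(h), 5L)
  expect_true(all(!h$died))
  cfg2 <- flat_config(1, p = 0.9)
  h2 <- simulate_patient_history(10, prof, cfg2, seed = 2)
  expect_lte(nrow(h2), 10L)
  expect_true(all(!h2$died[-nrow(h2)]))
  expect_error(simulate_patient_history(0, prof, cfg), "m")
})

test_that("empty hospitals give an empty, well-typed cohort", {
  cfg <- cohort_config(list(hospital_profile("A", 0)))
  co <- generate_cohort(cfg, seed = 1)
  expect_identical(nrow(co), 0L)
  expect_true(all(admission_columns %in% names(co)))
})
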