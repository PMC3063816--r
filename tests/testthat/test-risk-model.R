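# Stratified casemix logistic model: calibration identities, prediction
# semantics, pooling and diagnostics.

small_linked <- function(n = 4000, theta = 0, seed = 21) {
  cfg <- cohort_config(list(hospital_profile("A", n)),
                       frailty_theta = theta)
  link_admissions(generate_cohort(cfg, seed = seed))
}

test_that("an intercept-only model predicts the overall death rate", {
  lk <- small_linked()
  fit <- risk_model(died ~ 1, lk, stratify_by = "none")
  expect_equal(unique(round(fitted(fit), 12)),
               round(mean(lk$died), 12))
})

test_that("maximum-likelihood calibration holds globally and per stratum", {
  lk <- small_linked()
  fit <- risk_model(casemix_formula(), lk, stratify_by = "ccs_group")
  expect_equal(sum(fitted(fit)), sum(lk$died), tolerance = 1e-6)
  p <- predict(fit, lk)
  expect_equal(sum(p), sum(lk$died), tolerance = 1e-6)
  # per fitted stratum
  own <- setdiff(names(fit$strata), "(pooled)")
  for (g in own) {
    idx <- as.character(lk$ccs_group) == g
    expect_equal(sum(p[idx]), sum(lk$died[idx]), tolerance = 1e-6,
                 info = g)
  }
  # grouped expected deaths sum to the overall total
  byg <- expected_deaths(fit, lk, by = "ccs_group")
  expect_equal(sum(byg$expected), expected_deaths(fit, lk),
               tolerance = 1e-8)
})

test_that("a record at all reference levels is scored at plogis(intercept)", {
  lk <- small_linked()
  fit <- risk_model(died ~ sex + emergency, lk, stratify_by = "none")
  beta <- coef(fit)[, 1]
  ref <- make_record("ref", "p", "2004-01-01", "2004-01-03",
                     sex = "male", emergency = FALSE)
  expect_equal(predict(fit, ref), unname(plogis(beta["(Intercept)"])),
               tolerance = 1e-12)
  # duplicated records score identically
  two <- rbind(ref, transform(ref, record_id = "ref2"))
  expect_identical(predict(fit, two)[1], predict(fit, two)[2])
})

test_that("probabilities are strictly inside (0,1)", {
  lk <- small_linked()
  fit <- risk_model(casemix_formula(), lk)
  p <- predict(fit, lk)
  expect_true(all(p > 0 & p < 1))
})

test_that("strata below the event threshold fall back to the pooled fit", {
  lk <- small_linked(1500)
  fit <- risk_model(died ~ sex + emergency, lk, stratify_by = "ccs_group",
                    min_events = 1e6)
  expect_identical(names(fit$strata), "(pooled)")
  fit2 <- risk_model(died ~ sex + emergency, lk,
                     stratify_by = "ccs_group", min_events = 20)
  s <- summary(fit2)
  expect_true(all(c("stratum", "deaths", "converged") %in%
                    colnames(s$strata)))
  if (length(fit2$pooled_members)) {
    expect_true("(pooled)" %in% names(fit2$strata))
  }
})

test_that("unseen strata and factor levels map to fallbacks with a warning", {
  lk <- small_linked()
  fit <- risk_model(died ~ sex + factor(discharge_year), lk,
                    stratify_by = "ccs_group")
  odd <- make_record("z", "p", "2004-01-01", "2004-01-02")
  odd$ccs_group <- factor("brand-new-group")
  expect_warning(p1 <- predict(fit, odd), "unseen strata")
  expect_true(p1 > 0 && p1 < 1)
  odd2 <- make_record("z2", "p", "2004-01-01", "2004-01-02", ccs = "other")
  odd2$discharge_year <- 1999L
  expect_warning(p2 <- predict(fit, odd2), "reference")
  ref <- make_record("z3", "p", "2003-01-01", "2003-01-02", ccs = "other")
  ref$discharge_year <- min(lk$discharge_year)
  expect_equal(unname(p2), unname(predict(fit, ref)), tolerance = 1e-12)
})

test_that("degenerate inputs abort cleanly", {
  lk <- small_linked(200)
  expect_error(risk_model(casemix_formula(), lk[0, ]), "empty")
  nod <- lk; nod$died <- FALSE
  expect_error(risk_model(died ~ sex, nod), "both")
})

test_that("recovered coefficients track the generator truth", {
  cfg <- cohort_config(list(hospital_profile("A", 2e4)),
                       frailty_theta = 0)
  lk <- link_admissions(generate_cohort(cfg, seed = 31))
  fit <- stats::glm(generator_truth_formula(), binomial(), lk)
  truth <- generator_truth_coef(cfg)
  est <- coef(fit)[names(truth)]
  se <- sqrt(diag(vcov(fit)))[names(truth)]
  expect_true(all(abs(est - truth) < pmax(3.5 * se, 0.05)))
})

test_that("model methods behave: residuals, simulate, print", {
  lk <- small_linked(1000)
  fit <- risk_model(died ~ sex + emergency, lk, stratify_by = "none")
  r <- residuals(fit)
  expect_equal(length(r), nrow(lk))
  expect_equal(sum(r), 0, tolerance = 1e-6)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(nrow(lk), 3L))
  expect_true(all(unlist(sims) %in% 0:1))
  expect_identical(simulate(fit, nsim = 2, seed = 5),
                   simulate(fit, nsim = 2, seed = 5))
  expect_output(print(fit), "Casemix logistic risk model")
  expect_output(print(summary(fit)), "overall")
})
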