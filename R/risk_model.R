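# Casemix logistic risk model: a per-diagnostic-group stratified logistic
# regression of in-hospital death on casemix, the engine behind expected
# (predicted) deaths in every SMR in this package.

#' Age and length-of-stay bands
#'
#' Default categorical codings for the casemix model: 5-year age bands (0-4
#' through 90-94, then 95+) and length-of-stay bands 0 (day case), 1, 2-3,
#' 4-7, 8-14, 15+ days.
#'
#' @param age,los numeric vectors.
#' @return Factors with fixed level sets.
#' @export
age_band <- function(age) {
  br <- c(seq(0, 95, by = 5), Inf)
  lab <- c(paste(seq(0, 90, 5), seq(4, 94, 5), sep = "-"), "95+")
  cut(age, breaks = br, labels = lab, right = FALSE)
}

#' @rdname age_band
#' @export
los_band <- function(los) {
  cut(los, breaks = c(-Inf, 0, 1, 3, 7, 14, Inf),
      labels = c("0", "1", "2-3", "4-7", "8-14", "15+"))
}

#' Default casemix model formula
#'
#' The standard adjustment set of national in-hospital mortality models:
#' age, sex, admission type (emergency), length of stay, year of discharge,
#' socio-economic deprivation and comorbidity band; the diagnostic group
#' enters through stratification (see [risk_model()]). Set `freq = TRUE` to
#' add the admission-frequency class (the patient-view variable `m`) as an
#' additional adjustment covariate.
#'
#' @param covariates character subset of the default covariate terms.
#' @param freq add `freq_class(m)` as a covariate.
#' @return A model formula with response `died`.
#' @export
casemix_formula <- function(covariates = c("age_band", "sex", "emergency",
                                           "los_band", "discharge_year",
                                           "deprivation", "charlson_band"),
                            freq = FALSE) {
  terms <- c(
    age_band = "age_band(age_years)",
    sex = "sex",
    emergency = "emergency",
    los_band = "los_band(los_days)",
    discharge_year = "factor(discharge_year)",
    deprivation = "factor(deprivation)",
    charlson_band = "charlson_band"
  )[covariates]
  if (freq) terms <- c(terms, "freq_class(m)")
  if (!length(terms)) abort("at least one covariate is required")
  stats::as.formula(paste("died ~", paste(terms, collapse = " + ")),
                    env = asNamespace("hsmradjust"))
}

#' Fit a stratified casemix logistic risk model
#'
#' Fits one logistic regression of in-hospital death on casemix per stratum
#' (by default per diagnostic group), with a shared covariate coding across
#' strata. Strata with fewer observed deaths than `min_events` are pooled
#' into a single fallback stratum, which is also used at prediction time for
#' stratum labels never seen in training. No shrinkage is applied, so the
#' maximum-likelihood calibration identity holds exactly on the training
#' data: within every stratum (and every included covariate level) the
#' predicted probabilities sum to the observed deaths.
#'
#' @param formula model formula with response `died`; defaults to
#'   [casemix_formula()].
#' @param data admission records (linked records if the formula uses
#'   `freq_class(m)`).
#' @param stratify_by column to stratify on (default `"ccs_group"`), or
#'   `NULL`/`"none"` for a single pooled fit.
#' @param min_events minimum observed deaths for a stratum to be fitted on
#'   its own.
#' @return An object of class `risk_model` with `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `simulate` and `plot` methods.
#' @examples
#' cfg <- cohort_config(list(hospital_profile("A", 500)), frailty_theta = 0)
#' rec <- link_admissions(generate_cohort(cfg, seed = 1))
#' fit <- risk_model(died ~ sex + emergency, rec, stratify_by = "none")
#' sum(predict(fit, rec)) - sum(rec$died)  # ~ 0: calibration identity
#' @export
risk_model <- function(formula = casemix_formula(), data,
                       stratify_by = "ccs_group", min_events = 20) {
  if (!nrow(data)) abort("empty data")
  if (is.null(stratify_by) || identical(stratify_by, "none")) {
    strat <- factor(rep("(all)", nrow(data)))
    stratify_by <- NULL
  } else {
    if (!stratify_by %in% names(data)) {
      abort("stratification column not found: ", stratify_by)
    }
    strat <- factor(data[[stratify_by]])
  }
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  if (anyNA(mf)) abort("missing values in model variables")
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.integer(y)
  if (length(unique(y)) < 2) abort("need both survivors and deaths to fit")
  trms <- stats::delete.response(attr(mf, "terms"))
  xlev <- stats::.getXlevels(attr(mf, "terms"), mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)

  deaths_by <- tapply(y, strat, sum, default = 0L)
  own <- names(deaths_by)[deaths_by >= min_events]
  pooled_members <- setdiff(levels(strat), own)
  groups <- as.character(strat)
  groups[groups %in% pooled_members] <- "(pooled)"
  if (all(groups == "(pooled)")) groups[] <- "(pooled)"

  # Per-stratum ML fit. Fitting on the subset data frame (rather than a
  # slice of the shared design matrix) lets unused factor levels drop out,
  # which keeps the IRLS stable on small, separation-prone strata; the
  # coefficients are mapped back into the shared coding by name. A stratum
  # whose fit fails the calibration self-check (sum of fitted probabilities
  # must equal its observed deaths at the optimum) is retried with a
  # tighter control and flagged if still off.
  fit_one <- function(idx) {
    di <- data[idx, , drop = FALSE]
    fit <- suppressWarnings(stats::glm(formula, stats::binomial(), di))
    ok <- abs(sum(fit$fitted.values) - sum(y[idx])) <=
      max(0.001 * max(sum(y[idx]), 1), 1e-6)
    if (!ok || !fit$converged) {
      fit <- suppressWarnings(stats::glm(
        formula, stats::binomial(), di,
        control = stats::glm.control(epsilon = 1e-10, maxit = 200)))
      ok <- abs(sum(fit$fitted.values) - sum(y[idx])) <=
        max(0.001 * max(sum(y[idx]), 1), 1e-6)
    }
    beta <- rep(NA_real_, ncol(X))
    names(beta) <- colnames(X)
    cf <- stats::coef(fit)
    beta[intersect(names(cf), names(beta))] <-
      cf[intersect(names(cf), names(beta))]
    list(coef = beta, n = length(idx), deaths = sum(y[idx]),
         converged = fit$converged && ok,
         separation = any(abs(beta) > 15, na.rm = TRUE))
  }
  strata <- lapply(split(seq_len(nrow(X)), groups), fit_one)

  fitted <- numeric(nrow(X))
  for (g in names(strata)) {
    idx <- which(groups == g)
    beta <- strata[[g]]$coef
    ok <- !is.na(beta)
    fitted[idx] <- stats::plogis(
      drop(X[idx, ok, drop = FALSE] %*% beta[ok]))
  }

  structure(list(
    call = match.call(), formula = formula, terms = trms, xlevels = xlev,
    stratify_by = stratify_by, min_events = min_events,
    strata = strata, pooled_members = pooled_members,
    fitted = fitted, y = y, n = nrow(X), deaths = sum(y)
  ), class = "risk_model")
}

# Map each row of newdata to the stratum whose coefficients apply.
stratum_of <- function(object, newdata) {
  if (is.null(object$stratify_by)) {
    return(rep(names(object$strata)[1], nrow(newdata)))
  }
  g <- as.character(newdata[[object$stratify_by]])
  known <- setdiff(names(object$strata), "(pooled)")
  unseen <- !(g %in% known) & !(g %in% object$pooled_members)
  g[g %in% object$pooled_members] <- "(pooled)"
  if (any(unseen)) {
    fallback <- if ("(pooled)" %in% names(object$strata)) "(pooled)" else
      names(object$strata)[which.max(sapply(object$strata, `[[`, "n"))]
    warning(sum(unseen), " record(s) in unseen strata mapped to ", fallback)
    g[unseen] <- fallback
  }
  g
}

#' Predict per-admission death probabilities
#'
#' @param object a [risk_model()].
#' @param newdata admission records; omitting it returns the training fitted
#'   values. Factor levels unseen in training are mapped to the reference
#'   level with a warning (the apply-a-national-model use case).
#' @param type `"response"` (probabilities) or `"link"` (logits).
#' @param ... unused.
#' @return Numeric vector, one probability per record, strictly inside (0,1).
#' @export
predict.risk_model <- function(object, newdata = NULL,
                               type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "link") return(stats::qlogis(object$fitted))
    return(object$fitted)
  }
  nd <- newdata
  remapped <- 0L
  for (v in names(object$xlevels)) {
    # bare factor columns, plus single-column factor(...) terms such as
    # factor(discharge_year); band helpers (age_band, los_band, freq_class)
    # have fixed level sets and need no remapping
    col <- if (v %in% names(nd)) v else sub("^factor\\((.*)\\)$", "\\1", v)
    if (col %in% names(nd)) {
      val <- as.character(nd[[col]])
      bad <- !(val %in% object$xlevels[[v]]) & !is.na(val)
      if (any(bad)) {
        remapped <- remapped + sum(bad)
        val[bad] <- object$xlevels[[v]][1]
      }
      nd[[col]] <- if (identical(col, v))
        factor(val, levels = object$xlevels[[v]])
      else if (is.numeric(nd[[col]])) as.numeric(val)
      else val
    }
  }
  if (remapped > 0) {
    warning(remapped,
            " value(s) at unseen factor levels mapped to the reference level")
  }
  mf <- stats::model.frame(object$terms, nd, na.action = stats::na.pass,
                           xlev = object$xlevels)
  X <- stats::model.matrix(object$terms, mf)
  g <- stratum_of(object, nd)
  eta <- numeric(nrow(X))
  for (s in unique(g)) {
    idx <- which(g == s)
    beta <- object$strata[[s]]$coef
    ok <- !is.na(beta)
    eta[idx] <- drop(X[idx, ok, drop = FALSE] %*% beta[ok])
  }
  if (type == "link") eta else stats::plogis(eta)
}

#' Expected deaths by group
#'
#' Sums the model's predicted per-admission death probabilities — the
#' denominator of an (H)SMR — optionally within groups.
#'
#' @param object a [risk_model()].
#' @param records admission records.
#' @param by optional grouping column name (e.g. `"hospital_id"`,
#'   `"freq_class"`).
#' @return A single total when `by` is `NULL`, otherwise a data.frame with
#'   columns `group` and `expected`. Group totals always sum to the overall
#'   total.
#' @export
expected_deaths <- function(object, records, by = NULL) {
  p <- predict(object, records)
  if (is.null(by)) return(sum(p))
  g <- records[[by]]
  agg <- tapply(p, g, sum, default = 0)
  data.frame(group = names(agg), expected = as.numeric(agg),
             stringsAsFactors = FALSE)
}

#' Attach predicted risks to records
#'
#' @param records admission records.
#' @param object a [risk_model()].
#' @param col name of the column to create.
#' @return `records` with the predicted-risk column appended.
#' @export
add_risk <- function(records, object, col = "risk") {
  records[[col]] <- predict(object, records)
  records
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Casemix logistic risk model\n")
  cat(sprintf("  records: %d, deaths: %d (%.2f%%)\n",
              x$n, x$deaths, 100 * x$deaths / x$n))
  cat(sprintf("  strata (%s): %d fitted%s\n",
              x$stratify_by %||% "pooled", length(x$strata),
              if (length(x$pooled_members))
                sprintf(", %d pooled into fallback",
                        length(x$pooled_members)) else ""))
  cat(sprintf("  training calibration: expected %.1f vs observed %d\n",
              sum(x$fitted), x$deaths))
  invisible(x)
}

#' @export
summary.risk_model <- function(object, ...) {
  d <- do.call(rbind, lapply(names(object$strata), function(g) {
    s <- object$strata[[g]]
    data.frame(stratum = g, n = s$n, deaths = s$deaths,
               n_coef = sum(!is.na(s$coef)), converged = s$converged,
               separation = s$separation, stringsAsFactors = FALSE)
  }))
  structure(list(strata = d, pooled_members = object$pooled_members,
                 formula = object$formula, n = object$n,
                 deaths = object$deaths, expected = sum(object$fitted)),
            class = "summary.risk_model")
}

#' @export
print.summary.risk_model <- function(x, ...) {
  cat("Casemix logistic risk model\n")
  cat(deparse(x$formula), "\n\n")
  print(x$strata, row.names = FALSE)
  if (length(x$pooled_members)) {
    cat("pooled fallback covers:",
        paste(x$pooled_members, collapse = ", "), "\n")
  }
  cat(sprintf("\noverall: %d records, %d deaths, %.2f expected\n",
              x$n, x$deaths, x$expected))
  invisible(x)
}

#' @export
coef.risk_model <- function(object, ...) {
  do.call(cbind, lapply(object$strata, `[[`, "coef"))
}

#' @export
fitted.risk_model <- function(object, ...) object$fitted

#' @export
residuals.risk_model <- function(object,
                                 type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "pearson") {
    r <- r / sqrt(object$fitted * (1 - object$fitted))
  }
  r
}

#' Simulate death indicators from a fitted risk model
#'
#' Draws Bernoulli death indicators at the model's predicted probabilities —
#' the parametric-bootstrap view of the fitted casemix model.
#'
#' @param object a [risk_model()].
#' @param nsim number of replicate vectors.
#' @param seed optional seed (RNG state restored afterwards).
#' @param newdata optional records to simulate for (defaults to training
#'   fitted values).
#' @param ... unused.
#' @return A data.frame with `nsim` columns of 0/1 indicators.
#' @export
simulate.risk_model <- function(object, nsim = 1, seed = NULL,
                                newdata = NULL, ...) {
  p <- if (is.null(newdata)) object$fitted else predict(object, newdata)
  with_seed(seed, {
    out <- as.data.frame(matrix(
      stats::rbinom(length(p) * nsim, 1L, rep(p, nsim)),
      ncol = nsim))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' Calibration plot for a fitted risk model
#'
#' Observed versus expected deaths by decile of predicted risk on the
#' training data; a well-calibrated model tracks the identity line.
#'
#' @param x a [risk_model()].
#' @param bins number of risk bins.
#' @param ... passed to [graphics::plot()].
#' @export
plot.risk_model <- function(x, bins = 10, ...) {
  q <- unique(stats::quantile(x$fitted, seq(0, 1, length.out = bins + 1)))
  b <- cut(x$fitted, q, include.lowest = TRUE)
  obs <- tapply(x$y, b, sum)
  exp <- tapply(x$fitted, b, sum)
  graphics::plot(exp, obs, xlab = "expected deaths per risk bin",
                 ylab = "observed deaths per risk bin", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(data.frame(expected = as.numeric(exp),
                       observed = as.numeric(obs)))
}
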