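# Standardised mortality ratios and their confidence limits.
#
# The (H)SMR is classical indirect standardisation: 100 x observed deaths
# over the deaths expected if reference-population risks applied to the local
# casemix. Expected deaths are treated as fixed constants and the observed
# count as Poisson, the conventional inference for hospital mortality
# monitoring.

#' Standardised mortality ratio
#'
#' `100 * observed / expected`; 100 means parity with the reference
#' population.
#'
#' @param observed non-negative integer count(s) of observed deaths.
#' @param expected positive expected death total(s).
#' @return Numeric vector of SMRs on the percentage-like scale.
#' @examples
#' smr(8836, 6971)  # 126.8 at one decimal
#' @export
smr <- function(observed, expected) {
  if (any(expected <= 0)) abort("expected must be > 0")
  if (any(observed < 0) || any(observed != floor(observed))) {
    abort("observed must be a non-negative integer count")
  }
  100 * observed / expected
}

#' Confidence limits for an SMR
#'
#' Byar's approximation (default) gives closed-form limits for the Poisson
#' count `O`:
#' `O_low = O (1 - 1/(9O) - z/(3 sqrt(O)))^3` and
#' `O_high = (O+1) (1 - 1/(9(O+1)) + z/(3 sqrt(O+1)))^3`,
#' divided by the expected count and scaled by 100. The `"exact"` method uses
#' the gamma-quantile (exact Poisson) limits and `"normal"` the Wald
#' approximation. At `O = 0` the lower limit is 0 and the upper limit is the
#' exact Poisson limit under every method.
#'
#' @param observed,expected as in [smr()]; vectorised.
#' @param level confidence level in (0, 1).
#' @param method `"byar"`, `"exact"` or `"normal"`.
#' @return A data.frame with columns `low` and `high` on the SMR scale.
#' @examples
#' smr_ci(8836, 6971)  # 124.1 - 129.4 at one decimal
#' @export
smr_ci <- function(observed, expected, level = 0.95,
                   method = c("byar", "exact", "normal")) {
  method <- match.arg(method)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("level must be a single number in (0, 1)")
  }
  if (any(expected <= 0)) abort("expected must be > 0")
  O <- observed
  alpha <- 1 - level
  z <- stats::qnorm(1 - alpha / 2)
  lo_cnt <- hi_cnt <- numeric(length(O))
  pos <- O > 0
  if (method == "byar") {
    lo_cnt[pos] <- O[pos] *
      (1 - 1 / (9 * O[pos]) - z / (3 * sqrt(O[pos])))^3
    O1 <- O + 1
    hi_cnt <- O1 * (1 - 1 / (9 * O1) + z / (3 * sqrt(O1)))^3
  } else if (method == "exact") {
    lo_cnt[pos] <- stats::qgamma(alpha / 2, O[pos])
    hi_cnt <- stats::qgamma(1 - alpha / 2, O + 1)
  } else {
    lo_cnt[pos] <- pmax(0, O[pos] - z * sqrt(O[pos]))
    hi_cnt <- O + z * sqrt(O)
  }
  # O = 0: lower limit exactly 0, upper limit from the exact Poisson bound
  if (any(!pos)) hi_cnt[!pos] <- stats::qgamma(1 - alpha / 2, 1)
  data.frame(low = 100 * lo_cnt / expected, high = 100 * hi_cnt / expected)
}

# Assemble SMR rows from observed/expected vectors.
smr_rows <- function(group, observed, expected, level, method) {
  ci <- smr_ci(observed, expected, level, method)
  data.frame(
    group = as.character(group),
    observed = observed, expected = expected,
    smr = smr(observed, expected),
    ci_low = ci$low, ci_high = ci$high,
    stringsAsFactors = FALSE
  )
}

#' Per-class SMR table from a class count table
#'
#' Turns a patient-view or admission-view class table (with expected deaths
#' filled in, either model-based via [class_table()] or transcribed counts)
#' into per-class SMRs with confidence limits, an overall row, and a flag for
#' whether each class interval contains the overall ratio — the visual test
#' for whether the casemix model fits that view.
#'
#' @param counts data.frame with columns `class`, `observed_deaths`,
#'   `expected_deaths` (a `Total` row, if present, is ignored and
#'   recomputed).
#' @param level confidence level.
#' @param method CI method, see [smr_ci()].
#' @return A data.frame of class `smr_table`: one row per populated class
#'   (classes with neither observed nor expected deaths are dropped) plus an
#'   `Overall` row, with `observed`, `expected`, `smr`, `ci_low`, `ci_high`,
#'   `contains_overall`.
#' @export
class_smr_table <- function(counts, level = 0.95, method = "byar") {
  body <- counts[counts$class != "Total", , drop = FALSE]
  if (!"expected_deaths" %in% names(body) &&
      "predicted_deaths" %in% names(body)) {
    body$expected_deaths <- body$predicted_deaths
  }
  if (!"expected_deaths" %in% names(body) ||
      anyNA(body$expected_deaths)) {
    abort("expected_deaths must be filled in for every class")
  }
  empty <- body$expected_deaths <= 0 & body$observed_deaths == 0
  body <- body[!empty, , drop = FALSE]
  if (!nrow(body)) abort("no populated classes")
  if (any(body$expected_deaths <= 0)) {
    abort("class with observed deaths but expected_deaths = 0: ",
          paste(body$class[body$expected_deaths <= 0], collapse = ", "))
  }
  out <- smr_rows(body$class, body$observed_deaths, body$expected_deaths,
                  level, method)
  overall <- smr_rows("Overall", sum(body$observed_deaths),
                      sum(body$expected_deaths), level, method)
  out <- rbind(out, overall)
  out$contains_overall <- out$ci_low <= overall$smr &
    overall$smr <= out$ci_high
  structure(out, class = c("smr_table", "data.frame"),
            level = level, method = method,
            view = attr(counts, "view"))
}

#' SMRs for arbitrary groupings of records
#'
#' Aggregates observed deaths and model-expected deaths by a key (hospital,
#' diagnostic group, ...) and returns the per-group SMR table. Group observed
#' and expected totals always sum to the cohort totals.
#'
#' @param records admission records carrying a predicted-risk column.
#' @param by grouping column name, or `NULL` for the overall ratio only.
#' @param risk_col name of the predicted-risk column.
#' @param level,method as in [class_smr_table()].
#' @return An `smr_table` with one row per group plus an `Overall` row.
#' @export
hsmr_by <- function(records, by = "hospital_id", risk_col = "risk",
                    level = 0.95, method = "byar") {
  if (!risk_col %in% names(records)) {
    abort("records must carry predicted risks in column '", risk_col, "'")
  }
  if (is.null(by)) {
    g <- factor(rep("Overall", nrow(records)))
  } else {
    g <- factor(records[[by]])
  }
  obs <- as.integer(tapply(records$died, g, sum, default = 0L))
  exp <- as.numeric(tapply(records[[risk_col]], g, sum, default = 0))
  out <- smr_rows(levels(g), obs, exp, level, method)
  if (!is.null(by)) {
    overall <- smr_rows("Overall", sum(obs), sum(exp), level, method)
    out <- rbind(out, overall)
  }
  ov <- out$smr[out$group == "Overall"]
  out$contains_overall <- out$ci_low <= ov & ov <= out$ci_high
  structure(out, class = c("smr_table", "data.frame"),
            level = level, method = method)
}

#' @export
print.smr_table <- function(x, digits = 1, ...) {
  lv <- attr(x, "level"); mth <- attr(x, "method")
  vw <- attr(x, "view")
  cat(sprintf("SMR table (%s%% CI, %s method%s)\n", format(100 * lv),
              mth, if (!is.null(vw)) paste0(", ", vw, " view") else ""))
  y <- as.data.frame(x)
  for (col in c("expected", "smr", "ci_low", "ci_high")) {
    y[[col]] <- round_half_up(y[[col]], digits)
  }
  print(y, row.names = FALSE)
  invisible(x)
}

#' Monotone-gradient permutation test for a set of class SMRs
#'
#' Spearman rank correlation between class index and SMR, with a two-sided
#' permutation p-value: a surrogate significance test for the decreasing
#' SMR gradient across admission-frequency classes that the constant-risk
#' fallacy produces.
#'
#' SMR differences smaller than `tol` are treated as ties, so that numerical
#' jitter around an exactly calibrated table cannot register as a trend; a
#' constant vector has `rho = 0` and `p_value = 1`.
#'
#' @param smr_values per-class SMRs in class order.
#' @param n_perm number of permutations.
#' @param seed optional seed (RNG state restored afterwards).
#' @param tol resolution below which SMR values are tied.
#' @return A list with `rho` and `p_value`.
#' @export
smr_gradient_test <- function(smr_values, n_perm = 2000, seed = NULL,
                              tol = 0.5) {
  k <- length(smr_values)
  if (k < 3) abort("need at least 3 classes")
  idx <- seq_len(k)
  vals <- if (tol > 0) round(smr_values / tol) * tol else smr_values
  if (stats::sd(vals) == 0) return(list(rho = 0, p_value = 1))
  rho <- stats::cor(idx, vals, method = "spearman")
  with_seed(seed, {
    perm <- replicate(n_perm, {
      abs(stats::cor(idx, sample(vals), method = "spearman"))
    })
    list(rho = rho, p_value = (1 + sum(perm >= abs(rho))) / (n_perm + 1))
  })
}
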