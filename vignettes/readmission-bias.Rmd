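---
title: "Readmission linkage and the bias of hospital standardised mortality ratios"
author: "hsmradjust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Readmission linkage and the bias of hospital standardised mortality ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsmradjust)
```

## The problem

A hospital standardised mortality ratio compares observed in-hospital
deaths with the deaths a casemix model predicts,

$$\mathrm{HSMR} = 100 \times \frac{\sum_i d_i}{\sum_i \hat p_i},$$

where the sums run over admissions, $d_i$ is the in-hospital death flag and
$\hat p_i$ the model's predicted death probability for admission $i$ given
its casemix (age, sex, admission type, length of stay, discharge year,
deprivation, comorbidity band, diagnostic group). The model treats every
admission as an independent trial. Linking admissions of the same patient
over a multi-year window exposes two problems with that assumption:

1. **A patient can die at most once.** A patient admitted $m$ times
   contributes up to $m$ predicted deaths to the denominator but at most one
   observed death to the numerator.
2. **Frequent readmission is informative.** The practices that generate
   many admissions — splitting diagnosis and treatment into separate stays,
   chemotherapy schedules, referral traffic — lower the real risk carried by
   each individual admission in ways the casemix variables do not fully
   record.

Grouping the same records two ways makes the consequences visible. The
*patient view* $P(m)$ partitions patients by their total in-window
admission frequency $m$; all $m$ admissions of a patient land in the class
of $m$. The *admission view* $A(n)$ groups records by their ordinal
position $n$ within the patient's history; a patient with $m$ admissions
contributes one record to every $A(n)$ with $n \le m$. Classes above
$m,n = 4$ are pooled into 5–6, 7–9, 10–20 and >20 to preserve power.
Because a death terminates the admission sequence, a death at ordinal $n$
belongs to a patient with $m = n$: the observed-death columns of the two
views are identical class by class, while the expected-death columns differ
— that asymmetry is the whole story. Treating admission counts as carrying
the same risk meaning across frequency classes when they do not is an
instance of the constant risk fallacy.

## The pipeline

`link_admissions()` orders each patient's records by discharge date
(admission date and record id only break exact ties, so numbering is total
and reproducible) and computes `nth` and `m`; records after an in-hospital
death are rejected. `risk_model()` fits one logistic regression per
diagnostic-group stratum with a shared covariate coding; strata with fewer
than `min_events = 20` deaths are pooled into a fallback stratum. No
shrinkage is applied, deliberately: the maximum-likelihood score equations
then make predicted deaths equal observed deaths within every stratum and
every included covariate level on the training data, which is the identity
all calibration checks rest on. `class_smr_table()` and `hsmr_by()` turn
observed/expected pairs into SMRs with confidence limits.
`adjust_for_frequency()` adds the patient-view class of `m` as a
categorical covariate and refits: the score equations then force
$\sum \hat p = \sum d$ within every frequency class, which is exactly why
the adjusted patient-view SMRs collapse onto 100.

### Confidence limits

Expected deaths are treated as fixed constants (classical indirect
standardisation) and the observed count as Poisson. The default limits are
Byar's closed-form approximation,
$$O_{\mathrm{low}} = O\left(1 - \tfrac{1}{9O} - \tfrac{z}{3\sqrt{O}}\right)^3,
\qquad
O_{\mathrm{high}} = (O+1)\left(1 - \tfrac{1}{9(O+1)} +
\tfrac{z}{3\sqrt{O+1}}\right)^3,$$
scaled by $100/E$. Exact Poisson (gamma-quantile) limits and the normal
approximation are available; the exact method is the independent oracle in
the test suite, and Byar agrees with it to well under 0.2 SMR points for
counts of 100 or more. At $O = 0$ the lower limit is 0 and the upper limit
is taken from the exact bound under every method. Byar is the default
because it reproduces the published worked-example intervals at one decimal.

### Reporting conventions

Reports round half away from zero to one decimal for SMRs and limits
(`round_half_up()`), matching how registry tables are printed; CSV outputs
always carry full precision alongside.

## The synthetic cohort generator

No admission-level registry extract of this kind is public, so the
generator produces cohorts with the statistical structure the analysis
assumes. Its defaults are the study conditions, chosen once:

* **Admission-frequency profile.** Class weights are admission shares
  (39.4, 20.0, 11.0, 6.8, 7.8, 5.5, 6.3, 3.3 percent for classes 1, 2, 3,
  4, 5–6, 7–9, 10–20, >20, the pooled six-hospital profile); patient-level
  class probabilities are those shares divided by the class mean frequency,
  renormalised. Within composite classes the frequency is uniform; the
  open class draws from a geometric tail truncated to 21–60 (mean ≈ 33), so
  extreme frequencies exist but stay bounded. The within-class rules are
  stated defaults — published profiles report class shares, not
  within-class distributions.
* **Casemix drift.** Age peaks around the fourth admission; the Charlson
  2–3 band rises from 10% to 60% of records across ordinal classes;
  neoplasms rise from 13% to 72% while heart disease falls from 40% to 2%;
  the emergency fraction falls from 43% to 7%; mean length of stay falls
  from ~7 to 1.8 days. Each patient also has a *primary* diagnostic group
  drawn from the mix of their frequency class and used for 70% of their
  admissions: chronically ill, frequently admitted patients keep their
  diagnosis, which lets the casemix model see part of what drives frequent
  admission.
* **Risk model.** Per-admission death probability is
  $\operatorname{logit}^{-1}(\beta_{0,\mathrm{ccs}} + x^\top\beta -
  \theta \log m)$ with diagnostic-group intercepts and effects for age
  (+0.5 per decade), sex, emergency (+0.8), deprivation and Charlson band;
  intercepts are set so crude mortality lands near the published profile
  (≈5% for first-and-only admissions, ≈3.5% per admission overall).
* **Death ends the sequence.** Deaths are drawn admission by admission and
  a death terminates the history, so a planned frequency can be cut short
  and the death flag can only sit on the last record. This is the honest
  rendering of in-hospital death, and it has a consequence worth stating
  plainly: *even with $\theta = 0$* the patient view shows a steep
  decreasing SMR gradient. Class $P(1)$ inherits the first-admission deaths
  of every patient who would have returned, while high-$m$ classes are
  populated by survivors whose denominators keep accumulating. The
  patient-view gradient is therefore not evidence of a latent mechanism by
  itself — it is partly an accounting artifact of indirect standardisation
  under readmission, which is precisely the overcount that
  `frequency_overcount_audit()` itemises per patient. The admission view,
  by contrast, is exactly calibrated at $\theta = 0$: every ordinal-$n$
  record is a correctly specified Bernoulli trial, so a flat admission view
  coexisting with a graded patient view emerges naturally.
* **The latent knob.** `frailty_theta` (default 0.1) lowers the
  per-admission logit by $\theta \log m$ using the patient's total planned
  frequency — one interpretable dial standing in for split admissions,
  treatment schedules and referral effects that casemix cannot see. The
  default is deliberately modest: the published admission-view SMRs sit in
  90–99 with predicted per-admission mortality falling from ~4% to ~1%
  across ordinals, so most of the real risk decline must be visible
  casemix drift; $33^{-0.1} \approx 0.7$ leaves a ~30% residual reduction
  at the highest frequencies invisible to the model. Substantially larger
  values push the mid admission-view classes well below parity, which the
  published tables do not show.
* **Timing.** Inter-admission gaps are exponential with class-dependent
  means (470 days for $m=2$ down to ~29 days for the most frequent
  classes), calibrated once so that ~63% of multi-admission patients have
  a first-to-last-discharge span under one year and the >20 class spans
  ~2.5 years on average. An exponential tail is lighter than real
  readmission tails: it puts ~98% of spans under three years where ~91%
  would be realistic; matching both quantiles would need a heavier-tailed
  gap law and is not attempted.
* **Truncation.** Histories are placed uniformly on the study window
  padded by `margin_years` (default 1) on each side and records discharged
  outside the window are dropped, so in-window frequencies are truncated
  exactly as registry extracts truncate them; `margin_years = 0` disables
  truncation. The five-year window 2003-01-01 to 2007-12-31 is the
  default.
* **Randomness.** One seeded stream with fully vectorised generation:
  cohorts are identical for a fixed configuration and seed, which is the
  reproducibility every test relies on. Per-patient substreams were
  considered and rejected — base R offers no cheap substream mechanism and
  the single stream already guarantees the property that matters.

### What the generator does not emulate

Clinical-coding variation between hospitals, inter-hospital transfers as
linked events (referral effects are folded into $\theta$), seasonality,
30-day unplanned-readmission semantics, and the actual coefficients of any
national casemix model. Tests passing on synthetic cohorts therefore
demonstrate the *mechanics* of the bias and its repair, not the magnitude
of either in any particular health system.

## Numerical choices

* Stratum fits run `stats::glm` on the stratum's own records (unused
  factor levels drop out, which keeps IRLS stable in small
  separation-prone strata) and map coefficients back into the shared
  coding by name; every stratum fit is verified against the calibration
  identity and retried with a tighter control if it fails. Aliased
  coefficients count as zero, i.e. reference-level behaviour.
* Unknown stratum labels at prediction time fall back to the pooled
  stratum; unknown factor levels map to the reference level, with
  warnings. This is the apply-a-national-model-to-a-new-hospital case.
* The gradient statistic is a Spearman rank correlation between class
  index and SMR with a seeded permutation p-value; SMR differences below
  0.5 points are treated as ties so that numerical jitter around an
  exactly calibrated table cannot register as a trend.
* Day cases carry `los_days = 0`, permitted only for same-day stays;
  length of stay is otherwise validated against the dates but carried as
  its own column, since registries compute it with local rules.
* The frequency adjustment uses the full-window $m$ (a look-ahead, exactly
  as the patient view defines it). A prospective running-counter variant
  (`prospective = TRUE`) is provided but not the default; the covariate
  form (class dummies) was chosen over post-hoc reweighting because it
  inherits the per-class calibration identity from the score equations.

## Statistical power at the sparse tail

The demonstration cohort uses $10^5$ patients (~175,000 admissions), at
which size the sparse admission-view classes carry only ~10–90 expected
deaths, i.e. Poisson standard errors of 10–30 SMR points. Assertions that
*every* admission-view class sit inside a ±5/±15-point band around parity
are therefore near coin-flips at this scale even though the view is exactly
calibrated in expectation — the published >20-class interval itself spans
more than 50 points. The same noise breaks strict monotonicity between
neighbouring tail classes of the patient view, so monotonicity is asserted
on the well-populated classes and as a rank-correlation trend. Cohort
sizes in the test suite (1,500–100,000 patients) are the package's chosen
problem sizes, balancing resolution of these identities against run time.

## Known limitations

* The casemix model's banding (5-year age bands; LOS bands 0, 1, 2–3, 4–7,
  8–14, 15+) is a documented default, not a claim about any national
  model's functional form.
* Patient identity is an exact `patient_id` match; probabilistic linkage
  and cross-registry identity resolution are out of scope.
* Expected deaths are treated as constants; no uncertainty from model
  fitting is propagated into SMR intervals, matching conventional
  monitoring practice.
* The worked-example replay recomputes from printed, rounded per-class
  counts; the sparsest patient-view class and the admission-view cells can
  differ from the published one-decimal values by a few tenths because the
  original denominators were not rounded.
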