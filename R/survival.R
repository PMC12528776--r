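# Prognostic-evaluation layer: Cox proportional hazards, Kaplan-Meier,
# log-rank, Harrell's C, time-dependent IPCW ROC, proportional-hazards
# diagnostics, progression labelling, and a cohort simulator for
# parameter-recovery testing.
#
# Cox/KM/log-rank/Schoenfeld computations are delegated to the survival
# package (Efron ties); the concordance, time-dependent AUC, increment and
# simulation layers are implemented here.

#' @importFrom survival coxph Surv survfit survdiff cox.zph
NULL

check_cohort <- function(cohort, covariates = character(0)) {
  if (!all(c("time", "event") %in% names(cohort)))
    airtree_error("cohort needs time and event columns", "airtree_missing_column")
  miss <- setdiff(covariates, names(cohort))
  if (length(miss))
    airtree_error(paste0("cohort is missing covariate(s): ",
                         paste(miss, collapse = ", ")), "airtree_missing_column")
  invisible(TRUE)
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood maximisation with Efron tie handling; Wald confidence
#' intervals and p-values.
#'
#' @param cohort a `cohort` data frame (or any data frame with `time`,
#'   `event` and covariate columns).
#' @param covariates character vector of covariate column names.
#' @param conf_level confidence level for the hazard-ratio intervals.
#' @param ties tie handling: `"efron"` (default, less biased) or
#'   `"breslow"` (under which duplicating every record leaves the point
#'   estimate exactly unchanged).
#' @return A `cox_fit`: `table` (covariate, log_hr, hr, ci_lower, ci_upper,
#'   p), `loglik`, `n`, `events`, and the underlying `coxph` object in
#'   `model`.
#' @export
fit_cox <- function(cohort, covariates, conf_level = 0.95,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_cohort(cohort, covariates)
  if (sum(cohort$event) < 2)
    airtree_error("need at least 2 events to fit a Cox model",
                  "airtree_too_few_events")
  for (cv in covariates) {
    v <- cohort[[cv]]
    if (!is.numeric(v))
      airtree_error(sprintf("covariate '%s' is not numeric", cv),
                    "airtree_bad_covariate")
    if (length(unique(v[!is.na(v)])) < 2L)
      airtree_error(sprintf("covariate '%s' is constant", cv),
                    "airtree_bad_covariate")
  }
  fml <- stats::as.formula(paste("Surv(time, event) ~",
                                 paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- coxph(fml, data = cohort, ties = ties,
               control = survival::coxph.control(eps = 1e-9, iter.max = 50))
  if (!is.null(fit$info) && grepl("infinite", paste(fit$info, collapse = " ")))
    warning("possible separation: infinite coefficient reported")
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(
    covariate = covariates,
    log_hr = unname(beta),
    se = unname(se),
    hr = unname(exp(beta)),
    ci_lower = unname(exp(beta - z * se)),
    ci_upper = unname(exp(beta + z * se)),
    p = unname(2 * stats::pnorm(-abs(beta / se))))
  structure(list(table = tab, loglik = fit$loglik[2], n = fit$n,
                 events = fit$nevent, model = fit), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit n=%d events=%d loglik=%.3f>\n", x$n, x$events, x$loglik))
  print(x$table, digits = 4)
  invisible(x)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with Greenwood standard errors, optionally per
#' group.
#'
#' @param cohort data frame with `time`, `event`.
#' @param groups optional factor of group labels.
#' @return data frame: group, time, n_risk, n_event, n_censor, surv, se,
#'   lower, upper (log-log intervals).
#' @export
km_estimate <- function(cohort, groups = NULL) {
  check_cohort(cohort)
  if (is.null(groups)) {
    fit <- survfit(Surv(time, event) ~ 1, data = cohort, conf.type = "log-log")
    grp <- rep("all", length(fit$time))
  } else {
    df <- data.frame(time = cohort$time, event = cohort$event, g = groups)
    fit <- survfit(Surv(time, event) ~ g, data = df, conf.type = "log-log")
    grp <- rep(sub("^g=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, n_censor = fit$n.censor,
             surv = fit$surv, se = fit$std.err * fit$surv,
             lower = fit$lower, upper = fit$upper)
}

#' Log-rank test across groups
#'
#' @param cohort data frame with `time`, `event`.
#' @param groups factor of k >= 2 group labels.
#' @return list with `statistic` (chi-square), `df` (k - 1), `p`.
#' @export
logrank_test <- function(cohort, groups) {
  check_cohort(cohort)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    airtree_error("log-rank needs at least 2 groups", "airtree_bad_values")
  df <- data.frame(time = cohort$time, event = cohort$event, g = droplevels(groups))
  sd <- survdiff(Surv(time, event) ~ g, data = df)
  k <- length(sd$n)
  list(statistic = unname(sd$chisq), df = k - 1L,
       p = unname(stats::pchisq(sd$chisq, k - 1L, lower.tail = FALSE)))
}

#' Harrell's concordance index
#'
#' Fraction of usable pairs (the member with the shorter observed time had
#' an event, and observed times differ) in which the higher risk score
#' belongs to the shorter time; risk-score ties count 1/2.
#'
#' @param cohort data frame with `time`, `event` (or a numeric time vector).
#' @param risk numeric risk scores (higher = worse prognosis).
#' @param event event indicator when `cohort` is a plain time vector.
#' @return C-index in `[0, 1]`; attribute `pairs` gives the usable-pair count.
#' @export
harrell_c <- function(cohort, risk, event = NULL) {
  if (is.data.frame(cohort)) {
    time <- cohort$time; ev <- cohort$event
  } else {
    time <- cohort; ev <- event
  }
  n <- length(time)
  if (length(risk) != n || is.null(ev))
    airtree_error("time, event and risk must have equal length", "airtree_bad_values")
  conc <- 0; usable <- 0
  for (i in which(ev == 1)) {
    later <- time > time[i]
    usable <- usable + sum(later)
    conc <- conc + sum(risk[i] > risk[later]) + 0.5 * sum(risk[i] == risk[later])
  }
  if (usable == 0)
    airtree_error("no usable pairs for the concordance index", "airtree_bad_values")
  structure(conc / usable, pairs = usable)
}

# censoring-distribution KM, evaluated at t (left limit optional)
censoring_km <- function(time, event) {
  fit <- survfit(Surv(time, 1 - event) ~ 1)
  function(t, left = FALSE) {
    tt <- if (left) t - 1e-12 else t
    s <- c(1, fit$surv)[findInterval(tt, fit$time) + 1L]
    s
  }
}

#' Time-dependent ROC AUC (cumulative cases, dynamic controls)
#'
#' Discrimination of events occurring by horizon `t` (cases) versus
#' subjects still event-free past `t` (controls), weighting cases by the
#' inverse probability of remaining uncensored (Kaplan-Meier of the
#' censoring distribution).
#'
#' @param cohort data frame with `time`, `event`.
#' @param marker numeric marker (higher = higher risk).
#' @param horizon time horizon `t`.
#' @return AUC(t); attributes `n_cases` and `n_controls`.
#' @export
time_dependent_auc <- function(cohort, marker, horizon) {
  check_cohort(cohort)
  time <- cohort$time; event <- cohort$event
  cases <- which(time <= horizon & event == 1)
  controls <- which(time > horizon)
  if (!length(cases))
    airtree_error("no cases (events by the horizon)", "airtree_no_cases")
  if (!length(controls))
    airtree_error("no controls (subjects beyond the horizon)", "airtree_no_controls")
  G <- censoring_km(time, event)
  w_case <- 1 / pmax(G(time[cases], left = TRUE), 1e-12)
  w_ctrl <- rep(1 / pmax(G(horizon), 1e-12), length(controls))
  num <- 0
  for (k in seq_along(cases)) {
    mi <- marker[cases[k]]
    num <- num + w_case[k] * sum(w_ctrl * ((mi > marker[controls]) +
                                             0.5 * (mi == marker[controls])))
  }
  auc <- num / (sum(w_case) * sum(w_ctrl))
  structure(auc, n_cases = length(cases), n_controls = length(controls))
}

#' Proportional-hazards check via scaled Schoenfeld residuals
#'
#' Scaled Schoenfeld residuals regressed on event time; under proportional
#' hazards the slope is zero.
#'
#' @param fit a `cox_fit`.
#' @param transform time transform passed to the score test
#'   (default `"identity"`).
#' @return data frame: covariate, chisq, df, p.
#' @export
schoenfeld_ph_check <- function(fit, transform = "identity") {
  zp <- cox.zph(fit$model, transform = transform, global = FALSE)
  tab <- as.data.frame(zp$table)
  data.frame(covariate = rownames(tab), chisq = tab$chisq, df = tab$df,
             p = tab$p, row.names = NULL)
}

#' 12-month physiological progression label
#'
#' Progression = decline in FVC percent-predicted of at least 10% or in
#' DLCO percent-predicted of at least 15% over the interval. `"relative"`
#' interprets the thresholds as fractions of baseline (the usual IPF trial
#' convention); `"absolute"` as percentage-point drops. Missing DLCO falls
#' back to the FVC criterion alone (flagged in attribute `dlco_missing`).
#'
#' @param fvc0,fvc12 baseline and follow-up FVC percent predicted.
#' @param dlco0,dlco12 baseline and follow-up DLCO percent predicted
#'   (may be NA).
#' @param mode `"relative"` or `"absolute"`.
#' @return logical vector of progression labels.
#' @export
progression_label <- function(fvc0, fvc12, dlco0 = NA, dlco12 = NA,
                              mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  if (mode == "relative") {
    fvc_prog <- (fvc0 - fvc12) / fvc0 >= 0.10
    dlco_prog <- (dlco0 - dlco12) / dlco0 >= 0.15
  } else {
    fvc_prog <- (fvc0 - fvc12) >= 10
    dlco_prog <- (dlco0 - dlco12) >= 15
  }
  dlco_missing <- is.na(dlco_prog)
  out <- fvc_prog | (!dlco_missing & dlco_prog)
  attr(out, "dlco_missing") <- dlco_missing
  out
}

#' Specification for a proportional-hazards cohort simulation
#'
#' Event times are exponential with rate `baseline_rate * exp(beta' x)`;
#' censoring is uniform on `[0, censor_max]` (administrative window).
#'
#' @param n cohort size (>= 2).
#' @param betas named numeric vector of true log hazard ratios.
#' @param covariates optional named list of generator functions `f(n)`;
#'   defaults to standard normal draws per covariate in `betas`.
#' @param baseline_rate exponential baseline hazard (> 0).
#' @param censor_max administrative censoring window upper bound.
#' @param seed RNG seed.
#' @return A `sim_spec`.
#' @export
sim_spec <- function(n, betas = c(x = 0), covariates = NULL,
                     baseline_rate = 0.2, censor_max = 10, seed = 1L) {
  if (n < 2) airtree_error("n must be >= 2", "airtree_bad_spec")
  if (baseline_rate <= 0) airtree_error("baseline_rate must be > 0", "airtree_bad_spec")
  if (is.null(names(betas)) || any(names(betas) == ""))
    airtree_error("betas must be a named vector", "airtree_bad_spec")
  structure(list(n = as.integer(n), betas = betas, covariates = covariates,
                 baseline_rate = baseline_rate, censor_max = censor_max,
                 seed = as.integer(seed)), class = "sim_spec")
}

#' Simulate a proportional-hazards cohort
#'
#' @param spec a [sim_spec()].
#' @return A `cohort` data frame with `id`, `time`, `event` and one column
#'   per covariate. Deterministic given `spec$seed`.
#' @export
simulate_cohort <- function(spec) {
  with_seed(spec$seed, function() {
    nm <- names(spec$betas)
    X <- sapply(nm, function(v) {
      gen <- spec$covariates[[v]]
      if (is.null(gen)) rnorm(spec$n) else gen(spec$n)
    })
    X <- matrix(X, nrow = spec$n, dimnames = list(NULL, nm))
    lp <- as.vector(X %*% spec$betas)
    t_event <- rexp(spec$n, rate = spec$baseline_rate * exp(lp))
    t_cens <- runif(spec$n, 0, spec$censor_max)
    df <- data.frame(id = seq_len(spec$n),
                     time = pmin(t_event, t_cens),
                     event = as.numeric(t_event <= t_cens))
    for (v in nm) df[[v]] <- X[, v]
    as_cohort(df)
  })
}

#' C-index increment from adding a covariate
#'
#' Fits Cox models on the base covariates and on base + added covariate,
#' scores both by their linear predictors and reports Harrell's C for each
#' together with the increment.
#'
#' @param cohort a cohort data frame.
#' @param base character vector of base covariate names.
#' @param added name of the covariate to add.
#' @return list with `c_base`, `c_with`, `delta`, and both fits.
#' @export
cindex_increment <- function(cohort, base, added) {
  fit_base <- fit_cox(cohort, base)
  fit_with <- fit_cox(cohort, c(base, added))
  lp_base <- as.vector(as.matrix(cohort[base]) %*% fit_base$table$log_hr)
  lp_with <- as.vector(as.matrix(cohort[c(base, added)]) %*% fit_with$table$log_hr)
  c_base <- as.numeric(harrell_c(cohort, lp_base))
  c_with <- as.numeric(harrell_c(cohort, lp_with))
  list(c_base = c_base, c_with = c_with, delta = c_with - c_base,
       fit_base = fit_base, fit_with = fit_with)
}

#' Tertile risk-strata analysis of a biomarker
#'
#' Cuts the biomarker into low/medium/high tertile groups, estimates
#' Kaplan-Meier curves, tests survival differences by log-rank, and fits a
#' Cox model of the strata with the low-risk group as reference.
#'
#' @param cohort a cohort data frame.
#' @param values biomarker values aligned with the cohort rows.
#' @return list with `groups`, `km`, `logrank`, and `hr_table` (hazard
#'   ratios of medium and high vs low).
#' @export
strata_analysis <- function(cohort, values) {
  g <- tertile_groups(values)
  km <- km_estimate(cohort, g)
  lr <- logrank_test(cohort, g)
  df <- data.frame(time = cohort$time, event = cohort$event,
                   medium = as.numeric(g == "medium"),
                   high = as.numeric(g == "high"))
  fit <- fit_cox(df, c("medium", "high"))
  list(groups = g, km = km, logrank = lr, hr_table = fit$table)
}
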