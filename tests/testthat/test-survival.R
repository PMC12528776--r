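toy_cohort <- function() {
  as_cohort(data.frame(id = 1:4, time = c(1, 2, 3, 4),
                       event = c(1, 1, 1, 0), x = c(1, 0, 1, 0)))
}

test_that("Cox log-hazard matches the brute-force partial-likelihood oracle", {
  co <- toy_cohort()
  fit <- fit_cox(co, "x")
  ll <- oracle_cox_loglik(co$time, co$event, co$x)
  opt <- optimize(ll, c(-5, 5), maximum = TRUE, tol = 1e-8)
  expect_equal(fit$table$log_hr, opt$maximum, tolerance = 1e-4)
  expect_equal(fit$loglik, opt$objective, tolerance = 1e-6)
  expect_equal(fit$table$hr, exp(fit$table$log_hr))
  expect_true(fit$table$ci_lower < fit$table$hr &
                fit$table$hr < fit$table$ci_upper)
})

test_that("duplicating every record leaves the Cox point estimate unchanged", {
  # exact under Breslow tie handling (the partial likelihood is proportional);
  # Efron's tie correction intentionally treats the duplicated events as ties
  co <- toy_cohort()
  co2 <- as_cohort(rbind(co, transform(co, id = id + 4)))
  f1 <- fit_cox(co, "x", ties = "breslow")
  f2 <- fit_cox(co2, "x", ties = "breslow")
  expect_equal(f1$table$log_hr, f2$table$log_hr, tolerance = 1e-6)
})

test_that("degenerate Cox inputs raise distinct errors", {
  co <- toy_cohort()
  co$z <- 1
  expect_error(fit_cox(co, "z"), class = "airtree_bad_covariate")
  co1 <- as_cohort(data.frame(id = 1:4, time = 1:4, event = c(1, 0, 0, 0),
                              x = rnorm(4)))
  expect_error(fit_cox(co1, "x"), class = "airtree_too_few_events")
})

test_that("Kaplan-Meier matches the hand product-limit and handles censoring", {
  co <- as_cohort(data.frame(id = 1:3, time = c(1, 2, 3), event = 1))
  km <- km_estimate(co)
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # no events -> survival identically 1
  co0 <- as_cohort(data.frame(id = 1:3, time = c(1, 2, 3), event = 0))
  expect_true(all(km_estimate(co0)$surv == 1))
  # all censored after the first event -> curve constant thereafter
  co2 <- as_cohort(data.frame(id = 1:4, time = c(1, 2, 3, 4),
                              event = c(1, 0, 0, 0)))
  km2 <- km_estimate(co2)
  expect_equal(km2$surv[km2$time >= 1], rep(3 / 4, 4))
})

test_that("KM equals the empirical survivor function without censoring", {
  set.seed(3)
  t <- round(rexp(40, 0.3), 2) + 0.01
  co <- as_cohort(data.frame(id = 1:40, time = t, event = 1))
  km <- km_estimate(co)
  emp <- vapply(km$time, function(u) mean(t > u), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("log-rank is near zero for identical groups and matches its null", {
  co <- as_cohort(data.frame(id = 1:20, time = rep(1:10, 2), event = 1))
  g <- rep(c("a", "b"), each = 10)
  lr <- logrank_test(co, g)
  expect_lt(lr$statistic, 1e-9)
  expect_equal(lr$df, 1L)
  # permutation oracle on a small two-group cohort
  set.seed(9)
  co2 <- as_cohort(data.frame(id = 1:24, time = rexp(24) + 0.01,
                              event = rbinom(24, 1, 0.8)))
  g2 <- rep(c("a", "b"), 12)
  obs <- logrank_test(co2, g2)$statistic
  perm <- replicate(300, logrank_test(co2, sample(g2))$statistic)
  p_perm <- mean(perm >= obs)
  expect_lt(abs(logrank_test(co2, g2)$p - p_perm), 0.12)
})

test_that("Harrell's C hits the concordant / reversed / random anchors", {
  set.seed(5)
  t <- runif(300) + 0.01
  co <- as_cohort(data.frame(id = seq_along(t), time = t, event = 1))
  expect_equal(as.numeric(harrell_c(co, -t)), 1.0)
  expect_equal(as.numeric(harrell_c(co, t)), 0.0)
  expect_lt(abs(as.numeric(harrell_c(co, rnorm(300))) - 0.5), 0.05)
  # invariance under strictly monotone transforms of the risk score
  r <- rnorm(300)
  expect_equal(as.numeric(harrell_c(co, r)),
               as.numeric(harrell_c(co, exp(r))))
})

test_that("time-dependent AUC: perfect marker, null marker, oracle reduction", {
  set.seed(11)
  t <- sort(runif(80)) + 0.01
  co <- as_cohort(data.frame(id = seq_along(t), time = t, event = 1))
  expect_equal(as.numeric(time_dependent_auc(co, -t, median(t))), 1.0)
  # uncensored case reduces to the empirical ROC AUC
  m <- rnorm(80)
  h <- median(t)
  expect_equal(as.numeric(time_dependent_auc(co, m, h)),
               oracle_empirical_auc(t, m, h), tolerance = 1e-12)
  expect_error(time_dependent_auc(co, m, max(t) + 1), class = "airtree_no_controls")
  expect_error(time_dependent_auc(co, m, min(t) / 2), class = "airtree_no_cases")
})

test_that("Schoenfeld residuals sum to zero and detect a time-varying effect", {
  spec <- sim_spec(300, betas = c(x = 0.5), baseline_rate = 0.3,
                   censor_max = 8, seed = 21L)
  co <- simulate_cohort(spec)
  fit <- fit_cox(co, "x")
  res <- residuals(fit$model, type = "schoenfeld")
  expect_lt(abs(sum(res)), 1e-6)
  tab <- schoenfeld_ph_check(fit)
  expect_true(is.finite(tab$p))
  # strong sign-flip effect: simulate piecewise hazard by editing events
  set.seed(22)
  n <- 400
  x <- rnorm(n)
  t1 <- rexp(n, 0.5 * exp(1.5 * x))     # early: strong positive effect
  t2 <- 1 + rexp(n, 0.5 * exp(-1.5 * x))  # late: strong negative effect
  tm <- ifelse(t1 < 1, t1, t2)
  co2 <- as_cohort(data.frame(id = 1:n, time = tm, event = 1, x = x))
  p2 <- schoenfeld_ph_check(fit_cox(co2, "x"))$p
  expect_lt(p2, 0.01)
})

test_that("progression labels follow both decline conventions", {
  # relative: 80 -> 72 is exactly a 10% decline -> progressed
  expect_true(progression_label(80, 72, 60, 60))
  expect_false(progression_label(80, 75, 60, 60))
  # DLCO route: 50 -> 40 is a 20% decline
  expect_true(progression_label(80, 76, 50, 40))
  # absolute-points convention
  expect_true(progression_label(80, 70, NA, NA, mode = "absolute"))
  expect_false(progression_label(80, 72, 60, 60, mode = "absolute"))
  out <- progression_label(c(80, 80), c(79, 79), c(NA, 50), c(NA, 20))
  expect_equal(as.vector(out), c(FALSE, TRUE))
  expect_equal(attr(out, "dlco_missing"), c(TRUE, FALSE))
})

test_that("cohort simulation is seeded and recovers the null", {
  spec <- sim_spec(500, betas = c(x = 0), seed = 7L)
  co <- simulate_cohort(spec)
  expect_identical(co, simulate_cohort(spec))
  expect_true(all(co$time > 0))
  expect_true(all(co$event %in% c(0, 1)))
  big <- simulate_cohort(sim_spec(2000, betas = c(x = 0), seed = 8L))
  fit <- fit_cox(big, "x")
  expect_lt(abs(fit$table$log_hr), 0.1)
})

test_that("C-index increments separate informative from noise covariates", {
  spec <- sim_spec(400, betas = c(driver = log(2), base = 0.3),
                   baseline_rate = 0.2, censor_max = 12, seed = 31L)
  co <- simulate_cohort(spec)
  set.seed(32)
  co$noise <- rnorm(nrow(co))
  inc_noise <- cindex_increment(co, c("base", "driver"), "noise")
  expect_lt(abs(inc_noise$delta), 0.02)
  inc_driver <- cindex_increment(co, "base", "driver")
  expect_gt(inc_driver$delta, 0.05)
})

test_that("strata analysis wires tertiles, log-rank and hazard ratios together", {
  spec <- sim_spec(300, betas = c(spav = log(1.6)), baseline_rate = 0.15,
                   censor_max = 10, seed = 41L)
  co <- simulate_cohort(spec)
  sa <- strata_analysis(co, co$spav)
  expect_s3_class(sa$groups, "factor")
  expect_lt(sa$logrank$p, 0.05)
  hr_high <- sa$hr_table$hr[sa$hr_table$covariate == "high"]
  expect_gt(hr_high, 1)
})
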