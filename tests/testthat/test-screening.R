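test_that("univariable Cox matches the brute-force partial-likelihood grid search", {
  fx <- surv_fixture(n = 30, seed = 13)
  res <- fit_univariable_cox(fx$risk, fx$time, fx$event, name = "x")
  beta_grid <- bf_cox_grid(fx$risk, fx$time, fx$event)
  expect_lt(abs(log(res$hr) - beta_grid), 2e-3)
  ## CI contains the HR and the HR is positive
  expect_true(res$ci_lower <= res$hr && res$hr <= res$ci_upper)
  expect_gt(res$hr, 0)
})

test_that("negating a covariate reciprocates the hazard ratio", {
  fx <- surv_fixture(n = 40, seed = 21)
  hr_pos <- fit_univariable_cox(fx$risk, fx$time, fx$event)$hr
  hr_neg <- fit_univariable_cox(-fx$risk, fx$time, fx$event)$hr
  expect_equal(hr_pos * hr_neg, 1, tolerance = 1e-8)
})

test_that("a covariate independent of outcome has near-zero log HR at n = 2000", {
  set.seed(31)
  x <- rnorm(2000)
  st <- generate_survival_times(rep(0, 2000), seed = 7)
  res <- fit_univariable_cox(x, st$time_months, st$event)
  expect_lt(abs(log(res$hr)), 0.1)
})

test_that("a simulated binary covariate with true HR 2.37 is recovered", {
  set.seed(41)
  x <- rbinom(5000, 1, 0.18)
  st <- generate_survival_times(log(2.37) * x, seed = 9)
  res <- fit_univariable_cox(x, st$time_months, st$event)
  expect_true(res$hr >= 2.1 && res$hr <= 2.7)
})

test_that("degenerate covariates are rejected with informative errors", {
  fx <- surv_fixture(n = 20, seed = 2)
  expect_error(fit_univariable_cox(rep(1, 20), fx$time, fx$event), "constant")
  expect_error(fit_univariable_cox(fx$risk, fx$time, c(rep(0, 19), 1)), "events")
})

test_that("the log-rank test matches brute-force observed-minus-expected", {
  fx <- surv_fixture(n = 24, seed = 8)
  grp <- rep(c("a", "b"), each = 12)
  lr <- logrank_test(grp, fx$time, fx$event)

  ## brute force over the pooled event times
  O <- E <- V <- 0
  for (t in sort(unique(fx$time[fx$event == 1]))) {
    at_risk <- fx$time >= t
    d <- sum(fx$time == t & fx$event == 1)
    n_tot <- sum(at_risk); n_a <- sum(at_risk & grp == "a")
    d_a <- sum(fx$time == t & fx$event == 1 & grp == "a")
    O <- O + d_a
    E <- E + d * n_a / n_tot
    if (n_tot > 1) {
      V <- V + d * (n_a / n_tot) * (1 - n_a / n_tot) * (n_tot - d) / (n_tot - 1)
    }
  }
  expect_equal(lr$chisq, (O - E)^2 / V, tolerance = 1e-10)

  ## identical survival in the duplicated two-group setting
  lr0 <- logrank_test(rep(c("a", "b"), times = 24),
                      rep(fx$time, each = 2), rep(fx$event, each = 2))
  expect_lt(lr0$chisq, 1e-10)
  expect_gt(lr0$p_value, 0.999)
  expect_error(logrank_test(rep("a", 24), fx$time, fx$event), "2 groups")
})

test_that("log-rank p agrees with the Cox score test for a binary covariate", {
  fx <- surv_fixture(n = 30, seed = 44)
  grp <- rep(c(0, 1), 15)
  lr <- logrank_test(grp, fx$time, fx$event)
  sc <- summary(survival::coxph(
    survival::Surv(fx$time, fx$event) ~ grp))$sctest["pvalue"]
  expect_lt(abs(lr$p_value - sc), 0.01)
})

test_that("Kaplan-Meier reproduces the hand-computed product limit", {
  time <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  event <- c(1, 1, 0, 1, 0, 1, 1, 0, 1, 0)
  km <- kaplan_meier(time, event)
  ## product-limit by hand: drops at 1,2,4,6,7,9 with risk sets 10,9,7,5,4,2
  s_hand <- cumprod(1 - 1 / c(10, 9, 7, 5, 4, 2))
  expect_equal(summary(km$fit, times = c(1, 2, 4, 6, 7, 9))$surv, s_hand)
  ## median: first time S(t) <= 0.5 (S(6) = 0.549, S(7) = 0.411)
  expect_equal(km$median, 7)
  ## no censoring: S(t) equals the empirical survival fraction
  km2 <- kaplan_meier(time, rep(1, 10))
  expect_equal(summary(km2$fit, times = time)$surv, 1 - (1:10) / 10)
  ## all censored: flat at 1, median not reached
  km3 <- kaplan_meier(time, rep(0, 10))
  expect_true(all(km3$fit$surv == 1))
  expect_true(is.na(km3$median))
  ## survival probability at a time point comes with a CI
  s2 <- km$surv_at(5)
  expect_true(s2$ci_lower <= s2$surv && s2$surv <= s2$ci_upper)
})

test_that("the candidate filter applies a strict p < 0.100 rule per variable", {
  mock <- structure(data.frame(), min_p = c(clinA = 0.0999, radB = 0.100,
                                            radC = 0.0015, clinD = 0.69))
  sets <- filter_candidates(mock, clinical_vars = c("clinA", "clinD"))
  expect_equal(sets$full, c("clinA", "radC"))
  expect_equal(sets$clinicopathological, "clinA")
})

test_that("a categorical variable is kept when any level crosses the threshold", {
  ## two levels at p = 0.69 and p = 0.0015: minimum per-level p decides
  set.seed(3)
  n <- 300
  x <- factor(sample(0:2, n, replace = TRUE))
  lp <- ifelse(x == 2, 1.0, ifelse(x == 1, 0.02, 0))
  st <- generate_survival_times(lp, seed = 5)
  sc <- univariable_screen(data.frame(v = x), st$time_months, st$event, "v")
  expect_equal(length(attr(sc, "min_p")), 1L)
  expect_equal(attr(sc, "min_p")[["v"]], min(sc$p_wald))
  sets <- filter_candidates(sc, clinical_vars = "v")
  expect_equal(sets$full, "v")
})

test_that("correlation pruning follows the priority rules", {
  set.seed(19)
  n <- 80
  base <- rnorm(n)
  dat <- data.frame(
    clin = base + rnorm(n, 0, 0.1),          # clinicopathological
    radA = base + rnorm(n, 0, 0.05),         # correlated with clin
    radB = rnorm(n),
    radC = NA
  )
  dat$radC <- dat$radB + rnorm(n, 0, 0.05)   # rad-rad correlated pair
  min_p <- c(clin = 0.04, radA = 0.001, radB = 0.01, radC = 0.03)
  out <- prune_correlated(c("clin", "radA", "radB", "radC"), dat, min_p,
                          clinical_vars = "clin")
  ## radiomics dropped against clinicopathological regardless of p;
  ## among rad-rad the higher univariable p is dropped
  expect_setequal(as.character(out), c("clin", "radB"))
  dropped <- attr(out, "dropped")
  expect_true("radA" %in% dropped$dropped)
  expect_true("radC" %in% dropped$dropped)
})

test_that("mutually independent variables are rarely pruned", {
  ## type-I behaviour of the pruning step: one independent pair at n = 500
  ## should survive intact in ~95% of draws
  drops <- vapply(1:40, function(s) {
    set.seed(s)
    dat <- data.frame(radA = rnorm(500), radB = rnorm(500))
    out <- prune_correlated(c("radA", "radB"), dat,
                            c(radA = 0.01, radB = 0.05),
                            clinical_vars = character(0))
    2L - length(out)
  }, numeric(1))
  expect_gte(mean(drops == 0), 0.85)
})
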