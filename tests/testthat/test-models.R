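## Shared fixture: linear-hazard simulation with one strong covariate.
model_fixture <- function(n = 200, seed = 1, beta = c(0.8, 0, 0, 0)) {
  ipithsurv:::with_seed(seed, {
    x <- matrix(rnorm(n * length(beta)), n,
                dimnames = list(NULL, paste0("v", seq_along(beta))))
    st <- generate_survival_times(as.numeric(x %*% beta),
                                  seed = seed + 1000L)
    list(x = x, time = st$time_months, event = st$event)
  })
}

test_that("one-hot encoding drops the reference level and round-trips", {
  df <- data.frame(ps = factor(c(0, 1, 2, 1), levels = 0:2),
                   sex = c("f", "m", "m", "f"),
                   age = c(60, 70, 55, 65))
  enc <- one_hot_encode(df)
  expect_equal(colnames(enc$x), c("ps=1", "ps=2", "sex=m", "age"))
  expect_equal(enc$x[, "ps=1"], c(0, 1, 0, 1))
  expect_equal(enc$x[, "ps=2"], c(0, 0, 1, 0))  # reference ps = 0 implicit
  back <- one_hot_decode(enc$x, enc$map)
  expect_equal(as.character(back$ps), as.character(df$ps))
  expect_equal(back$age, df$age)
  ## unseen level at prediction time is an error naming the level
  expect_error(one_hot_encode(data.frame(ps = "3", sex = "m", age = 1),
                              map = enc$map), "3")
})

test_that("all five learners satisfy the survival-function contract", {
  fx <- model_fixture(n = 150, seed = 5)
  times <- seq(0, 24, by = 3)
  specs <- list(
    model_spec("stepwise_cox"),
    model_spec("lasso_cox"),
    model_spec("rsf", list(num_trees = 200L)),
    model_spec("gbm", list(n_trees = 200L)),
    model_spec("deepsurv", list(epochs = 40L, l2_reg = 1))
  )
  for (sp in specs) {
    fit <- fit_survival_model(sp, fx$x, fx$time, fx$event)
    r <- predict_risk(fit, fx$x)
    expect_true(all(is.finite(r)), info = sp$model)
    S <- predict_survival(fit, fx$x[1:5, , drop = FALSE], times)
    expect_equal(unname(S[, 1]), rep(1, 5), info = sp$model)   # S(0|x) = 1
    expect_true(all(apply(S, 1, function(s) all(diff(s) <= 1e-9))),
                info = sp$model)                               # nonincreasing
    ## orientation: higher true hazard -> higher mean predicted risk
    hi <- fx$x[, 1] > median(fx$x[, 1])
    expect_gt(mean(r[hi]), mean(r[!hi]))
  }
})

test_that("backward stepwise selection minimizes AIC like the all-subsets oracle", {
  fx <- model_fixture(n = 120, seed = 9, beta = c(0.9, 0.5, 0))
  fit <- fit_stepwise_cox(fx$x, fx$time, fx$event)

  ## brute force over all 8 subsets, following the backward path
  aic_of <- function(vars) AIC(ipithsurv:::cox_on(fx$x, fx$time, fx$event, vars))
  vars <- colnames(fx$x)
  repeat {
    if (length(vars) == 0) break
    cand <- vapply(vars, function(v) aic_of(setdiff(vars, v)), numeric(1))
    if (min(cand) >= aic_of(vars)) break
    vars <- setdiff(vars, names(cand)[which.min(cand)])
  }
  expect_setequal(fit$variables, vars)
  ## AIC of the final model never exceeds the full model's
  expect_lte(tail(fit$trace$aic, 1), fit$trace$aic[1])
})

test_that("stepwise retains a true covariate and discards pure noise", {
  keeps <- vapply(1:5, function(s) {
    fx <- model_fixture(n = 500, seed = s, beta = c(0.7, 0, 0, 0, 0, 0))
    "v1" %in% fit_stepwise_cox(fx$x, fx$time, fx$event)$variables
  }, logical(1))
  expect_gte(mean(keeps), 0.8)
})

test_that("LASSO Cox shrinks fully at large lambda and matches Cox at lambda = 0", {
  fx <- model_fixture(n = 250, seed = 3, beta = c(0.8, -0.5, 0))
  big <- fit_lasso_cox(fx$x, fx$time, fx$event, lambda = 50)
  expect_true(all(big$coefficients == 0))
  expect_equal(var(predict_risk(big, fx$x)), 0)

  free <- fit_lasso_cox(fx$x, fx$time, fx$event, lambda = 0)
  cph <- survival::coxph(survival::Surv(fx$time, fx$event) ~ fx$x)
  expect_equal(unname(free$coefficients), unname(coef(cph)), tolerance = 1e-3)

  ## nonzero count is nonincreasing along an increasing lambda path
  nz <- vapply(c(0, 0.01, 0.05, 0.1, 0.5, 2), function(l) {
    sum(fit_lasso_cox(fx$x, fx$time, fx$event, lambda = l)$coefficients != 0)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("the survival forest is seeded-deterministic and calibrated on noise", {
  fx <- model_fixture(n = 150, seed = 7, beta = c(0, 0, 0, 0))
  f1 <- fit_rsf(fx$x[1:100, ], fx$time[1:100], fx$event[1:100],
                num_trees = 300L, seed = 42)
  f2 <- fit_rsf(fx$x[1:100, ], fx$time[1:100], fx$event[1:100],
                num_trees = 300L, seed = 42)
  expect_equal(predict_risk(f1, fx$x[101:150, ]),
               predict_risk(f2, fx$x[101:150, ]))
  ## pure noise: out-of-sample c-index near 0.5
  c_null <- harrell_cindex(predict_risk(f1, fx$x[101:150, ]),
                           fx$time[101:150], fx$event[101:150])
  expect_lt(abs(c_null - 0.5), 0.08)
  expect_error(fit_rsf(fx$x, fx$time, fx$event, mtry = 99), "mtry")
})

test_that("the survival forest detects a strong covariate out of sample", {
  fx <- model_fixture(n = 300, seed = 11, beta = c(log(3), 0, 0))
  tr <- 1:200; te <- 201:300
  fit <- fit_rsf(fx$x[tr, ], fx$time[tr], fx$event[tr], seed = 2,
                 num_trees = 500L)
  expect_gt(harrell_cindex(predict_risk(fit, fx$x[te, ]),
                           fx$time[te], fx$event[te]), 0.65)
})

test_that("Cox boosting is deterministic, learns monotonically, and nulls at 0.5", {
  fx <- model_fixture(n = 200, seed = 13, beta = c(1, 0, 0))
  g1 <- fit_gbm(fx$x, fx$time, fx$event, n_trees = 150L, seed = 4)
  g2 <- fit_gbm(fx$x, fx$time, fx$event, n_trees = 150L, seed = 4)
  expect_equal(predict_risk(g1, fx$x), predict_risk(g2, fx$x))

  ## training concordance grows over the first trees (depth 1, small rate)
  cis <- vapply(c(5, 25, 50), function(k) {
    f <- fit_gbm(fx$x, fx$time, fx$event, shrinkage = 0.01, depth = 1L,
                 n_trees = k, seed = 4)
    harrell_cindex(predict_risk(f, fx$x), fx$time, fx$event)
  }, numeric(1))
  expect_true(all(diff(cis) > 0))

  fx0 <- model_fixture(n = 150, seed = 15, beta = c(0, 0, 0))
  f0 <- fit_gbm(fx0$x[1:100, ], fx0$time[1:100], fx0$event[1:100], seed = 1)
  c0 <- harrell_cindex(predict_risk(f0, fx0$x[101:150, ]),
                       fx0$time[101:150], fx0$event[101:150])
  expect_lt(abs(c0 - 0.5), 0.1)
  expect_error(fit_gbm(fx$x, fx$time, fx$event, shrinkage = 0), "positive")
})
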