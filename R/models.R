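## The five survival learners behind one common contract:
##   fit_survival_model(spec, x, time, event) -> `survival_fit`
##   predict_risk(fit, newdata)               -> higher = worse
##   predict_survival(fit, newdata, times)    -> S(t|x) matrix, S(0|x) = 1

#' One-hot encode a mixed patient table
#'
#' Factors and character columns become indicator columns with the reference
#' (first) level dropped for identifiability; numeric columns pass through.
#' The encoding map is returned so new data can be encoded identically; an
#' unseen level at prediction time is an error naming the level.
#'
#' @param data Data.frame.
#' @param map Optional encoding map from a previous call (training map).
#' @return List with `x` (numeric matrix) and `map` (per-variable levels).
#' @export
one_hot_encode <- function(data, map = NULL) {
  data <- as.data.frame(data)
  if (is.null(map)) {
    map <- lapply(data, function(col) {
      if (is.factor(col)) levels(col)
      else if (is.character(col)) sort(unique(col))
      else NULL
    })
  }
  cols <- lapply(names(data), function(nm) {
    col <- data[[nm]]
    lev <- map[[nm]]
    if (is.null(lev)) {
      m <- matrix(as.numeric(col), ncol = 1,
                  dimnames = list(NULL, nm))
    } else {
      vals <- as.character(col)
      unseen <- setdiff(unique(vals), lev)
      if (length(unseen) > 0) {
        stop("unseen level(s) in `", nm, "`: ", paste(unseen, collapse = ", "))
      }
      ref_dropped <- lev[-1]
      m <- sapply(ref_dropped, function(l) as.numeric(vals == l))
      m <- matrix(m, ncol = length(ref_dropped),
                  dimnames = list(NULL, paste0(nm, "=", ref_dropped)))
    }
    m
  })
  list(x = do.call(cbind, cols), map = map)
}

#' Decode a one-hot matrix back to the original columns
#' @param x Encoded matrix.
#' @param map Encoding map from [one_hot_encode()].
#' @return Data.frame with the original columns.
#' @export
one_hot_decode <- function(x, map) {
  out <- list()
  for (nm in names(map)) {
    lev <- map[[nm]]
    if (is.null(lev)) {
      out[[nm]] <- as.numeric(x[, nm])
    } else {
      ind <- x[, paste0(nm, "=", lev[-1]), drop = FALSE]
      idx <- apply(ind, 1, function(r) {
        j <- which(r == 1)
        if (length(j) == 0) 1L else j + 1L
      })
      out[[nm]] <- factor(lev[idx], levels = lev)
    }
  }
  as.data.frame(out, check.names = FALSE)
}

## ---------------------------------------------------------------------------
## Breslow baseline: risk scores -> survival curves
## ---------------------------------------------------------------------------

## Nonparametric cumulative baseline hazard from training risk scores.
breslow_baseline <- function(time, event, risk) {
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; r_s <- exp(risk[ord])
  ut <- unique(t_s[e_s == 1])
  if (length(ut) == 0L) {
    return(list(times = 0, cumhaz = 0))
  }
  ## risk-set sums: total - cumulative sum of exp(risk) for subjects with t < t_k
  h0 <- vapply(ut, function(tk) {
    d <- sum(e_s == 1 & t_s == tk)
    d / sum(r_s[t_s >= tk])
  }, numeric(1))
  list(times = ut, cumhaz = cumsum(h0))
}

## Evaluate S(t|x) = exp(-H0(t) exp(s)) on a time grid.
breslow_survival <- function(baseline, risk, times) {
  H0 <- approx(c(0, baseline$times), c(0, baseline$cumhaz), xout = times,
               method = "constant", rule = 2, f = 0)$y
  out <- exp(-outer(exp(risk), H0))
  dimnames(out) <- list(NULL, paste0("t", times))
  out
}

## ---------------------------------------------------------------------------
## Model specs and generics
## ---------------------------------------------------------------------------

#' Survival model specification
#'
#' @param model One of `"stepwise_cox"`, `"lasso_cox"`, `"rsf"`, `"gbm"`,
#'   `"deepsurv"`.
#' @param hyperparameters Named list of model hyperparameters (see the
#'   individual `fit_*` functions for the grids).
#' @param seed Integer seed used by the stochastic learners.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(model = c("stepwise_cox", "lasso_cox", "rsf", "gbm",
                                 "deepsurv"),
                       hyperparameters = list(), seed = 1L) {
  model <- match.arg(model)
  structure(list(model = model, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Fit a survival learner under the common contract
#'
#' @param spec A [model_spec()].
#' @param x Numeric design matrix (one-hot encoded, scaled as appropriate).
#' @param time,event Survival outcome.
#' @return An object inheriting from `survival_fit` supporting
#'   [predict_risk()] and [predict_survival()].
#' @export
fit_survival_model <- function(spec, x, time, event) {
  stopifnot(inherits(spec, "model_spec"))
  hp <- spec$hyperparameters
  fit <- switch(spec$model,
    stepwise_cox = fit_stepwise_cox(x, time, event),
    lasso_cox = do.call(fit_lasso_cox,
                        c(list(x = x, time = time, event = event,
                               seed = spec$seed), hp)),
    rsf = do.call(fit_rsf, c(list(x = x, time = time, event = event,
                                  seed = spec$seed), hp)),
    gbm = do.call(fit_gbm, c(list(x = x, time = time, event = event,
                                  seed = spec$seed), hp)),
    deepsurv = {
      cfg <- do.call(deepsurv_config, c(list(seed = spec$seed), hp))
      fit_deepsurv(x, time, event, cfg)
    }
  )
  fit$spec <- spec
  fit
}

#' Predict risk scores (higher = worse) from a fitted survival model
#' @param object A `survival_fit`.
#' @param newdata Numeric design matrix with the training columns.
#' @param ... Unused.
#' @return Numeric vector of risk scores.
#' @export
predict_risk <- function(object, newdata, ...) UseMethod("predict_risk")

#' Predict survival curves S(t|x) from a fitted survival model
#' @inheritParams predict_risk
#' @param times Nonnegative time grid.
#' @return Matrix (subjects x times), nonincreasing in `t` with S(0|x) = 1.
#' @export
predict_survival <- function(object, newdata, times, ...) UseMethod("predict_survival")

#' @export
predict_survival.default <- function(object, newdata, times, ...) {
  breslow_survival(object$baseline, predict_risk(object, newdata), times)
}

## ---------------------------------------------------------------------------
## Stepwise-AIC Cox (benchmark model)
## ---------------------------------------------------------------------------

cox_on <- function(x, time, event, vars) {
  df <- data.frame(time = time, event = event)
  if (length(vars) == 0L) {
    return(survival::coxph(survival::Surv(time, event) ~ 1, data = df))
  }
  df <- cbind(df, as.data.frame(x[, vars, drop = FALSE], check.names = FALSE))
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", vars), collapse = " + ")
  ))
  suppressWarnings(survival::coxph(fml, data = df, ties = "efron"))
}

#' Backward stepwise Cox regression under AIC
#'
#' Starts from the full multivariable Cox model (Efron ties) and repeatedly
#' removes the design column whose removal most decreases the Akaike
#' information criterion, until no removal decreases it. Survival curves use
#' the Breslow baseline of the final model. With all columns removed the fit
#' degenerates to the null model (constant risk).
#'
#' @param x Numeric design matrix.
#' @param time,event Survival outcome (>= 10 events recommended).
#' @return Object of class `c("stepwise_cox_fit", "survival_fit")` with the
#'   retained `variables`, `coefficients`, and the AIC `trace`.
#' @export
fit_stepwise_cox <- function(x, time, event) {
  x <- as.matrix(x)
  vars <- colnames(x)
  fit <- cox_on(x, time, event, vars)
  aic <- AIC(fit)
  trace <- data.frame(step = 0L, dropped = NA_character_, aic = aic)
  repeat {
    if (length(vars) == 0L) break
    cand <- vapply(vars, function(v) {
      AIC(cox_on(x, time, event, setdiff(vars, v)))
    }, numeric(1))
    best <- which.min(cand)
    if (cand[best] >= aic) break
    vars <- setdiff(vars, vars[best])
    aic <- cand[best]
    fit <- cox_on(x, time, event, vars)
    trace <- rbind(trace, data.frame(step = nrow(trace),
                                     dropped = names(cand)[best], aic = aic))
  }
  risk <- if (length(vars) == 0L) rep(0, length(time))
          else as.numeric(x[, vars, drop = FALSE] %*% coef(fit))
  structure(
    list(variables = vars,
         coefficients = if (length(vars)) setNames(coef(fit), vars) else numeric(0),
         trace = trace,
         baseline = breslow_baseline(time, event, risk)),
    class = c("stepwise_cox_fit", "survival_fit")
  )
}

#' @export
predict_risk.stepwise_cox_fit <- function(object, newdata, ...) {
  if (length(object$variables) == 0L) return(rep(0, nrow(newdata)))
  as.numeric(as.matrix(newdata)[, object$variables, drop = FALSE] %*%
               object$coefficients)
}

## ---------------------------------------------------------------------------
## LASSO Cox
## ---------------------------------------------------------------------------

#' L1-penalized Cox regression
#'
#' Penalized Cox solution path via coordinate descent; when `lambda` is not
#' supplied it is chosen by seeded k-fold cross-validated partial likelihood
#' (`lambda.min`). Zero-coefficient variables are reported as excluded.
#'
#' @param x Standardized numeric design matrix.
#' @param time,event Survival outcome.
#' @param lambda Penalty; `NULL` for internal CV selection.
#' @param nlambda Length of the automatic log-spaced path.
#' @param nfolds Folds for the internal selection.
#' @param seed Seed for the internal fold assignment.
#' @return Object of class `c("lasso_cox_fit", "survival_fit")`.
#' @export
fit_lasso_cox <- function(x, time, event, lambda = NULL, nlambda = 50L,
                          nfolds = 5L, seed = 1L) {
  if (!is.null(lambda) && lambda < 0) stop("`lambda` must be nonnegative")
  x <- as.matrix(x)
  y <- survival::Surv(time, event)
  if (is.null(lambda)) {
    foldid <- with_seed(seed, sample(rep(seq_len(nfolds), length.out = nrow(x))))
    cv <- glmnet::cv.glmnet(x, y, family = "cox", nlambda = nlambda,
                            foldid = foldid)
    lambda <- cv$lambda.min
  }
  fit <- glmnet::glmnet(x, y, family = "cox", lambda = lambda)
  beta <- as.numeric(coef(fit))
  names(beta) <- rownames(coef(fit))
  risk <- as.numeric(x %*% beta)
  structure(
    list(coefficients = beta, lambda = lambda,
         excluded = names(beta)[beta == 0],
         baseline = breslow_baseline(time, event, risk)),
    class = c("lasso_cox_fit", "survival_fit")
  )
}

#' @export
predict_risk.lasso_cox_fit <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata)[, names(object$coefficients), drop = FALSE] %*%
               object$coefficients)
}

## ---------------------------------------------------------------------------
## Random survival forest (ranger backend)
## ---------------------------------------------------------------------------

#' Random survival forest
#'
#' 1000-tree log-rank-split survival forest (ranger backend). The risk score
#' is the total ensemble cumulative hazard (higher = worse); survival curves
#' are the tree-averaged survival functions carried onto the requested grid.
#'
#' @param x Numeric design matrix.
#' @param time,event Survival outcome.
#' @param mtry Variables tried per split (must not exceed `ncol(x)`).
#' @param nodesize Minimum terminal-node size.
#' @param num_trees Number of trees (default 1000).
#' @param seed Seed (single-threaded, deterministic).
#' @return Object of class `c("rsf_fit", "survival_fit")`.
#' @export
fit_rsf <- function(x, time, event, mtry = NULL, nodesize = 15L,
                    num_trees = 1000L, seed = 1L) {
  x <- as.matrix(x)
  if (!is.null(mtry) && mtry > ncol(x)) {
    stop("`mtry` exceeds the number of covariates")
  }
  df <- data.frame(time = time, event = event, x, check.names = TRUE)
  fit <- ranger::ranger(
    survival::Surv(time, event) ~ ., data = df,
    num.trees = num_trees, mtry = mtry, min.node.size = nodesize,
    splitrule = "logrank", seed = seed, num.threads = 1
  )
  structure(list(forest = fit, colmap = colnames(df)[-(1:2)],
                 orig_cols = colnames(x)),
            class = c("rsf_fit", "survival_fit"))
}

rsf_newdata <- function(object, newdata) {
  nd <- as.data.frame(as.matrix(newdata), check.names = TRUE)
  colnames(nd) <- make.names(object$orig_cols)
  nd
}

#' @export
predict_risk.rsf_fit <- function(object, newdata, ...) {
  pr <- predict(object$forest, data = rsf_newdata(object, newdata),
                num.threads = 1)
  rowSums(pr$chf)
}

#' @export
predict_survival.rsf_fit <- function(object, newdata, times, ...) {
  pr <- predict(object$forest, data = rsf_newdata(object, newdata),
                num.threads = 1)
  tt <- pr$unique.death.times
  out <- t(apply(pr$survival, 1, function(s) {
    approx(c(0, tt), c(1, s), xout = times, method = "constant",
           rule = 2, f = 0)$y
  }))
  dimnames(out) <- list(NULL, paste0("t", times))
  out
}

## ---------------------------------------------------------------------------
## Gradient-boosted Cox model (xgboost backend)
## ---------------------------------------------------------------------------

#' Gradient boosting with the Cox partial-likelihood loss
#'
#' 1000 sequential trees boosting the Cox partial-likelihood gradient
#' (xgboost `survival:cox` objective, single-threaded for determinism).
#' `mnotn` (minimum number of observations in terminal nodes) maps to
#' xgboost's hessian-weighted `min_child_weight`. Survival curves use the
#' Breslow baseline on the boosted log-risk scores.
#'
#' @param x Numeric design matrix.
#' @param time,event Survival outcome.
#' @param shrinkage Learning rate (> 0).
#' @param depth Interaction depth (max tree depth).
#' @param mnotn Minimum observations per terminal node.
#' @param n_trees Boosting rounds (default 1000).
#' @param seed Seed.
#' @return Object of class `c("gbm_fit", "survival_fit")`.
#' @export
fit_gbm <- function(x, time, event, shrinkage = 0.01, depth = 2L,
                    mnotn = 8L, n_trees = 1000L, seed = 1L) {
  if (shrinkage <= 0) stop("`shrinkage` must be positive")
  x <- as.matrix(x)
  ## xgboost cox convention: negative label magnitude = censored time
  label <- ifelse(event == 1, time, -time)
  dtrain <- xgboost::xgb.DMatrix(x, label = label, nthread = 1)
  params <- list(objective = "survival:cox", eta = shrinkage,
                 max_depth = depth, min_child_weight = mnotn,
                 nthread = 1, seed = seed)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = n_trees, verbose = 0)
  risk <- predict(booster, dtrain, outputmargin = TRUE)
  structure(
    list(booster = booster, cols = colnames(x),
         baseline = breslow_baseline(time, event, risk)),
    class = c("gbm_fit", "survival_fit")
  )
}

#' @export
predict_risk.gbm_fit <- function(object, newdata, ...) {
  nd <- xgboost::xgb.DMatrix(as.matrix(newdata)[, object$cols, drop = FALSE],
                             nthread = 1)
  predict(object$booster, nd, outputmargin = TRUE)
}
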