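## Event-stratified repeated k-fold cross-validation for survival learners.

#' Cross-validation plan
#'
#' @param repetitions Number of repeated partitionings (default 100).
#' @param folds Folds per repetition (default 5; at n = 140 each training
#'   partition has 112 patients and each test fold 28).
#' @param seed Base seed; repetition `r` uses a seed derived from it, so the
#'   whole rCV is reproducible from the base seed.
#' @return Object of class `cv_plan`.
#' @export
cv_plan <- function(repetitions = 100L, folds = 5L, seed = 1L) {
  stopifnot(repetitions >= 1, folds >= 2)
  structure(list(repetitions = as.integer(repetitions),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "cv_plan")
}

#' Event-stratified fold assignment
#'
#' Events and censored subjects are allocated to folds separately, so the
#' per-fold event count differs by at most 1 from proportional allocation
#' (the progression rate is the same in each partitioning). A draw leaving
#' any fold without events is re-drawn with the next seed.
#'
#' @param event Binary event vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold labels in `1..k`.
#' @export
stratified_event_folds <- function(event, k, seed) {
  for (try in 0:20) {
    fold <- with_seed(seed + try, {
      f <- integer(length(event))
      offset <- 0L
      for (g in unique(event)) {
        idx <- sample(which(event == g))
        ## continue the round-robin across strata so total fold sizes stay
        ## within 1 of n/k (exactly n/k when k divides n)
        f[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
        offset <- offset + length(idx)
      }
      perm <- sample(k)
      perm[f]
    })
    if (all(vapply(seq_len(k), function(j) sum(event[fold == j]) > 0, logical(1)))) {
      return(fold)
    }
  }
  stop("could not build folds with events in every fold")
}

## Leakage-safe preprocessing: numeric columns scaled with training-fold
## statistics; categorical columns one-hot encoded (level sets are data
## dictionary metadata, taken from the full table).
preprocess_fold <- function(data, variables, train_idx, map) {
  sub <- data[, variables, drop = FALSE]
  num <- names(sub)[vapply(sub, is.numeric, logical(1))]
  ctr <- scl <- NULL
  for (nm in num) {
    mu <- mean(sub[[nm]][train_idx])
    s <- sd(sub[[nm]][train_idx])
    sub[[nm]] <- (sub[[nm]] - mu) / (if (is.finite(s) && s > 0) s else 1)
  }
  one_hot_encode(sub, map = map)$x
}

fit_and_score <- function(spec, x, time, event, train_idx, test_idx,
                          brier_times = NULL, seed = NULL) {
  sp <- spec
  if (!is.null(seed)) sp$seed <- seed
  fit <- fit_survival_model(sp, x[train_idx, , drop = FALSE],
                            time[train_idx], event[train_idx])
  risk <- predict_risk(fit, x[test_idx, , drop = FALSE])
  ci <- harrell_cindex(risk, time[test_idx], event[test_idx])
  bs <- NULL
  if (!is.null(brier_times)) {
    G <- censoring_km(time[train_idx], event[train_idx])
    S <- predict_survival(fit, x[test_idx, , drop = FALSE], brier_times)
    bs <- vapply(seq_along(brier_times), function(j) {
      brier_score(S[, j], time[test_idx], event[test_idx], brier_times[j], G = G)
    }, numeric(1))
  }
  list(cindex = ci, brier = bs, fit = fit)
}

#' Repeated event-stratified cross-validation of a survival learner
#'
#' For each repetition, draws an event-stratified k-fold split (seeded from
#' the plan's base seed plus the repetition index), fits the model on k-1
#' folds with all preprocessing (covariate scaling, censoring distribution)
#' estimated on the training folds only, and evaluates Harrell's c-index
#' (and optionally an IPCW Brier curve) on the held-out fold. Fold results
#' are averaged per repetition.
#'
#' When `spec` is a list of [model_spec()]s (a hyperparameter grid), each
#' grid point is run through the full rCV and all results are returned, with
#' the best mean c-index flagged (`protocol = "grid_rcv"`, mirroring a single
#' reported configuration per model); `protocol = "nested"` instead selects a
#' grid point per training fold by an inner 3-fold c-index and reports the
#' unbiased outer estimate.
#'
#' @param data Patient-level data.frame (mixed numeric / factor columns).
#' @param time,event Survival outcome aligned with `data`.
#' @param variables Predictor columns to use (an input set).
#' @param spec A [model_spec()] or a list of them.
#' @param plan A [cv_plan()].
#' @param brier_times Optional time grid for Brier curves.
#' @param protocol Hyperparameter-selection protocol for grids.
#' @return Data.frame of class `cv_result`: one row per (model config,
#'   repetition) with `model`, `hyperparameters` (JSON), `repetition`,
#'   `cindex`; attribute `brier` holds the fold-averaged curves, attribute
#'   `best` the best configuration index for grids.
#' @export
repeated_stratified_cv <- function(data, time, event, variables, spec,
                                   plan = cv_plan(), brier_times = NULL,
                                   protocol = c("grid_rcv", "nested")) {
  protocol <- match.arg(protocol)
  specs <- if (inherits(spec, "model_spec")) list(spec) else spec
  stopifnot(all(vapply(specs, inherits, logical(1), "model_spec")))
  n <- nrow(data)
  if (n < 5 * plan$folds) warning("cohort small relative to the fold count")
  map <- one_hot_encode(data[, variables, drop = FALSE])$map

  run_one <- function(sp, tag) {
    rows <- vector("list", plan$repetitions)
    briers <- list()
    for (r in seq_len(plan$repetitions)) {
      fold_seed <- derive_seed(plan$seed, "folds", r)
      fold <- stratified_event_folds(event, plan$folds, fold_seed)
      cis <- numeric(plan$folds)
      bs_fold <- NULL
      for (f in seq_len(plan$folds)) {
        tr <- which(fold != f); te <- which(fold == f)
        x <- preprocess_fold(data, variables, tr, map)
        res <- fit_and_score(sp, x, time, event, tr, te, brier_times,
                             seed = derive_seed(plan$seed, tag, r * 100 + f))
        cis[f] <- res$cindex
        if (!is.null(res$brier)) {
          bs_fold <- rbind(bs_fold, res$brier)
        }
      }
      rows[[r]] <- data.frame(model = sp$model,
                              hyperparameters = jsonlite::toJSON(
                                sp$hyperparameters, auto_unbox = TRUE),
                              repetition = r, cindex = mean(cis))
      if (!is.null(bs_fold)) briers[[r]] <- colMeans(bs_fold)
    }
    out <- do.call(rbind, rows)
    attr(out, "brier") <- if (length(briers)) do.call(rbind, briers) else NULL
    out
  }

  if (protocol == "nested" && length(specs) > 1L) {
    return(nested_cv(data, time, event, variables, specs, plan, map))
  }

  parts <- lapply(seq_along(specs), function(i) run_one(specs[[i]], paste0("model", i)))
  out <- do.call(rbind, lapply(seq_along(parts), function(i) {
    cbind(config = i, parts[[i]])
  }))
  means <- vapply(parts, function(p) mean(p$cindex), numeric(1))
  structure(out, class = c("cv_result", "data.frame"),
            best = which.max(means),
            brier = attr(parts[[which.max(means)]], "brier"))
}

## Nested variant: inner 3-fold c-index selects the grid point per outer
## training fold; only the outer estimate is reported.
nested_cv <- function(data, time, event, variables, specs, plan, map) {
  rows <- vector("list", plan$repetitions)
  for (r in seq_len(plan$repetitions)) {
    fold <- stratified_event_folds(event, plan$folds,
                                   derive_seed(plan$seed, "folds", r))
    cis <- numeric(plan$folds)
    for (f in seq_len(plan$folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      x <- preprocess_fold(data, variables, tr, map)
      inner <- stratified_event_folds(event[tr], 3L,
                                      derive_seed(plan$seed, "inner", r * 10 + f))
      inner_ci <- vapply(specs, function(sp) {
        mean(vapply(1:3, function(g) {
          itr <- tr[inner != g]; ite <- tr[inner == g]
          fit_and_score(sp, x, time, event, itr, ite,
                        seed = derive_seed(plan$seed, "ifit", r))$cindex
        }, numeric(1)))
      }, numeric(1))
      best_sp <- specs[[which.max(inner_ci)]]
      cis[f] <- fit_and_score(best_sp, x, time, event, tr, te,
                              seed = derive_seed(plan$seed, "ofit", r * 100 + f))$cindex
    }
    rows[[r]] <- data.frame(model = specs[[1]]$model,
                            hyperparameters = "nested",
                            repetition = r, cindex = mean(cis))
  }
  structure(cbind(config = NA_integer_, do.call(rbind, rows)),
            class = c("cv_result", "data.frame"), best = NA_integer_)
}

#' Summarize a cv_result
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return Data.frame with per-configuration mean c-index and the 2.5/97.5
#'   percentile interval over repetitions.
#' @export
summary.cv_result <- function(object, ...) {
  sp <- split(object, object$config)
  do.call(rbind, lapply(sp, function(p) {
    q <- quantile(p$cindex, c(0.025, 0.975), names = FALSE)
    data.frame(config = p$config[1], model = p$model[1],
               hyperparameters = p$hyperparameters[1],
               mean_cindex = mean(p$cindex),
               ci_lower = q[1], ci_upper = q[2],
               repetitions = nrow(p))
  }))
}
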