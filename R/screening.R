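## Univariable survival screening and correlation pruning.

#' Univariable Cox regression for one covariate
#'
#' Fits a univariable Cox proportional-hazards model (Efron tie handling)
#' and reports the hazard ratio, Wald 95% confidence interval, and Wald
#' p-value; for categorical covariates, one row per non-reference level plus
#' the log-rank p-value across levels.
#'
#' @param x Numeric vector or factor.
#' @param time,event Survival outcome (months > 0; event 1 = progression).
#' @param name Variable name used in the output.
#' @param conf_level Confidence level (default 0.95).
#' @return Data.frame of class `univariable_result` with columns `variable`,
#'   `level`, `hr`, `ci_lower`, `ci_upper`, `p_wald`, `p_logrank`.
#' @export
fit_univariable_cox <- function(x, time, event, name = "x", conf_level = 0.95) {
  if (any(time <= 0) || any(!is.finite(time))) stop("times must be finite and positive")
  if (sum(event) < 2) stop("need at least 2 events")
  if (is.character(x)) x <- factor(x)
  if ((is.numeric(x) && sd(x) == 0) ||
      (is.factor(x) && nlevels(droplevels(x)) < 2)) {
    stop("constant covariate: ", name)
  }
  df <- data.frame(time = time, event = event, x = x)
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ x, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        stop("Cox fit did not converge for ", name,
             " (possible monotone likelihood / perfect separation)", call. = FALSE)
      }
      suppressWarnings(survival::coxph(survival::Surv(time, event) ~ x,
                                       data = df, ties = "efron"))
    }
  )
  z <- qnorm(1 - (1 - conf_level) / 2)
  s <- summary(fit)
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  p_lr <- if (is.factor(x)) logrank_test(x, time, event)$p_value else NA_real_
  lev <- if (is.factor(x)) sub("^x", "", names(beta)) else NA_character_
  structure(
    data.frame(variable = name,
               level = lev,
               hr = exp(beta),
               ci_lower = exp(beta - z * se),
               ci_upper = exp(beta + z * se),
               p_wald = 2 * pnorm(-abs(beta / se)),
               p_logrank = p_lr,
               row.names = NULL),
    class = c("univariable_result", "data.frame")
  )
}

#' Log-rank test for categorical group labels
#'
#' @param group Factor (or coercible) with >= 2 non-empty groups.
#' @param time,event Survival outcome.
#' @return List with `chisq`, `df`, and `p_value`.
#' @export
logrank_test <- function(group, time, event) {
  group <- droplevels(factor(group))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(fit$n) - 1L
  list(chisq = fit$chisq, df = df, p_value = pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Kaplan-Meier estimate with log-log confidence intervals
#'
#' @param time,event Survival outcome.
#' @param conf_level Confidence level.
#' @return List of class `km_estimate`: the `survfit` object, `median`
#'   (first time S(t) <= 0.5; `NA` = not reached), and `surv_at(t)` giving
#'   the survival probability and CI at time `t`.
#' @export
kaplan_meier <- function(time, event, conf_level = 0.95) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  med <- unname(summary(fit)$table["median"])
  surv_at <- function(t) {
    s <- summary(fit, times = t, extend = TRUE)
    data.frame(time = t, surv = s$surv, ci_lower = s$lower, ci_upper = s$upper)
  }
  structure(list(fit = fit, median = med, surv_at = surv_at),
            class = "km_estimate")
}

#' Run the univariable screen over a table of candidate variables
#'
#' @param data Data.frame holding the candidate columns.
#' @param time,event Survival outcome vectors (aligned with `data` rows).
#' @param variables Column names to screen.
#' @return A `univariable_result` data.frame (one row per variable level)
#'   plus attribute `min_p` (named per-variable minimum Wald p, the
#'   screening statistic for categorical variables).
#' @export
univariable_screen <- function(data, time, event, variables = names(data)) {
  res <- do.call(rbind, lapply(variables, function(v) {
    fit_univariable_cox(data[[v]], time, event, name = v)
  }))
  min_p <- vapply(split(res$p_wald, res$variable), min, numeric(1))[unique(res$variable)]
  structure(res, min_p = min_p, class = c("univariable_result", "data.frame"))
}

#' Candidate filter at the univariable screening threshold
#'
#' Keeps variables whose univariable Cox p-value is strictly below the
#' threshold (for categorical variables, the minimum per-level Wald p), and
#' partitions the survivors by provenance into the `clinicopathological` and
#' `full` model inputs.
#'
#' @param screen A result of [univariable_screen()].
#' @param clinical_vars Names of clinicopathological variables (everything
#'   else counts as radiomics-based).
#' @param threshold Strict p-value cutoff (default 0.100).
#' @return List of class `input_sets` with `full` and `clinicopathological`
#'   character vectors (screen order preserved).
#' @export
filter_candidates <- function(screen, clinical_vars, threshold = 0.100) {
  min_p <- attr(screen, "min_p")
  kept <- names(min_p)[min_p < threshold]
  structure(
    list(full = kept,
         clinicopathological = kept[kept %in% clinical_vars],
         threshold = threshold),
    class = "input_sets"
  )
}

## Numeric encoding for Spearman correlation: factors -> integer codes.
spearman_numeric <- function(x) {
  if (is.factor(x) || is.character(x)) as.numeric(factor(x)) else as.numeric(x)
}

#' Prune correlated variables from the full input
#'
#' Computes pairwise Spearman correlations among the full-input variables and
#' iterates over significantly correlated pairs (p < `alpha`) in descending
#' absolute correlation. In each pair, clinicopathological variables are
#' systematically privileged over radiomics-based ones; between two
#' radiomics-based variables the one with the higher univariable p-value is
#' dropped (alphabetical tie-break); clinicopathological pairs are both kept.
#' Iteration continues until no significant pair remains among survivors.
#'
#' @param full_vars Character vector (the full input).
#' @param data Data.frame with the variable columns.
#' @param min_p Named per-variable univariable minimum p-values.
#' @param clinical_vars Clinicopathological variable names.
#' @param alpha Spearman significance cutoff (default 0.05).
#' @param exact Use the exact permutation p-value (only sensible for n < 30);
#'   default asymptotic.
#' @return Character vector: the uncorrelated input (subset of `full_vars`,
#'   order preserved), with attribute `dropped` (data.frame of the pruning
#'   decisions).
#' @export
prune_correlated <- function(full_vars, data, min_p, clinical_vars,
                             alpha = 0.05, exact = FALSE) {
  if (length(full_vars) < 2L) {
    return(structure(full_vars, dropped = data.frame()))
  }
  pairs <- t(combn(full_vars, 2L))
  stats <- apply(pairs, 1, function(pr) {
    ct <- suppressWarnings(
      cor.test(spearman_numeric(data[[pr[1]]]), spearman_numeric(data[[pr[2]]]),
               method = "spearman", exact = exact)
    )
    c(rho = unname(ct$estimate), p = ct$p.value)
  })
  ord <- order(-abs(stats["rho", ]), pairs[, 1], pairs[, 2])
  dropped <- character(0)
  log <- list()
  for (k in ord) {
    if (stats["p", k] >= alpha) next
    a <- pairs[k, 1]; b <- pairs[k, 2]
    if (a %in% dropped || b %in% dropped) next
    a_clin <- a %in% clinical_vars
    b_clin <- b %in% clinical_vars
    if (a_clin && b_clin) next   # clinicopathological pairs are both kept
    drop <- if (a_clin) b else if (b_clin) a else {
      ## two radiomics-based variables: drop the weaker univariable signal
      pa <- min_p[[a]]; pb <- min_p[[b]]
      if (pa < pb) b else if (pb < pa) a else sort(c(a, b))[2]
    }
    dropped <- c(dropped, drop)
    log[[length(log) + 1L]] <- data.frame(
      kept = setdiff(c(a, b), drop), dropped = drop,
      rho = stats["rho", k], p = stats["p", k]
    )
  }
  structure(setdiff(full_vars, dropped),
            dropped = if (length(log)) do.call(rbind, log) else data.frame())
}
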