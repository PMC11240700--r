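## Performance evaluation: Harrell c-index, IPCW Brier score and IBS,
## distribution comparison, permutation importance.

#' Harrell's concordance index
#'
#' Over comparable subject pairs (the shorter time has an event, including
#' the tie case of an event at the same time as a censoring), counts
#' concordant pairs (higher risk score for the shorter survival) as 1 and
#' risk-score ties as 0.5. Pairs of events at exactly the same time carry no
#' ordering information and receive 0.5. Ranges from 0 (perfectly wrong)
#' through 0.5 (random) to 1 (perfect).
#'
#' @param risk Risk scores, higher = worse.
#' @param time,event Survival outcome.
#' @return Concordance fraction in `[0, 1]`; error when no pair is comparable.
#' @export
harrell_cindex <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  dt <- outer(time, time, `-`)            # dt[i,j] = t_i - t_j
  ei <- matrix(event, length(event), length(event))
  ## i is the (strictly or tie-censored) earlier subject with an event
  comparable <- (dt < 0 & ei == 1) |
    (dt == 0 & ei == 1 & t(ei) == 0)
  tied_events <- dt == 0 & ei == 1 & t(ei) == 1
  tied_events[lower.tri(tied_events, diag = TRUE)] <- FALSE
  n_pairs <- sum(comparable) + sum(tied_events)
  if (n_pairs == 0) stop("no comparable pairs: c-index undefined")
  dr <- outer(risk, risk, `-`)            # dr[i,j] = r_i - r_j
  conc <- sum((dr > 0) * comparable) + 0.5 * sum((dr == 0) * comparable) +
    0.5 * sum(tied_events)
  conc / n_pairs
}

#' Kaplan-Meier estimate of the censoring distribution
#'
#' @param time,event Survival outcome (the censoring indicator is
#'   `1 - event`).
#' @return Function `G(t, left = FALSE)` returning the censoring survival
#'   probability (left limit when `left = TRUE`), for IPCW weighting.
#' @export
censoring_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  tt <- c(0, fit$time)
  ss <- c(1, fit$surv)
  function(t, left = FALSE) {
    eval_t <- if (left) t - 1e-9 else t
    approx(tt, ss, xout = pmax(eval_t, 0), method = "constant",
           rule = 2, f = 0)$y
  }
}

#' IPCW time-dependent Brier score
#'
#' Inverse-probability-of-censoring weighted mean squared error of the
#' predicted survival probabilities at time `t`: subjects with an event by
#' `t` contribute \eqn{(0 - S(t|x))^2 / G(T_i^-)}, subjects still at risk
#' contribute \eqn{(1 - S(t|x))^2 / G(t)}, and subjects censored before `t`
#' are weighted 0. The censoring distribution `G` should be estimated on the
#' training partition ([censoring_km()]).
#'
#' @param surv_prob Predicted S(t|x), one value per subject.
#' @param time,event Test outcome.
#' @param t Evaluation time.
#' @param G Censoring survival function (default: estimated from
#'   `time`/`event` themselves).
#' @param weight_cap Cap on IPCW weights (applied with a warning when the
#'   censoring survival estimate reaches 0).
#' @return Brier score at `t` (>= 0).
#' @export
brier_score <- function(surv_prob, time, event, t,
                        G = censoring_km(time, event), weight_cap = 100) {
  stopifnot(length(surv_prob) == length(time))
  if (t <= 0) return(mean((1 - surv_prob)^2))  # everyone at risk at t = 0
  had_event <- time <= t & event == 1
  at_risk <- time > t
  g_event <- G(time, left = TRUE)
  g_t <- G(t)
  w <- numeric(length(time))
  w[had_event] <- 1 / g_event[had_event]
  w[at_risk] <- 1 / g_t
  if (any(!is.finite(w)) || any(w > weight_cap)) {
    warning("censoring survival estimate near 0: IPCW weights capped")
    w <- pmin(w, weight_cap)
  }
  resid <- numeric(length(time))
  resid[had_event] <- (0 - surv_prob[had_event])^2
  resid[at_risk] <- (1 - surv_prob[at_risk])^2
  mean(w * resid)
}

#' Integrated Brier score over a time window
#'
#' Trapezoidal integral of the Brier curve divided by the window length
#' (default grid: every 3 months from 0 to 24).
#'
#' @param times Sorted grid covering the window.
#' @param bs Brier scores on the grid (no missing values).
#' @return Scalar IBS.
#' @export
integrated_brier_score <- function(times, bs) {
  if (length(times) != length(bs) || anyNA(bs)) {
    stop("Brier curve must be defined on the full grid")
  }
  if (is.unsorted(times)) stop("`times` must be sorted")
  trapz(times, bs) / (max(times) - min(times))
}

#' Compare two c-index distributions over CV repetitions
#'
#' Two-sided paired Wilcoxon signed-rank test on the repetition-level mean
#' c-indices (paired by repetition, i.e. identical splits). All-zero
#' differences return p = 1.
#'
#' @param a,b Numeric vectors of per-repetition c-indices, equal length.
#' @return List with `p_value`, `statistic`, `median_difference`.
#' @export
compare_cindex_distributions <- function(a, b) {
  if (length(a) != length(b)) stop("unpaired lengths")
  d <- a - b
  if (all(d == 0)) {
    return(list(p_value = 1, statistic = NA_real_, median_difference = 0))
  }
  wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       median_difference = median(d))
}

#' Permutation importance of each predictor
#'
#' For each predictor, the c-index loss after randomly shuffling its values
#' is averaged over `n_permutations` seeded shuffles; negative mean losses
#' are clipped to 0 and the importances scaled to sum to 100%.
#'
#' @param fit A `survival_fit`.
#' @param x Test design matrix.
#' @param time,event Test outcome.
#' @param n_permutations Shuffles per predictor (default 100).
#' @param seed Integer seed.
#' @return Data.frame of class `importance_report` with `variable`,
#'   `mean_cindex_loss`, `importance_pct` (sums to 100 unless all losses
#'   are nonpositive).
#' @export
permutation_importance <- function(fit, x, time, event,
                                   n_permutations = 100L, seed = 1L) {
  x <- as.matrix(x)
  base_c <- harrell_cindex(predict_risk(fit, x), time, event)
  loss <- with_seed(seed, {
    vapply(seq_len(ncol(x)), function(j) {
      mean(vapply(seq_len(n_permutations), function(r) {
        xp <- x
        xp[, j] <- sample(xp[, j])
        base_c - harrell_cindex(predict_risk(fit, xp), time, event)
      }, numeric(1)))
    }, numeric(1))
  })
  clipped <- pmax(loss, 0)
  pct <- if (sum(clipped) > 0) 100 * clipped / sum(clipped) else clipped
  structure(
    data.frame(variable = colnames(x), mean_cindex_loss = loss,
               importance_pct = pct),
    class = c("importance_report", "data.frame"),
    baseline_cindex = base_c
  )
}
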