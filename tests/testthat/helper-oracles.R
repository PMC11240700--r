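## Independent brute-force oracles and tiny fixtures shared across tests.
## These deliberately re-derive each quantity by direct enumeration, never
## through the package's own code paths.

## Harrell c-index by explicit double loop over ordered pairs.
bf_cindex <- function(risk, time, event) {
  num <- den <- 0
  n <- length(risk)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      comparable <- (time[i] < time[j] && event[i] == 1) ||
        (time[i] == time[j] && event[i] == 1 && event[j] == 0)
      if (comparable) {
        den <- den + 1
        if (risk[i] > risk[j]) num <- num + 1
        else if (risk[i] == risk[j]) num <- num + 0.5
      } else if (time[i] == time[j] && event[i] == 1 && event[j] == 1 && i < j) {
        den <- den + 1
        num <- num + 0.5
      }
    }
  }
  num / den
}

## Cox negative log partial likelihood for a single covariate (no ties in
## the fixtures, so Breslow/Efron coincide) and a grid-search estimator.
bf_cox_npll <- function(beta, x, time, event) {
  s <- beta * x
  val <- 0
  for (i in which(event == 1)) {
    val <- val - (s[i] - log(sum(exp(s[time >= time[i]]))))
  }
  val
}

bf_cox_grid <- function(x, time, event, grid = seq(-3, 3, by = 1e-3)) {
  lik <- vapply(grid, bf_cox_npll, numeric(1), x = x, time = time, event = event)
  grid[which.min(lik)]
}

## Symmetric GLCM counts by explicit voxel-pair enumeration.
bf_glcm <- function(levels, off, B) {
  d <- dim(levels)
  M <- matrix(0, B, B)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- levels[x, y, z]
    if (is.na(a)) next
    q <- c(x, y, z) + off
    if (any(q < 1) || any(q > d)) next
    b <- levels[q[1], q[2], q[3]]
    if (is.na(b)) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M
}

## Runs along one direction by walking each line from its start voxel.
bf_runs <- function(levels, off) {
  d <- dim(levels)
  runs <- data.frame(level = integer(0), length = integer(0))
  inside <- function(p) all(p >= 1) && all(p <= d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    p <- c(x, y, z)
    prev <- p - off
    if (inside(prev)) next        # not a line start
    ## walk the full line, splitting runs at NAs and level changes
    cur_lev <- NA_integer_; cur_len <- 0L
    while (inside(p)) {
      v <- levels[p[1], p[2], p[3]]
      if (!is.na(v) && !is.na(cur_lev) && v == cur_lev) {
        cur_len <- cur_len + 1L
      } else {
        if (cur_len > 0L) runs <- rbind(runs, data.frame(level = cur_lev, length = cur_len))
        cur_lev <- v
        cur_len <- if (is.na(v)) 0L else 1L
      }
      p <- p + off
    }
    if (cur_len > 0L) runs <- rbind(runs, data.frame(level = cur_lev, length = cur_len))
  }
  runs
}

## 26-connected equal-level zones by repeated flood fill.
bf_zones <- function(levels) {
  d <- dim(levels)
  lab <- array(0L, dim = d)
  nxt <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  idx_all <- which(!is.na(levels))
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      p <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        qi <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
        if (lab[qi] == 0L && !is.na(levels[qi]) && levels[qi] == levels[cur]) {
          lab[qi] <- nxt
          queue <- c(queue, qi)
        }
      }
    }
  }
  sizes <- as.integer(table(lab[lab > 0]))
  sizes
}

## Wrap an integer level array as the analysis products discretize_volume
## would emit (levels NA outside the mask).
as_level_phantom <- function(arr) {
  arr <- array(as.integer(arr), dim = dim(arr))
  mask <- array(as.integer(!is.na(arr)), dim = dim(arr))
  list(levels = arr, mask = mask, n_levels = max(arr, na.rm = TRUE))
}

## A small survival fixture with censoring and no tied times.
surv_fixture <- function(n = 12, seed = 5) {
  ipithsurv:::with_seed(seed, {
    data.frame(time = round(rexp(n, 0.2) + 0.3, 3),
               event = rbinom(n, 1, 0.7),
               risk = rnorm(n))
  })
}

## Compact simulated cohort used by several modelling tests.
small_cohort <- function(n = 60, p = 6, seed = 1, ...) {
  generate_cohort(cohort_sim_config(n_patients = n, n_features = p,
                                    seed = seed, ...))
}

## Cohort -> patient-level predictor table joined with clinical covariates.
cohort_predictor_table <- function(cohort, metrics = ipith_metrics()) {
  fc <- grep("^rf_", names(cohort$lesions), value = TRUE)
  cs <- center_scale(cohort$lesions[, fc, drop = FALSE])
  l2 <- cohort$lesions
  l2[, fc] <- cs$scaled
  pt <- patient_predictor_table(l2, fc, metrics = metrics)
  tab <- cbind(pt, cohort$patients[match(pt$patient_id,
                                         cohort$patients$patient_id), -1])
  tab[match(cohort$outcomes$patient_id, tab$patient_id), , drop = FALSE]
}

clinical_vars <- c("who_ps", "staging", "met_sites", "bone_mets", "pdl1")
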