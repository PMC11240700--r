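#' Configuration for a simulated multi-lesion cohort
#'
#' Defines the generative model for a synthetic metastatic-lung-adenocarcinoma
#' style cohort: per patient, a feature centroid in radiomics space is drawn
#' and each lesion is the centroid plus independent lesion-level noise whose
#' scale is controlled by `heterogeneity_scale`; progression-free survival is
#' drawn from a Weibull proportional-hazards model whose linear predictor
#' combines clinicopathological covariates, one designated lesion feature
#' (the patient-level centroid of feature `rf_01`), and the patient's true
#' Canberra-mean inter-lesion distance.
#'
#' Defaults emulate the reference cohort conditions: 140 patients, 2-15
#' lesions per patient (median ~4), 68 features, ~82.9% events, median PFS
#' ~6 months, administrative follow-up cutoff at 27 months, and clinical
#' log-hazard effects of the magnitudes reported for WHO performance status 2,
#' >= 4 metastatic sites, bone metastases, and PD-L1 >= 50%.
#'
#' @param n_patients Number of patients.
#' @param lesion_count_range Integer interval for lesions per patient; the
#'   lower bound must be >= 2 (at least two measurable target lesions).
#' @param n_features Number of radiomics features per lesion.
#' @param patient_effect_sd SD of the patient feature centroid.
#' @param lesion_noise_sd SD of lesion-level feature noise before scaling by
#'   `heterogeneity_scale`.
#' @param heterogeneity_scale Nonnegative multiplier of inter-lesion
#'   divergence; 0 makes all of a patient's lesions identical.
#' @param beta List of true log-hazard coefficients: `clinical` (named vector
#'   over the generated covariate encodings), `feature` (per-SD effect of the
#'   designated lesion feature), `canberra` (per-SD effect of the true
#'   Canberra-mean).
#' @param baseline Weibull baseline: list with `shape` and `median_months`
#'   (survival median at linear predictor 0).
#' @param censoring List with `admin_cutoff_months` and
#'   `target_event_fraction`; an exponential censoring rate is solved at
#'   generation time so the expected event fraction matches the target.
#' @param seed Integer seed.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_patients = 140L,
                              lesion_count_range = c(2L, 15L),
                              n_features = 68L,
                              patient_effect_sd = 1,
                              lesion_noise_sd = 0.5,
                              heterogeneity_scale = 1,
                              beta = list(
                                clinical = c(who_ps1 = 0.25, who_ps2 = 0.86,
                                             met_sites_ge4 = 0.51,
                                             bone_mets = 0.38, pdl1_ge50 = -0.30),
                                feature = 0.4,
                                canberra = -0.3
                              ),
                              baseline = list(shape = 1.2, median_months = 6),
                              censoring = list(admin_cutoff_months = 27,
                                               target_event_fraction = 0.829),
                              seed = 1L) {
  if (n_patients < 2) stop("`n_patients` must be >= 2")
  if (length(lesion_count_range) != 2L || lesion_count_range[1] < 2L ||
      lesion_count_range[2] < lesion_count_range[1]) {
    stop("`lesion_count_range` must be an integer interval with lower bound >= 2")
  }
  if (n_features < 2) stop("`n_features` must be >= 2")
  if (patient_effect_sd <= 0 || lesion_noise_sd <= 0) {
    stop("dispersion parameters must be positive")
  }
  if (heterogeneity_scale < 0) stop("`heterogeneity_scale` must be nonnegative")
  stopifnot_scalar_number(baseline$shape, "baseline$shape", positive = TRUE)
  stopifnot_scalar_number(baseline$median_months, "baseline$median_months", positive = TRUE)
  tef <- censoring$target_event_fraction
  if (!is.null(tef) && (tef <= 0 || tef > 1)) {
    stop("`target_event_fraction` must be in (0, 1]")
  }
  structure(
    list(n_patients = as.integer(n_patients),
         lesion_count_range = as.integer(lesion_count_range),
         n_features = as.integer(n_features),
         patient_effect_sd = patient_effect_sd,
         lesion_noise_sd = lesion_noise_sd,
         heterogeneity_scale = heterogeneity_scale,
         beta = beta, baseline = baseline, censoring = censoring,
         seed = as.integer(seed)),
    class = "cohort_sim_config"
  )
}

## Weibull baseline scale such that S(median) = 1/2 at linear predictor 0.
weibull_scale_from_median <- function(shape, median_months) {
  median_months / log(2)^(1 / shape)
}

#' Draw survival times from a Weibull proportional-hazards model
#'
#' Event times follow \eqn{S(t|x) = \exp(-(t/b)^k e^{lp})} via inverse
#' transform. Censoring combines an administrative cutoff with an independent
#' exponential time; when `censoring$target_event_fraction` is supplied
#' (instead of `rate`) the exponential rate is solved by root finding so the
#' expected realized event fraction matches the target.
#'
#' @param linear_predictor Finite numeric vector of log-hazard ratios.
#' @param baseline List with Weibull `shape` and either `scale` or
#'   `median_months`.
#' @param censoring List with `admin_cutoff_months` and either `rate` or
#'   `target_event_fraction`. An all-zero cutoff censors everyone at the
#'   minimum representable positive time.
#' @param seed Integer seed.
#' @return A data.frame with columns `time_months` (> 0) and `event` (1 =
#'   progression/death, 0 = censored), plus attribute `censor_rate`.
#' @export
generate_survival_times <- function(linear_predictor,
                                    baseline = list(shape = 1.2, median_months = 6),
                                    censoring = list(admin_cutoff_months = 27,
                                                     target_event_fraction = 0.829),
                                    seed = 1L) {
  if (!all(is.finite(linear_predictor))) stop("linear predictors must be finite")
  n <- length(linear_predictor)
  shape <- baseline$shape
  scale <- baseline$scale %||% weibull_scale_from_median(shape, baseline$median_months)
  admin <- censoring$admin_cutoff_months %||% Inf

  with_seed(seed, {
    u <- runif(n)
    t_event <- scale * (-log(u) / exp(linear_predictor))^(1 / shape)

    if (admin <= 0) {
      return(structure(
        data.frame(time_months = rep(.Machine$double.eps, n), event = rep(0L, n)),
        censor_rate = Inf
      ))
    }

    rate <- censoring$rate
    if (is.null(rate)) {
      target <- censoring$target_event_fraction
      if (is.null(target)) {
        rate <- 0
      } else {
        ## expected event fraction given realized event times:
        ## P(event_i) = exp(-r * t_i) for t_i < admin, 0 otherwise
        f <- function(r) mean(ifelse(t_event < admin, exp(-r * t_event), 0)) - target
        rate <- if (f(0) <= 0) 0 else uniroot(f, c(0, 50), tol = 1e-10)$root
      }
    }
    t_cens <- pmin(if (rate > 0) rexp(n, rate) else rep(Inf, n), admin)
    time <- pmax(pmin(t_event, t_cens), .Machine$double.eps)
    structure(
      data.frame(time_months = time, event = as.integer(t_event <= t_cens)),
      censor_rate = rate
    )
  })
}

## Lesion counts: 2 + negative binomial, truncated at the configured maximum.
## Calibrated to a median of ~4 lesions with Q1-Q3 ~3-6 and range 2-15.
draw_lesion_counts <- function(n, range) {
  k <- 2L + stats::rnbinom(n, size = 2.2, mu = 2.7)
  pmin(pmax(k, range[1]), range[2])
}

#' Generate a synthetic multi-lesion cohort with ground truth
#'
#' @param config A [cohort_sim_config()].
#' @return A list of class `radcohort`:
#' \describe{
#'   \item{lesions}{per-lesion data.frame: `patient_id`, `lesion_id`,
#'     `location`, `volume_mm3`, and feature columns `rf_01..rf_k`.}
#'   \item{patients}{clinicopathological data.frame (age, sex, WHO performance
#'     status, staging, metastatic-site count category, bone metastases,
#'     PD-L1 category).}
#'   \item{outcomes}{`patient_id`, `time_months`, `event`.}
#'   \item{truth}{ground truth: `beta`, per-patient linear predictor, the true
#'     (raw and cohort-standardized) Canberra-mean, designated feature values,
#'     event and censoring times.}
#' }
#' @export
generate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n <- config$n_patients
  p <- config$n_features
  feat_names <- sprintf("rf_%02d", seq_len(p))

  sim <- with_seed(derive_seed(config$seed, "cohort"), {
    ## --- clinicopathological covariates (cohort-like prevalences) ---
    who_ps <- factor(sample(c(0L, 1L, 2L), n, replace = TRUE,
                            prob = c(0.27, 0.55, 0.18)), levels = c(0L, 1L, 2L))
    sex <- factor(sample(c("female", "male"), n, replace = TRUE,
                         prob = c(0.364, 0.636)), levels = c("female", "male"))
    age <- round(rnorm(n, 64.3, 8.8), 1)
    staging <- factor(sample(c("IIIB-IVA", "IVB"), n, replace = TRUE,
                             prob = c(0.257, 0.743)), levels = c("IIIB-IVA", "IVB"))
    met_sites <- factor(sample(c("1", "2", "3", ">=4"), n, replace = TRUE,
                               prob = c(0.25, 0.257, 0.207, 0.286)),
                        levels = c("1", "2", "3", ">=4"))
    bone_mets <- factor(sample(c("no", "yes"), n, replace = TRUE,
                               prob = c(0.493, 0.507)), levels = c("no", "yes"))
    pdl1 <- factor(sample(c("0%", "1-49%", ">=50%"), n, replace = TRUE,
                          prob = c(0.307, 0.25, 0.443)),
                   levels = c("0%", "1-49%", ">=50%"))

    ## --- hierarchical lesion features ---
    k_les <- draw_lesion_counts(n, config$lesion_count_range)
    centroids <- matrix(rnorm(n * p, 0, config$patient_effect_sd), n, p)
    lesions <- vector("list", n)
    canberra_true <- numeric(n)
    locations <- c("lung", "liver", "bone", "adrenal", "node", "pleura")
    for (i in seq_len(n)) {
      k <- k_les[i]
      noise <- matrix(rnorm(k * p, 0, config$lesion_noise_sd), k, p)
      X <- sweep(config$heterogeneity_scale * noise, 2, centroids[i, ], `+`)
      colnames(X) <- feat_names
      canberra_true[i] <- mean_pairwise_canberra(X)
      lesions[[i]] <- data.frame(
        patient_id = sprintf("P%03d", i),
        lesion_id = sprintf("P%03d_L%02d", i, seq_len(k)),
        location = sample(locations, k, replace = TRUE,
                          prob = c(0.35, 0.15, 0.2, 0.08, 0.17, 0.05)),
        volume_mm3 = pmax(round(rlnorm(k, log(5000), 0.9)), 1000),
        X,
        check.names = FALSE
      )
    }
    lesions <- do.call(rbind, lesions)

    ## --- linear predictor (effects per SD for the continuous terms) ---
    bc <- config$beta$clinical
    z_feat <- centroids[, 1] / config$patient_effect_sd
    z_canb <- if (sd(canberra_true) > 0) {
      (canberra_true - mean(canberra_true)) / sd(canberra_true)
    } else {
      rep(0, n)
    }
    lp <- (bc[["who_ps1"]] * (who_ps == 1) +
           bc[["who_ps2"]] * (who_ps == 2) +
           bc[["met_sites_ge4"]] * (met_sites == ">=4") +
           bc[["bone_mets"]] * (bone_mets == "yes") +
           bc[["pdl1_ge50"]] * (pdl1 == ">=50%") +
           config$beta$feature * z_feat +
           config$beta$canberra * z_canb)
    ## centred so the baseline describes the average patient and the cohort
    ## median PFS tracks the configured baseline median
    lp <- as.numeric(lp) - mean(as.numeric(lp))

    patients <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      age = age, sex = sex, who_ps = who_ps, staging = staging,
      met_sites = met_sites, bone_mets = bone_mets, pdl1 = pdl1
    )
    list(lesions = lesions, patients = patients, lp = lp,
         canberra_true = canberra_true, z_feat = z_feat, z_canb = z_canb)
  })

  out <- generate_survival_times(sim$lp, config$baseline, config$censoring,
                                 seed = derive_seed(config$seed, "survival"))
  outcomes <- data.frame(patient_id = sim$patients$patient_id, out)

  truth <- list(
    beta = config$beta,
    linear_predictor = setNames(sim$lp, sim$patients$patient_id),
    canberra_mean_true = setNames(sim$canberra_true, sim$patients$patient_id),
    canberra_mean_std = setNames(sim$z_canb, sim$patients$patient_id),
    designated_feature = "rf_01",
    designated_feature_std = setNames(sim$z_feat, sim$patients$patient_id),
    censor_rate = attr(out, "censor_rate")
  )
  structure(
    list(lesions = sim$lesions, patients = sim$patients, outcomes = outcomes,
         truth = truth, config = config),
    class = "radcohort"
  )
}

## Mean pairwise Canberra distance between the rows of X (ground truth for
## the hazard; computed on the raw generated features).
mean_pairwise_canberra <- function(X) {
  k <- nrow(X)
  if (k < 2L) return(0)
  d <- numeric(0)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      d <- c(d, canberra_distance(X[i, ], X[j, ]))
    }
  }
  mean(d)
}

#' @export
print.radcohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic multi-lesion cohort: %d patients, %d lesions, %d features\n",
    nrow(x$patients), nrow(x$lesions), x$config$n_features
  ))
  cat(sprintf("  events: %d/%d (%.1f%%); median follow-up config: %.1f months\n",
              sum(x$outcomes$event), nrow(x$outcomes),
              100 * mean(x$outcomes$event), x$config$baseline$median_months))
  invisible(x)
}

#' Write a cohort to disk as three CSVs plus a JSON ground-truth sidecar
#'
#' @param cohort A `radcohort`.
#' @param dir Output directory (created if missing).
#' @return The four file paths, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "radcohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("lesions.csv", "patients.csv", "outcomes.csv",
                            "ground_truth.json"))
  write.csv(cohort$lesions, paths[1], row.names = FALSE)
  write.csv(cohort$patients, paths[2], row.names = FALSE)
  write.csv(cohort$outcomes, paths[3], row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a cohort previously written by [write_cohort_csv()]
#'
#' @param dir Directory containing `lesions.csv`, `patients.csv`,
#'   `outcomes.csv` (and optionally `ground_truth.json`).
#' @return A `radcohort` (with `truth = NULL` when the sidecar is absent).
#' @export
read_cohort_csv <- function(dir) {
  lesions <- read.csv(file.path(dir, "lesions.csv"), check.names = FALSE)
  patients <- read.csv(file.path(dir, "patients.csv"), stringsAsFactors = TRUE)
  outcomes <- read.csv(file.path(dir, "outcomes.csv"))
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  structure(list(lesions = lesions, patients = patients, outcomes = outcomes,
                 truth = truth, config = NULL),
            class = "radcohort")
}
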