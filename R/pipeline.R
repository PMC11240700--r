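## End-to-end orchestration: simulate/load -> (extract) -> aggregate ->
## screen -> benchmark -> explain -> report, with deterministic seeding and
## persisted CSV/JSON artifacts per stage.

#' Pipeline configuration
#'
#' @param cohort_dir Directory with `lesions.csv`, `patients.csv`,
#'   `outcomes.csv` (the tabular entry point), or `NULL` to simulate.
#' @param sim_config A [cohort_sim_config()] used when `cohort_dir` is NULL.
#' @param clinical_vars Clinicopathological predictor columns.
#' @param metrics IPITH metrics.
#' @param minkowski_p Minkowski order.
#' @param screen_threshold Univariable screening p cutoff (default 0.100).
#' @param correlation_alpha Spearman pruning p cutoff (default 0.05).
#' @param plan A [cv_plan()].
#' @param models Named list of [model_spec()]s to benchmark.
#' @param brier_times Brier curve grid (default every 3 months, 0-24).
#' @param outdir Output directory for stage artifacts (`NULL`: no files).
#' @param seed Global seed; all stage randomness is derived from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_dir = NULL,
                            sim_config = cohort_sim_config(),
                            clinical_vars = c("who_ps", "staging", "met_sites",
                                              "bone_mets", "pdl1"),
                            metrics = ipith_metrics(),
                            minkowski_p = 3,
                            screen_threshold = 0.100,
                            correlation_alpha = 0.05,
                            plan = cv_plan(repetitions = 10L),
                            models = default_model_specs(),
                            brier_times = seq(0, 24, by = 3),
                            outdir = NULL,
                            seed = 1L) {
  if (screen_threshold <= 0 || screen_threshold >= 1 ||
      correlation_alpha <= 0 || correlation_alpha >= 1) {
    stop("thresholds must lie in (0, 1)")
  }
  if (!is.null(cohort_dir) && !dir.exists(cohort_dir)) {
    stop("`cohort_dir` does not exist: ", cohort_dir)
  }
  structure(
    list(cohort_dir = cohort_dir, sim_config = sim_config,
         clinical_vars = clinical_vars, metrics = metrics,
         minkowski_p = minkowski_p, screen_threshold = screen_threshold,
         correlation_alpha = correlation_alpha, plan = plan, models = models,
         brier_times = brier_times, outdir = outdir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Default benchmark model specifications
#'
#' One configuration per learner, drawn from the documented grids.
#'
#' @param seed Seed shared by the stochastic learners.
#' @return Named list of [model_spec()]s.
#' @export
default_model_specs <- function(seed = 1L) {
  list(
    stepwise_cox = model_spec("stepwise_cox", seed = seed),
    lasso_cox = model_spec("lasso_cox", seed = seed),
    rsf = model_spec("rsf", list(nodesize = 15L), seed = seed),
    gbm = model_spec("gbm", list(shrinkage = 0.01, depth = 2L, mnotn = 8L),
                     seed = seed),
    deepsurv = model_spec("deepsurv",
                          list(layers = 1L, nodes = 8L, l2_reg = 1,
                               epochs = 128L),
                          seed = seed)
  )
}

#' Default hyperparameter grids for the five learners
#'
#' Enumerable grids covering the commonly reported configurations: `lambda`
#' path length for LASSO; `mtry` up to `ceiling(sqrt(p))` and nodesize in
#' \{5, 10, 15, 20, 22, 25\} for the forest; shrinkage in \{0.005, 0.01,
#' 0.05, 0.095, 0.1\}, depth 1-4, MNOTN in \{5, 8, 11, 15\} for boosting;
#' 1-3 layers of 8-16 nodes, ReLU/SELU, adam/sgd for the network.
#'
#' @param model Learner label.
#' @param n_features Number of design columns (bounds `mtry`).
#' @param seed Seed.
#' @return List of [model_spec()]s.
#' @export
hyperparameter_grid <- function(model, n_features = 10L, seed = 1L) {
  grids <- switch(model,
    lasso_cox = list(list(nlambda = 50L)),
    rsf = {
      g <- expand.grid(mtry = seq_len(ceiling(sqrt(n_features))),
                       nodesize = c(5L, 10L, 15L, 20L, 22L, 25L))
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    gbm = {
      g <- expand.grid(shrinkage = c(0.005, 0.01, 0.05, 0.095, 0.1),
                       depth = 1:4, mnotn = c(5L, 8L, 11L, 15L))
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    deepsurv = {
      g <- expand.grid(layers = 1:3, nodes = 8:16,
                       activation = c("relu", "selu"),
                       optimizer = c("adam", "sgd"),
                       stringsAsFactors = FALSE)
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    stepwise_cox = list(list())
  )
  lapply(grids, function(hp) model_spec(model, hp, seed = seed))
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the [pipeline_config()] arguments;
#' `plan` is given as `repetitions`/`folds`, `sim` as [cohort_sim_config()]
#' fields.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  plan <- cv_plan(repetitions = y$plan$repetitions %||% 10L,
                  folds = y$plan$folds %||% 5L,
                  seed = y$seed %||% 1L)
  sim <- do.call(cohort_sim_config, y$sim %||% list())
  pipeline_config(
    cohort_dir = y$cohort_dir,
    sim_config = sim,
    clinical_vars = y$clinical_vars %||% c("who_ps", "staging", "met_sites",
                                           "bone_mets", "pdl1"),
    minkowski_p = y$minkowski_p %||% 3,
    screen_threshold = y$screen_threshold %||% 0.100,
    correlation_alpha = y$correlation_alpha %||% 0.05,
    plan = plan,
    outdir = y$outdir,
    seed = y$seed %||% 1L
  )
}

#' Validate input tables against the pipeline schema
#'
#' Checks the lesion/patient/outcome schemas, the minimum of two lesions per
#' patient, positive survival times, and the 1 cm^3 target-lesion volume
#' criterion. Never drops rows silently: every problem is a returned
#' violation.
#'
#' @param lesions,patients,outcomes Data.frames (or a `radcohort` via
#'   `cohort`).
#' @param cohort Optional `radcohort` overriding the three tables.
#' @return Data.frame with columns `rule`, `id`, `detail` (zero rows when
#'   everything is well formed).
#' @export
validate_inputs <- function(lesions = NULL, patients = NULL, outcomes = NULL,
                            cohort = NULL) {
  if (!is.null(cohort)) {
    lesions <- cohort$lesions; patients <- cohort$patients
    outcomes <- cohort$outcomes
  }
  v <- list()
  add <- function(rule, id, detail) {
    v[[length(v) + 1L]] <<- data.frame(rule = rule, id = as.character(id),
                                       detail = detail)
  }
  need_lesion_cols <- c("patient_id", "lesion_id", "location", "volume_mm3")
  miss <- setdiff(need_lesion_cols, names(lesions))
  if (length(miss)) add("lesion-columns", NA, paste("missing:", paste(miss, collapse = ", ")))
  need_out_cols <- c("patient_id", "time_months", "event")
  miss <- setdiff(need_out_cols, names(outcomes))
  if (length(miss)) add("outcome-columns", NA, paste("missing:", paste(miss, collapse = ", ")))

  if (all(need_lesion_cols %in% names(lesions))) {
    cnt <- table(lesions$patient_id)
    for (pid in names(cnt)[cnt < 2]) {
      add("min-two-lesions", pid, sprintf("%d lesion(s)", cnt[[pid]]))
    }
    small <- lesions$lesion_id[lesions$volume_mm3 < 1000]
    for (lid in small) add("volume-below-1cm3", lid, "not a radiomics target lesion")
    feat_cols <- setdiff(names(lesions), need_lesion_cols)
    if (length(feat_cols)) {
      bad <- feat_cols[vapply(lesions[feat_cols],
                              function(x) any(!is.finite(x)), logical(1))]
      for (f in bad) add("non-finite-feature", f, "NA/Inf values present")
    }
  }
  if (all(need_out_cols %in% names(outcomes))) {
    neg <- outcomes$patient_id[!is.finite(outcomes$time_months) |
                                 outcomes$time_months <= 0]
    for (pid in neg) add("nonpositive-time", pid, "time_months must be > 0")
    bad <- outcomes$patient_id[!outcomes$event %in% c(0, 1)]
    for (pid in bad) add("event-not-binary", pid, "event must be 0/1")
    if (!is.null(patients) && "patient_id" %in% names(patients)) {
      orphans <- setdiff(outcomes$patient_id, patients$patient_id)
      for (pid in orphans) add("unknown-patient", pid, "outcome without patient row")
    }
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(rule = character(0), id = character(0), detail = character(0))
}

#' Run the end-to-end analysis pipeline
#'
#' Stages: load or simulate the cohort; build the per-patient predictor
#' table (largest / min / avg / max lesion features plus center-scaled IPITH
#' summaries); univariable screen at the configured threshold; Spearman
#' correlation pruning into the uncorrelated input; benchmark the configured
#' models on the three inputs under event-stratified repeated CV; permutation
#' importance of the best model. Identical configuration and seed give an
#' identical report; artifacts are persisted under `outdir` when set.
#'
#' @param config A [pipeline_config()].
#' @return List of class `run_report`: `cohort`, `predictors`,
#'   `univariable`, `input_sets`, `cv` (per model x input summaries),
#'   `cv_raw`, `importance`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  ## --- stage 1: cohort ---
  cohort <- if (!is.null(config$cohort_dir)) {
    read_cohort_csv(config$cohort_dir)
  } else {
    sc <- config$sim_config
    sc$seed <- derive_seed(config$seed, "simulate")
    generate_cohort(sc)
  }
  viol <- validate_inputs(cohort = cohort)
  if (nrow(viol) > 0 && any(viol$rule %in%
        c("lesion-columns", "outcome-columns", "nonpositive-time"))) {
    stop("stage `validate`: schema violations; first: ",
         viol$rule[1], " (", viol$detail[1], ")")
  }

  ## --- stage 2: aggregate ---
  feat_cols <- grep("^rf_", names(cohort$lesions), value = TRUE)
  if (length(feat_cols) == 0) {
    feat_cols <- setdiff(names(cohort$lesions),
                         c("patient_id", "lesion_id", "location", "volume_mm3"))
  }
  nzv <- near_zero_variance_filter(cohort$lesions[, feat_cols, drop = FALSE])
  feat_cols <- nzv$kept
  cs <- center_scale(cohort$lesions[, feat_cols, drop = FALSE])
  lesions_scaled <- cohort$lesions
  lesions_scaled[, feat_cols] <- cs$scaled
  predictors <- patient_predictor_table(lesions_scaled, feat_cols,
                                        metrics = config$metrics,
                                        minkowski_p = config$minkowski_p)
  ord <- match(cohort$outcomes$patient_id, predictors$patient_id)
  predictors <- predictors[ord, , drop = FALSE]
  full_tab <- cbind(predictors,
                    cohort$patients[match(predictors$patient_id,
                                          cohort$patients$patient_id),
                                    setdiff(names(cohort$patients), "patient_id"),
                                    drop = FALSE])
  time <- cohort$outcomes$time_months
  event <- cohort$outcomes$event

  ## --- stage 3: univariable screen ---
  candidates <- c(config$clinical_vars,
                  setdiff(names(predictors), "patient_id"))
  candidates <- candidates[candidates %in% names(full_tab)]
  screen <- univariable_screen(full_tab, time, event, candidates)
  sets <- filter_candidates(screen, config$clinical_vars,
                            threshold = config$screen_threshold)
  uncorr <- prune_correlated(sets$full, full_tab, attr(screen, "min_p"),
                             config$clinical_vars,
                             alpha = config$correlation_alpha)
  input_sets <- list(clinicopathological = sets$clinicopathological,
                     full = sets$full,
                     uncorrelated = as.character(uncorr))

  ## --- stage 4: benchmark ---
  cv_raw <- list()
  cv_sum <- list()
  for (input in names(input_sets)) {
    vars <- input_sets[[input]]
    if (length(vars) == 0) next
    for (mn in names(config$models)) {
      res <- repeated_stratified_cv(full_tab, time, event, vars,
                                    config$models[[mn]], config$plan,
                                    brier_times = NULL)
      key <- paste(mn, input, sep = ".")
      cv_raw[[key]] <- res
      s <- summary(res)
      s$input <- input
      cv_sum[[key]] <- s
    }
  }
  cv_table <- do.call(rbind, cv_sum)

  ## --- stage 5: importance of the best model/input ---
  importance <- NULL
  if (length(cv_sum)) {
    best_key <- names(cv_sum)[which.max(vapply(cv_sum, function(s) s$mean_cindex,
                                               numeric(1)))]
    parts <- strsplit(best_key, ".", fixed = TRUE)[[1]]
    vars <- input_sets[[parts[2]]]
    x <- preprocess_fold(full_tab, vars, seq_along(time),
                         one_hot_encode(full_tab[, vars, drop = FALSE])$map)
    fit <- fit_survival_model(config$models[[parts[1]]], x, time, event)
    importance <- permutation_importance(
      fit, x, time, event,
      seed = derive_seed(config$seed, "importance")
    )
  }

  manifest <- list(seed = config$seed,
                   n_patients = nrow(cohort$patients),
                   n_lesions = nrow(cohort$lesions),
                   n_features = length(feat_cols),
                   plan = unclass(config$plan),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  report <- structure(
    list(cohort = cohort, predictors = full_tab, univariable = screen,
         input_sets = input_sets, cv = cv_table, cv_raw = cv_raw,
         importance = importance, violations = viol, manifest = manifest),
    class = "run_report"
  )

  if (!is.null(out)) {
    write.csv(as.data.frame(screen), file.path(out, "univariable.csv"),
              row.names = FALSE)
    jsonlite::write_json(input_sets, file.path(out, "input_sets.json"),
                         auto_unbox = TRUE)
    if (!is.null(cv_table)) {
      write.csv(cv_table, file.path(out, "cv_summary.csv"), row.names = FALSE)
    }
    if (!is.null(importance)) {
      write.csv(as.data.frame(importance), file.path(out, "importance.csv"),
                row.names = FALSE)
    }
    mf <- manifest
    jsonlite::write_json(mf, file.path(out, "manifest.json"), auto_unbox = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Multi-lesion radiomics survival pipeline report\n")
  cat(sprintf("  cohort: %d patients / %d lesions\n",
              x$manifest$n_patients, x$manifest$n_lesions))
  cat(sprintf("  input sets: clinicopathological (%d), full (%d), uncorrelated (%d)\n",
              length(x$input_sets$clinicopathological),
              length(x$input_sets$full), length(x$input_sets$uncorrelated)))
  if (!is.null(x$cv)) {
    cat("  rCV mean c-index by model.input:\n")
    o <- order(-x$cv$mean_cindex)
    for (i in head(o, 8)) {
      cat(sprintf("    %-28s %.3f (%.3f-%.3f)\n",
                  paste(x$cv$model[i], x$cv$input[i], sep = "."),
                  x$cv$mean_cindex[i], x$cv$ci_lower[i], x$cv$ci_upper[i]))
    }
  }
  invisible(x)
}
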