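## Per-patient aggregation of lesion-level feature vectors: largest-lesion
## features, elementwise min/avg/max summaries, and IPITH (intra-patient
## inter-tumor heterogeneity) distance statistics.

canberra_distance <- function(a, b) {
  num <- abs(a - b)
  den <- abs(a) + abs(b)
  term <- ifelse(den == 0, 0, num / den)   # 0/0 contributes 0
  sum(term)
}

#' Pairwise distance between two lesion feature vectors
#'
#' The six distances used for IPITH quantification in radiomics space:
#' \describe{
#'   \item{euclidean}{L2 norm of the difference.}
#'   \item{chebyshev}{max absolute coordinate difference.}
#'   \item{minkowski}{Lp norm (default order `p = 3`).}
#'   \item{canberra}{\eqn{\sum_i |a_i-b_i|/(|a_i|+|b_i|)}, 0/0 terms = 0.}
#'   \item{spearman}{\eqn{1 - \rho_s(a, b)}, range 0-2; `NA` when either
#'     vector is constant (rank correlation undefined).}
#'   \item{jaccard}{generalized (Ruzicka) distance
#'     \eqn{1 - \sum_i \min(a_i,b_i)/\sum_i \max(a_i,b_i)}; intended for
#'     vectors min-max rescaled to `[0, 1]` per feature over the cohort
#'     (see [ipith_summaries()]); both-all-zero vectors give 0 by convention.}
#' }
#'
#' @param a,b Numeric vectors of equal dimension >= 2.
#' @param metric One of the six metric labels.
#' @param p Minkowski order.
#' @return Nonnegative scalar (symmetric in `a`, `b`).
#' @export
pairwise_lesion_distance <- function(a, b,
                                     metric = c("euclidean", "spearman",
                                                "jaccard", "minkowski",
                                                "canberra", "chebyshev"),
                                     p = 3) {
  metric <- match.arg(metric)
  if (length(a) != length(b) || length(a) < 2L) {
    stop("`a` and `b` must share a dimension >= 2")
  }
  switch(metric,
    euclidean = sqrt(sum((a - b)^2)),
    chebyshev = max(abs(a - b)),
    minkowski = sum(abs(a - b)^p)^(1 / p),
    canberra = canberra_distance(a, b),
    spearman = {
      if (sd(a) == 0 || sd(b) == 0) NA_real_
      else 1 - cor(a, b, method = "spearman")
    },
    jaccard = {
      den <- sum(pmax(a, b))
      if (den == 0) 0 else 1 - sum(pmin(a, b)) / den
    }
  )
}

ipith_metrics <- function() {
  c("euclidean", "spearman", "jaccard", "minkowski", "canberra", "chebyshev")
}

#' Select the feature vector of the largest lesion
#'
#' @param features Numeric matrix, one row per lesion.
#' @param volumes Lesion volumes (mm^3); an error is raised when missing.
#' @param lesion_ids Lesion identifiers; volume ties are broken by the
#'   smallest identifier (deterministic under row permutation).
#' @return The selected row, with attribute `lesion_id`.
#' @export
select_largest_lesion <- function(features, volumes, lesion_ids = NULL) {
  features <- as.matrix(features)
  if (is.null(volumes) || any(is.na(volumes))) stop("lesion volumes are required")
  stopifnot(length(volumes) == nrow(features))
  if (is.null(lesion_ids)) lesion_ids <- seq_len(nrow(features))
  cand <- which(volumes == max(volumes))
  sel <- cand[order(lesion_ids[cand])][1]
  structure(features[sel, ], lesion_id = lesion_ids[sel])
}

#' Elementwise min / average / max feature summaries over a patient's lesions
#'
#' @param features Numeric matrix (>= 2 lesion rows).
#' @return Named vector concatenating the three summaries with `min_`,
#'   `avg_`, `max_` prefixes.
#' @export
summarize_min_avg_max <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need >= 2 lesions")
  lo <- apply(features, 2, min)
  av <- colMeans(features)
  hi <- apply(features, 2, max)
  c(setNames(lo, paste0("min_", colnames(features))),
    setNames(av, paste0("avg_", colnames(features))),
    setNames(hi, paste0("max_", colnames(features))))
}

#' IPITH summaries of one patient's pairwise lesion distances
#'
#' Computes all k(k-1)/2 pairwise distances between a patient's lesion
#' feature vectors under one metric, then summarizes the distance vector
#' with min, mean, max, and range. For the Jaccard metric the lesion vectors
#' should first be min-max rescaled to `[0, 1]` per feature over the cohort;
#' supply the cohort ranges via `rescale_range`. Undefined Spearman
#' distances (constant lesion vectors) are set to 0 with a warning.
#'
#' @param features Numeric matrix, one row per lesion (>= 2).
#' @param metric One of [ipith_metrics()].
#' @param p Minkowski order.
#' @param rescale_range Optional list with `min` and `max` per-feature
#'   cohort vectors, applied before Jaccard.
#' @return Named vector `<metric>_{min,mean,max,range}`.
#' @export
ipith_summaries <- function(features, metric, p = 3, rescale_range = NULL) {
  features <- as.matrix(features)
  k <- nrow(features)
  if (k < 2L) stop("IPITH requires >= 2 lesions")
  if (metric == "jaccard" && !is.null(rescale_range)) {
    rng <- pmax(rescale_range$max - rescale_range$min, .Machine$double.eps)
    features <- sweep(sweep(features, 2, rescale_range$min), 2, rng, `/`)
    features <- pmin(pmax(features, 0), 1)
  }
  d <- numeric(0)
  warned <- FALSE
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      dij <- pairwise_lesion_distance(features[i, ], features[j, ], metric, p)
      if (is.na(dij)) {
        if (!warned) {
          warning("undefined ", metric, " distance (constant lesion vector); set to 0")
          warned <- TRUE
        }
        dij <- 0
      }
      d <- c(d, dij)
    }
  }
  setNames(c(min(d), mean(d), max(d), max(d) - min(d)),
           paste0(metric, c("_min", "_mean", "_max", "_range")))
}

#' Build the per-patient predictor table
#'
#' Collapses a per-lesion feature table into one row per patient: the
#' largest-lesion features (`largest_` prefix), the elementwise min/avg/max
#' summaries, and the IPITH distance summaries for the requested metrics.
#' IPITH summary columns are center scaled across the cohort afterwards
#' (matching the treatment of the features themselves); set
#' `scale_ipith = FALSE` to keep raw distances.
#'
#' @param lesions Per-lesion data.frame with `patient_id`, `lesion_id`,
#'   `volume_mm3`, and the feature columns.
#' @param feature_cols Character vector of feature column names (assumed
#'   robust and center scaled).
#' @param metrics IPITH metrics to include.
#' @param minkowski_p Minkowski order.
#' @param scale_ipith Center scale the IPITH summary columns across patients.
#' @return Data.frame, one row per patient, with attribute `ipith_cols`.
#' @export
patient_predictor_table <- function(lesions, feature_cols,
                                    metrics = ipith_metrics(),
                                    minkowski_p = 3,
                                    scale_ipith = TRUE) {
  stopifnot(all(c("patient_id", "lesion_id", "volume_mm3") %in% names(lesions)),
            all(feature_cols %in% names(lesions)))
  X_all <- as.matrix(lesions[, feature_cols, drop = FALSE])
  rng <- list(min = apply(X_all, 2, min), max = apply(X_all, 2, max))
  ids <- unique(lesions$patient_id)
  rows <- lapply(ids, function(pid) {
    sub <- lesions[lesions$patient_id == pid, , drop = FALSE]
    if (nrow(sub) < 2L) stop("patient ", pid, " has fewer than 2 lesions")
    X <- as.matrix(sub[, feature_cols, drop = FALSE])
    largest <- select_largest_lesion(X, sub$volume_mm3, sub$lesion_id)
    mam <- summarize_min_avg_max(X)
    ip <- unlist(lapply(metrics, function(m) {
      ipith_summaries(X, m, p = minkowski_p,
                      rescale_range = if (m == "jaccard") rng else NULL)
    }))
    c(setNames(as.numeric(largest), paste0("largest_", feature_cols)), mam, ip)
  })
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  out <- cbind(data.frame(patient_id = ids), out)
  ipith_cols <- unlist(lapply(metrics, function(m) {
    paste0(m, c("_min", "_mean", "_max", "_range"))
  }))
  if (scale_ipith) {
    for (cc in ipith_cols) {
      s <- sd(out[[cc]])
      out[[cc]] <- if (is.finite(s) && s > 0) (out[[cc]] - mean(out[[cc]])) / s
                   else out[[cc]] - mean(out[[cc]])
    }
  }
  structure(out, ipith_cols = ipith_cols,
            largest_cols = paste0("largest_", feature_cols),
            summary_cols = names(rows[[1]])[!names(rows[[1]]) %in%
                                              c(paste0("largest_", feature_cols), ipith_cols)])
}
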