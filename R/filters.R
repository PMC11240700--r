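#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single rater - the standard
#' formulation for radiomics test-retest robustness. Symmetric in the two
#' measurement vectors.
#'
#' @param x,y Paired measurement vectors (e.g. features from the original and
#'   the eroded segmentation of the same lesions).
#' @return ICC value in `[-1, 1]`, or `NA` when the between-subject variance
#'   is degenerate.
#' @export
icc21 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  M <- cbind(x, y)
  k <- 2
  grand <- mean(M)
  row_m <- rowMeans(M)
  col_m <- colMeans(M)
  msr <- k * sum((row_m - grand)^2) / (n - 1)                 # rows (subjects)
  msc <- n * sum((col_m - grand)^2) / (k - 1)                 # columns (raters)
  sse <- sum((M - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (!is.finite(denom) || denom == 0) return(NA_real_)
  (msr - mse) / denom
}

#' Segmentation-robustness filter via erosion ICC
#'
#' For each feature, computes ICC(2,1) between the values extracted from the
#' original and the one-voxel-eroded segmentations of the same lesions, and
#' keeps the feature iff ICC > `threshold` (strictly). Features with zero
#' between-lesion variance have undefined ICC and are dropped.
#'
#' @param original,eroded Numeric matrices (lesions x features) with matched
#'   rows and identical column names.
#' @param threshold Keep threshold (default 0.85).
#' @return A data.frame of class `robustness_report` with columns `feature`,
#'   `icc`, `keep`, and attribute `n_lesions`.
#' @export
icc_robustness_filter <- function(original, eroded, threshold = 0.85) {
  original <- as.matrix(original); eroded <- as.matrix(eroded)
  if (!identical(dim(original), dim(eroded)) ||
      !identical(colnames(original), colnames(eroded))) {
    stop("`original` and `eroded` must have matched lesions and features")
  }
  if (nrow(original) < 10L) {
    warning("fewer than 10 matched lesions: ICC estimates will be unstable")
  }
  icc <- vapply(seq_len(ncol(original)), function(j) {
    icc21(original[, j], eroded[, j])
  }, numeric(1))
  rep <- data.frame(feature = colnames(original), icc = icc,
                    keep = !is.na(icc) & icc > threshold)
  structure(rep, class = c("robustness_report", "data.frame"),
            n_lesions = nrow(original), threshold = threshold)
}

#' Near-zero-variance filter
#'
#' Drops features that are (almost) constant across the cohort: a feature is
#' near zero variance when the frequency ratio of its most common to its
#' second most common value exceeds `freq_ratio` AND its number of distinct
#' values is below `unique_prop` of the number of rows.
#'
#' @param x Numeric matrix or data.frame (rows = lesions or patients).
#' @param freq_ratio Frequency-ratio cutoff (default 19, i.e. 95/5).
#' @param unique_prop Distinct-value proportion cutoff (default 0.1).
#' @return List with `kept` and `dropped` feature names and a `stats`
#'   data.frame (`feature`, `freq_ratio`, `unique_prop`, `nzv`).
#' @export
near_zero_variance_filter <- function(x, freq_ratio = 19, unique_prop = 0.1) {
  x <- as.data.frame(x)
  if (nrow(x) < 2L) stop("need at least 2 rows")
  stats <- do.call(rbind, lapply(names(x), function(nm) {
    tab <- sort(table(x[[nm]]), decreasing = TRUE)
    fr <- if (length(tab) == 1L) Inf else as.numeric(tab[1] / tab[2])
    up <- length(tab) / nrow(x)
    data.frame(feature = nm, freq_ratio = fr, unique_prop = up,
               nzv = fr > freq_ratio && up < unique_prop)
  }))
  list(kept = stats$feature[!stats$nzv],
       dropped = stats$feature[stats$nzv],
       stats = stats)
}

#' Center and scale a feature matrix
#'
#' Standardizes each feature to mean 0 and sample SD 1 across rows (applied
#' to the robust features so that all dimensions contribute comparably to
#' distance measurements and modelling). The transform parameters are
#' returned for leakage-safe reuse on new data.
#'
#' @param x Numeric matrix or data.frame.
#' @return List with `scaled` (matrix), `center`, and `scale`; an error names
#'   any zero-SD feature (those should have been removed by
#'   [near_zero_variance_filter()]).
#' @export
center_scale <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  bad <- colnames(x)[!is.finite(scl) | scl == 0]
  if (length(bad) > 0) {
    stop("zero-SD feature(s): ", paste(bad, collapse = ", "))
  }
  list(scaled = scale(x, center = ctr, scale = scl)[, , drop = FALSE],
       center = ctr, scale = scl)
}

#' @rdname center_scale
#' @param center,scale Parameters from a previous [center_scale()] fit.
#' @export
apply_center_scale <- function(x, center, scale) {
  x <- as.matrix(x)
  scale(x, center = center[colnames(x)], scale = scale[colnames(x)])[, , drop = FALSE]
}
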