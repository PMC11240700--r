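#' The 13 unique one-voxel 3-D displacement directions
#'
#' All offsets in \{-1, 0, 1\}^3 excluding the origin, with antipodal pairs
#' merged (each pair represented by its lexicographically positive member):
#' exactly 13 directions, the standard set for 3-D co-occurrence and
#' run-length texture matrices at one voxel displacement.
#'
#' @return A 13 x 3 integer matrix of offsets.
#' @export
texture_directions <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ## keep one representative per antipodal pair: first nonzero entry positive
  keep <- apply(g, 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  })
  out <- g[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Intensity (discretized histogram) features
## ---------------------------------------------------------------------------

#' Histogram-based intensity features on the discretized gray levels
#'
#' Statistics of the in-mask discretized gray-level histogram: moments
#' (population convention), energy \eqn{\sum p_k^2}, entropy
#' \eqn{-\sum p_k \log_2 p_k}, and level percentiles. For a single-voxel
#' mask, variance-based features are 0 and skewness/kurtosis are returned as
#' `NA` (undefined).
#'
#' @param levels Integer gray-level array (`NA` outside the analysis mask),
#'   as returned by [discretize_volume()].
#' @param mask Analysis mask.
#' @return Named numeric vector of `hist_*` features.
#' @export
compute_intensity_features <- function(levels, mask) {
  g <- as.numeric(levels[mask == 1L])
  g <- g[!is.na(g)]
  if (length(g) == 0L) stop("empty analysis mask")
  n <- length(g)
  m <- mean(g)
  v <- mean((g - m)^2)            # population variance (IBSI convention)
  sk <- if (n < 2L || v == 0) NA_real_ else mean((g - m)^3) / v^1.5
  ku <- if (n < 2L || v == 0) NA_real_ else mean((g - m)^4) / v^2
  p <- tabulate(as.integer(g))
  p <- p[p > 0] / n
  q <- quantile(g, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  c(hist_mean = m,
    hist_variance = v,
    hist_skewness = sk,
    hist_kurtosis = ku,
    hist_energy = sum(p^2),
    hist_entropy_log2 = -sum(p * log2(p)),
    hist_min = min(g),
    hist_p10 = q[1], hist_p25 = q[2], hist_median = q[3],
    hist_p75 = q[4], hist_p90 = q[5],
    hist_max = max(g),
    hist_iqr = q[4] - q[2],
    hist_range = max(g) - min(g))
}

## ---------------------------------------------------------------------------
## Shape features
## ---------------------------------------------------------------------------

#' Morphological (shape) features of a binary lesion mask
#'
#' Volume (voxel counting), surface area (exposed voxel faces, the convention
#' recorded in the feature metadata), sphericity
#' \eqn{\pi^{1/3}(6V)^{2/3}/A}, compactness \eqn{V/(\sqrt{\pi} A^{3/2})},
#' and the maximum 3-D diameter between boundary voxel centres.
#'
#' @param mask Binary 3-D array.
#' @param voxel_size mm triple.
#' @return Named numeric vector of `shape_*` features.
#' @export
compute_shape_features <- function(mask, voxel_size) {
  stopifnot(is_binary_mask(mask), length(voxel_size) == 3L)
  n <- sum(mask)
  if (n == 0L) stop("empty mask")
  vs <- voxel_size
  vol <- n * prod(vs)

  face_area <- c(vs[2] * vs[3], vs[1] * vs[3], vs[1] * vs[2])
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  surf <- 0
  exposed <- array(FALSE, dim = dim(mask))
  for (r in seq_len(nrow(offs))) {
    nb <- shift_array(mask, offs[r, ])
    nb[is.na(nb)] <- 0L
    ex <- mask == 1L & nb == 0L
    surf <- surf + sum(ex) * face_area[which(offs[r, ] != 0)]
    exposed <- exposed | ex
  }

  idx <- which(exposed, arr.ind = TRUE)
  if (nrow(idx) > 4000L) {      # cap the O(n^2) diameter search
    idx <- idx[seq(1L, nrow(idx), length.out = 4000L), , drop = FALSE]
  }
  pts <- sweep(idx, 2, vs, `*`)
  maxd <- if (nrow(pts) == 1L) 0 else sqrt(max(as.numeric(stats::dist(pts))^2))

  sph <- pi^(1 / 3) * (6 * vol)^(2 / 3) / surf
  comp <- vol / (sqrt(pi) * surf^1.5)
  c(shape_volume_mm3 = vol,
    shape_volume_cm3 = vol / 1000,
    shape_surface_mm2 = surf,
    shape_sphericity = sph,
    shape_compactness = comp,
    shape_max_diameter_mm = maxd)
}

## ---------------------------------------------------------------------------
## GLCM
## ---------------------------------------------------------------------------

## Symmetric co-occurrence counts for one direction; B x B matrix.
glcm_matrix <- function(levels, off, B) {
  b <- shift_array(levels, off)
  ok <- !is.na(levels) & !is.na(b)
  if (!any(ok)) return(NULL)
  i <- as.integer(levels[ok]); j <- as.integer(b[ok])
  cnt <- tabulate((i - 1L) * B + j, nbins = B * B)
  M <- matrix(cnt, nrow = B, byrow = TRUE)  # M[i, j] = #pairs (i -> j)
  M + t(M)   # symmetric accumulation
}

glcm_features_one <- function(P) {
  p <- P / sum(P)
  B <- nrow(p)
  i <- matrix(seq_len(B), B, B)
  j <- t(i)
  pij <- p
  mu_i <- sum(i * pij)
  mu_j <- sum(j * pij)
  s_i <- sqrt(sum((i - mu_i)^2 * pij))
  s_j <- sqrt(sum((j - mu_j)^2 * pij))
  nz <- pij > 0
  corr <- if (s_i * s_j > 0) sum((i - mu_i) * (j - mu_j) * pij) / (s_i * s_j) else 0
  c(glcm_contrast = sum((i - j)^2 * pij),
    glcm_dissimilarity = sum(abs(i - j) * pij),
    glcm_homogeneity = sum(pij / (1 + (i - j)^2)),
    glcm_energy = sum(pij^2),
    glcm_entropy_log2 = -sum(pij[nz] * log2(pij[nz])),
    glcm_correlation = corr)
}

#' Gray-level co-occurrence matrix features
#'
#' Symmetric co-occurrence matrices are accumulated at one voxel displacement
#' over the given directions (default: the 13 unique 3-D directions) and the
#' features are averaged over directions. Correlation with a degenerate
#' (zero-variance) matrix is defined as 0.
#'
#' @param levels Discretized gray-level array (`NA` outside the analysis mask).
#' @param mask Analysis mask (>= 2 voxels).
#' @param n_levels Number of gray levels `B`.
#' @param directions Integer matrix of offsets, one per row.
#' @return Named numeric vector of `glcm_*` features (NA when no direction
#'   contains a valid voxel pair).
#' @export
compute_glcm_features <- function(levels, mask, n_levels,
                                  directions = texture_directions()) {
  if (sum(mask) < 2L) stop("need at least 2 analysis voxels")
  feats <- NULL
  used <- 0L
  for (r in seq_len(nrow(directions))) {
    M <- glcm_matrix(levels, directions[r, ], n_levels)
    if (is.null(M) || sum(M) == 0) next
    f <- glcm_features_one(M)
    feats <- if (is.null(feats)) f else feats + f
    used <- used + 1L
  }
  if (used == 0L) {
    warning("no valid voxel pair in any direction: GLCM features undefined")
    return(setNames(rep(NA_real_, 6L),
                    c("glcm_contrast", "glcm_dissimilarity", "glcm_homogeneity",
                      "glcm_energy", "glcm_entropy_log2", "glcm_correlation")))
  }
  feats / used
}

## ---------------------------------------------------------------------------
## GLRLM
## ---------------------------------------------------------------------------

## Run lengths (with their gray levels) for one direction. Runs are broken by
## analysis-mask holes (NA levels) and by grid boundaries.
glrlm_runs <- function(levels, off) {
  d <- dim(levels)
  ok <- which(!is.na(levels))
  if (length(ok) == 0L) return(NULL)
  ai <- arrayInd(ok, d)
  ## position along the direction: any axis with a nonzero component steps by
  ## +/-1 per move, so that coordinate (sign-adjusted) orders voxels in a line
  ax <- which(off != 0)[1]
  t_pos <- ai[, ax] * off[ax]
  base <- ai - t_pos %*% t(off)   # line anchor, constant per line
  key <- paste(base[, 1], base[, 2], base[, 3], sep = ",")
  o <- order(key, t_pos)
  key <- key[o]; t_pos <- t_pos[o]
  lev <- levels[ok][o]
  n <- length(lev)
  new_run <- c(TRUE, key[-1] != key[-n] | t_pos[-1] != t_pos[-n] + 1L |
                 lev[-1] != lev[-n])
  run_id <- cumsum(new_run)
  data.frame(level = lev[new_run],
             length = tabulate(run_id))
}

#' Gray-level run-length matrix features
#'
#' Run-length matrices are built per direction (runs broken by analysis-mask
#' holes), feature values computed per IBSI formulas and averaged over the
#' directions: short-runs emphasis (IBSI 22OV), long-runs emphasis (IBSI
#' W4KF), run percentage (runs / voxels, IBSI 9ZK5), plus run-length and
#' gray-level non-uniformities.
#'
#' @inheritParams compute_glcm_features
#' @return Named numeric vector of `glrlm_*` features.
#' @export
compute_glrlm_features <- function(levels, mask,
                                   directions = texture_directions()) {
  nv <- sum(!is.na(levels) & mask == 1L)
  if (nv == 0L) stop("empty analysis mask")
  acc <- NULL
  used <- 0L
  for (r in seq_len(nrow(directions))) {
    runs <- glrlm_runs(levels, directions[r, ])
    if (is.null(runs) || nrow(runs) == 0L) next
    Nr <- nrow(runs)
    len <- runs$length
    sre <- sum(1 / len^2) / Nr
    lre <- sum(len^2) / Nr
    rp <- Nr / nv
    rlnu <- sum(table(len)^2) / Nr
    glnu <- sum(table(runs$level)^2) / Nr
    f <- c(glrlm_sre = sre, glrlm_lre = lre, glrlm_run_percentage = rp,
           glrlm_rlnu = rlnu, glrlm_glnu = glnu)
    acc <- if (is.null(acc)) f else acc + f
    used <- used + 1L
  }
  acc / used
}

## ---------------------------------------------------------------------------
## GLSZM
## ---------------------------------------------------------------------------

## Zone sizes: 26-connected components of equal gray level.
glszm_zones <- function(levels) {
  d <- dim(levels)
  ok <- which(!is.na(levels))
  if (length(ok) == 0L) return(integer(0))
  vid <- array(NA_integer_, dim = d)
  vid[ok] <- seq_along(ok)
  edges <- NULL
  dirs <- texture_directions()
  for (r in seq_len(nrow(dirs))) {
    nb_lev <- shift_array(levels, dirs[r, ])
    nb_id <- shift_array(vid, dirs[r, ])
    sel <- !is.na(levels) & !is.na(nb_lev) & levels == nb_lev
    if (!any(sel)) next
    edges <- rbind(edges, cbind(vid[sel], nb_id[sel]))
  }
  g <- igraph::make_empty_graph(n = length(ok), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  ## gray level of each component via its first member voxel
  first <- match(seq_len(comp$no), comp$membership)
  list(sizes = as.integer(comp$csize),
       levels = as.integer(levels[ok][first]))
}

#' Gray-level size-zone matrix features
#'
#' Zones are 26-connected components of equal gray level. Reports small-zone
#' emphasis (IBSI 5QRC), large-zone emphasis, zone percentage
#' (zones / voxels, IBSI P30P), normalised zone-size non-uniformity
#' \eqn{\sum_s n_s^2 / N_z^2} (IBSI VB3A), and gray-level non-uniformity.
#'
#' @inheritParams compute_glcm_features
#' @return Named numeric vector of `glszm_*` features.
#' @export
compute_glszm_features <- function(levels, mask) {
  nv <- sum(!is.na(levels) & mask == 1L)
  if (nv == 0L) stop("empty analysis mask")
  z <- glszm_zones(levels)
  Nz <- length(z$sizes)
  s <- z$sizes
  size_counts <- table(s)
  c(glszm_sze = sum(1 / s^2) / Nz,
    glszm_lze = sum(s^2) / Nz,
    glszm_zone_percentage = Nz / nv,
    glszm_nzsn = sum(size_counts^2) / Nz^2,
    glszm_glnu = sum(table(z$levels)^2) / Nz)
}

## ---------------------------------------------------------------------------
## Full extraction
## ---------------------------------------------------------------------------

#' Registry of extracted features
#'
#' @return A data.frame with columns `name`, `family`, and `ibsi_code`
#'   (the IBSI identifier where one applies, `NA` otherwise).
#' @export
feature_registry <- function() {
  reg <- rbind(
    data.frame(name = c("hist_mean", "hist_variance", "hist_skewness",
                        "hist_kurtosis", "hist_energy", "hist_entropy_log2",
                        "hist_min", "hist_p10", "hist_p25", "hist_median",
                        "hist_p75", "hist_p90", "hist_max", "hist_iqr",
                        "hist_range"),
               family = "histogram", ibsi_code = NA_character_),
    data.frame(name = c("shape_volume_mm3", "shape_volume_cm3",
                        "shape_surface_mm2", "shape_sphericity",
                        "shape_compactness", "shape_max_diameter_mm"),
               family = "shape", ibsi_code = NA_character_),
    data.frame(name = c("glcm_contrast", "glcm_dissimilarity",
                        "glcm_homogeneity", "glcm_energy",
                        "glcm_entropy_log2", "glcm_correlation"),
               family = "glcm", ibsi_code = NA_character_),
    data.frame(name = c("glrlm_sre", "glrlm_lre", "glrlm_run_percentage",
                        "glrlm_rlnu", "glrlm_glnu"),
               family = "glrlm", ibsi_code = NA_character_),
    data.frame(name = c("glszm_sze", "glszm_lze", "glszm_zone_percentage",
                        "glszm_nzsn", "glszm_glnu"),
               family = "glszm", ibsi_code = NA_character_)
  )
  codes <- c(glszm_nzsn = "VB3A", glszm_sze = "5QRC",
             glszm_zone_percentage = "P30P", glrlm_lre = "W4KF",
             glrlm_run_percentage = "9ZK5", glrlm_sre = "22OV",
             hist_mean = "Q4LE", hist_variance = "ECT3", hist_skewness = "88K1",
             hist_kurtosis = "C3I7", hist_entropy_log2 = "TLU2",
             shape_volume_mm3 = "RNU0", shape_sphericity = "QCFX",
             glcm_contrast = "ACUI", glcm_correlation = "NI2N",
             glcm_energy = "8ZQL")
  reg$ibsi_code[match(names(codes), reg$name)] <- unname(codes)
  reg
}

#' Extract the full radiomics feature vector from a lesion
#'
#' Runs the extraction chain: optional resampling to the target voxel size,
#' HU-window discretization, then the histogram, shape, GLCM, GLRLM, and
#' GLSZM feature families. Extraction is deterministic.
#'
#' @param volume 3-D HU array.
#' @param mask Binary lesion mask.
#' @param voxel_size mm triple.
#' @param disc_config A [discretization_config()].
#' @param resample_spec A [resampling_spec()], or `NULL` to extract on the
#'   native grid.
#' @param directions Texture directions (default the 13 standard ones).
#' @return Named numeric vector (one value per registry feature) with
#'   attributes `registry` and `bin_convention`.
#' @export
extract_features <- function(volume, mask, voxel_size,
                             disc_config = discretization_config(),
                             resample_spec = resampling_spec(),
                             directions = texture_directions()) {
  if (!is.null(resample_spec)) {
    rs <- resample_volume(volume, mask, voxel_size, resample_spec)
    volume <- rs$volume; mask <- rs$mask; voxel_size <- rs$voxel_size
  }
  disc <- discretize_volume(volume, mask, disc_config)
  if (!disc$analyzable) {
    reg <- feature_registry()
    return(structure(setNames(rep(NA_real_, nrow(reg)), reg$name),
                    analyzable = FALSE))
  }
  out <- c(
    compute_intensity_features(disc$levels, disc$mask),
    compute_shape_features(mask, voxel_size),
    compute_glcm_features(disc$levels, disc$mask, disc$n_levels, directions),
    compute_glrlm_features(disc$levels, disc$mask, directions),
    compute_glszm_features(disc$levels, disc$mask)
  )
  structure(out, registry = feature_registry(),
            bin_convention = "half-open [lo+(k-1)w, lo+kw), top bin closed",
            surface_convention = "voxel-face")
}
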