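#' Resampling specification
#'
#' @param target_voxel Target voxel size, mm triple (default 1 x 1 x 2 mm).
#' @param intensity_interpolator `"bspline"` (separable cubic interpolating
#'   spline, the default) or `"linear"`.
#' @param mask_interpolator Only `"nearest"` is supported (masks stay binary).
#' @return An object of class `resampling_spec`.
#' @export
resampling_spec <- function(target_voxel = c(1, 1, 2),
                            intensity_interpolator = c("bspline", "linear"),
                            mask_interpolator = "nearest") {
  intensity_interpolator <- match.arg(intensity_interpolator)
  mask_interpolator <- match.arg(mask_interpolator)
  if (length(target_voxel) != 3L || any(target_voxel <= 0)) {
    stop("`target_voxel` must be a strictly positive mm triple")
  }
  structure(list(target_voxel = as.numeric(target_voxel),
                 intensity_interpolator = intensity_interpolator,
                 mask_interpolator = mask_interpolator),
            class = "resampling_spec")
}

## Interpolate a 3-D array along one axis at new voxel-centre coordinates.
## `method` is "spline" (natural cubic) or "linear"; coordinates are clamped
## to the input extent (no extrapolation).
interp_axis <- function(arr, axis, old_x, new_x, method) {
  new_x <- pmin(pmax(new_x, min(old_x)), max(old_x))
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- matrix(a, nrow = d[1])
  out <- matrix(0, nrow = length(new_x), ncol = ncol(m))
  if (length(old_x) == 1L) {
    out[] <- rep(m[1, ], each = length(new_x))
  } else {
    for (j in seq_len(ncol(m))) {
      out[, j] <- if (method == "spline") {
        splinefun(old_x, m[, j], method = "natural")(new_x)
      } else {
        approx(old_x, m[, j], xout = new_x, rule = 2)$y
      }
    }
  }
  b <- array(out, dim = c(length(new_x), d[2], d[3]))
  aperm(b, order(perm))
}

#' Resample a volume/mask pair to a target voxel size
#'
#' Intensities are interpolated with a separable cubic spline (per the
#' `"bspline"` label) or trilinearly; the mask is resampled by nearest
#' neighbour so it remains binary. Voxel centres are aligned at the volume
#' origin; coordinates outside the input extent are clamped.
#'
#' @param volume 3-D intensity array.
#' @param mask Same-shape binary array.
#' @param voxel_size Input voxel size (mm triple); an error is raised when
#'   missing or invalid (spacing metadata is required).
#' @param spec A [resampling_spec()].
#' @return List with `volume`, `mask`, `voxel_size` (= target).
#' @export
resample_volume <- function(volume, mask, voxel_size, spec = resampling_spec()) {
  if (missing(voxel_size) || is.null(voxel_size) || length(voxel_size) != 3L ||
      any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("input voxel-size metadata is missing or invalid")
  }
  stopifnot(inherits(spec, "resampling_spec"), is_binary_mask(mask),
            all(dim(volume) == dim(mask)))
  dims <- dim(volume)
  tgt <- spec$target_voxel
  new_dims <- pmax(1L, as.integer(round(dims * voxel_size / tgt)))

  old_x <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * voxel_size[a])
  new_x <- lapply(1:3, function(a) (seq_len(new_dims[a]) - 0.5) * tgt[a])

  method <- if (spec$intensity_interpolator == "bspline") "spline" else "linear"
  v <- volume
  for (a in 1:3) v <- interp_axis(v, a, old_x[[a]], new_x[[a]], method)

  ## nearest-neighbour mask resampling via index lookup
  ix <- lapply(1:3, function(a) {
    i <- round((new_x[[a]] - voxel_size[a] / 2) / voxel_size[a]) + 1
    pmin(pmax(as.integer(i), 1L), dims[a])
  })
  m <- mask[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  m <- array(as.integer(m), dim = new_dims)

  list(volume = v, mask = m, voxel_size = tgt)
}

#' Gray-level discretization configuration
#'
#' Defaults reproduce the standard lung-CT window used throughout the
#' pipeline: 120 gray levels of width 2.5 HU from -100 to +200 HU; voxels
#' outside the window are excluded from the analysis mask.
#'
#' @param lower_bound,upper_bound HU window.
#' @param bin_width Bin width in HU; `(upper - lower) / width` must be a
#'   positive integer.
#' @return An object of class `discretization_config` with element `n_levels`.
#' @export
discretization_config <- function(lower_bound = -100, upper_bound = 200,
                                  bin_width = 2.5) {
  nb <- (upper_bound - lower_bound) / bin_width
  if (!isTRUE(all.equal(nb, round(nb))) || nb < 1) {
    stop("(upper_bound - lower_bound) / bin_width must be a positive integer")
  }
  structure(list(lower_bound = lower_bound, upper_bound = upper_bound,
                 bin_width = bin_width, n_levels = as.integer(round(nb))),
            class = "discretization_config")
}

#' Discretize a volume into integer gray levels inside the HU window
#'
#' In-mask voxels with HU inside `[lower, upper]` are mapped to levels
#' `1..B` using half-open bins `[lower + (k-1)w, lower + kw)` with the top
#' bin closed; in-mask voxels outside the window are removed from the
#' analysis mask.
#'
#' @param volume 3-D HU array.
#' @param mask Binary lesion mask.
#' @param config A [discretization_config()].
#' @return List with `levels` (integer array, `NA` outside the analysis
#'   mask), `mask` (analysis mask after exclusion), `n_levels`, and
#'   `analyzable` (`FALSE`, with a warning, when exclusion empties the mask).
#' @export
discretize_volume <- function(volume, mask, config = discretization_config()) {
  stopifnot(inherits(config, "discretization_config"), is_binary_mask(mask),
            all(dim(volume) == dim(mask)))
  B <- config$n_levels
  w <- config$bin_width
  inside <- mask == 1L & volume >= config$lower_bound & volume <= config$upper_bound
  lev <- array(NA_integer_, dim = dim(volume))
  lev[inside] <- pmin(
    as.integer(floor((volume[inside] - config$lower_bound) / w)) + 1L, B
  )
  amask <- array(as.integer(inside), dim = dim(mask))
  analyzable <- sum(amask) > 0L
  if (!analyzable) {
    warning("all in-mask voxels fall outside the HU window: unanalyzable lesion")
  }
  list(levels = lev, mask = amask, n_levels = B, analyzable = analyzable)
}

## One shift of a 3-D array by an integer offset, NA-filled at borders.
shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(NA, dim = d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) {
      src[[ax]] <- seq_len(d[ax] - o)
      dst[[ax]] <- seq_len(d[ax] - o) + o
    } else {
      src[[ax]] <- seq_len(d[ax] + o) - o
      dst[[ax]] <- seq_len(d[ax] + o)
    }
    if (length(src[[ax]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Erode a binary mask by one voxel (6-connected)
#'
#' A voxel survives the erosion iff it and all six face neighbours lie inside
#' the mask; voxels touching the array boundary are eroded away. Used to
#' build the secondary volume of interest for the segmentation-robustness
#' (ICC) analysis. An empty result signals that the lesion must be excluded
#' from the robustness set (reported by the caller, not fatal here).
#'
#' @param mask Binary 3-D array.
#' @return Eroded binary array (subset of the input).
#' @export
erode_mask <- function(mask) {
  stopifnot(is_binary_mask(mask))
  keep <- mask == 1L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  for (r in seq_len(nrow(offs))) {
    nb <- shift_array(mask, offs[r, ])
    nb[is.na(nb)] <- 0L
    keep <- keep & nb == 1L
  }
  array(as.integer(keep), dim = dim(mask))
}
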