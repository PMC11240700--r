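#' Configuration for a simulated textured lesion volume
#'
#' Defines a single synthetic 3-D CT lesion: an ellipsoidal (spherical in mm)
#' mask embedded in a regular voxel grid, with one of three texture regimes
#' controlling the spatial structure of in-mask Hounsfield units.
#'
#' @param grid_shape Integer triple, voxels per axis.
#' @param voxel_size Numeric triple, mm per axis (default 1 x 1 x 2 mm).
#' @param lesion_radius Lesion radius in mm. A lesion is flagged as a
#'   radiomics target lesion (RTL) when its volume is at least 1 cm^3.
#' @param texture_regime One of `"smooth"` (constant base intensity),
#'   `"speckled"` (independent per-voxel draws across `intensity_range`), or
#'   `"banded"` (sinusoidal bands along z).
#' @param intensity_range HU interval covered by the texture.
#' @param noise_sd Additive Gaussian noise, HU.
#' @param seed Integer seed; generation is fully deterministic given the seed.
#' @return An object of class `volume_sim_config`.
#' @export
volume_sim_config <- function(grid_shape = c(32L, 32L, 16L),
                              voxel_size = c(1, 1, 2),
                              lesion_radius = 8,
                              texture_regime = c("speckled", "smooth", "banded"),
                              intensity_range = c(-50, 150),
                              noise_sd = 5,
                              seed = 1L) {
  texture_regime <- match.arg(texture_regime)
  if (length(grid_shape) != 3L || any(grid_shape < 1)) {
    stop("`grid_shape` must be a positive integer triple")
  }
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("`voxel_size` must be a positive mm triple")
  }
  stopifnot_scalar_number(lesion_radius, "lesion_radius", positive = TRUE)
  if (length(intensity_range) != 2L || diff(intensity_range) < 0) {
    stop("`intensity_range` must be an increasing HU interval")
  }
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_size = as.numeric(voxel_size),
         lesion_radius = lesion_radius, texture_regime = texture_regime,
         intensity_range = as.numeric(intensity_range), noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "volume_sim_config"
  )
}

#' Generate a textured lesion volume and its label mask
#'
#' Produces a 3-D intensity array (HU) and a same-shape binary mask. The mask
#' is a single 26-connected spherical component; the texture regime
#' deterministically controls the spatial autocorrelation of in-mask
#' intensities (smooth > banded > speckled).
#'
#' @param config A [volume_sim_config()].
#' @return A list of class `lesion_volume` with elements `volume` (HU array),
#'   `mask` (0/1 array), `voxel_size` (mm), `volume_mm3`, `is_target_lesion`
#'   (TRUE when volume >= 1 cm^3), and `config`.
#' @export
generate_textured_lesion <- function(config) {
  stopifnot(inherits(config, "volume_sim_config"))
  dims <- config$grid_shape
  vs <- config$voxel_size
  ## lesion plus a 2-voxel margin must fit inside the grid
  need <- 2 * config$lesion_radius / vs + 4
  if (any(need > dims)) {
    stop("lesion (plus 2-voxel margin) does not fit in the grid; enlarge `grid_shape`")
  }

  centre <- (dims + 1) / 2
  cx <- (seq_len(dims[1]) - centre[1]) * vs[1]
  cy <- (seq_len(dims[2]) - centre[2]) * vs[2]
  cz <- (seq_len(dims[3]) - centre[3]) * vs[3]
  d2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  mask <- array(as.integer(d2 <= config$lesion_radius^2), dim = dims)

  lo <- config$intensity_range[1]
  hi <- config$intensity_range[2]
  mid <- (lo + hi) / 2
  vol <- with_seed(config$seed, {
    base <- switch(config$texture_regime,
      smooth = array(mid, dim = dims),
      speckled = array(runif(prod(dims), lo, hi), dim = dims),
      banded = {
        ## ~4 mm period bands along z spanning the intensity range
        z <- rep(cz, each = dims[1] * dims[2])
        array(mid + (hi - lo) / 2 * sin(2 * pi * z / 8), dim = dims)
      }
    )
    noise <- if (config$noise_sd > 0) {
      array(rnorm(prod(dims), 0, config$noise_sd), dim = dims)
    } else {
      0
    }
    base + noise
  })
  vol[mask == 0L] <- lo - 100  # background well below the analysis window
  stopifnot(all(is.finite(vol)))

  vol_mm3 <- sum(mask) * prod(vs)
  structure(
    list(volume = vol, mask = mask, voxel_size = vs, volume_mm3 = vol_mm3,
         is_target_lesion = vol_mm3 >= 1000, config = config),
    class = "lesion_volume"
  )
}

#' Write / read a lesion volume as a NIfTI pair
#'
#' @param lesion A `lesion_volume`.
#' @param prefix Output path prefix; writes `<prefix>_vol.nii.gz` and
#'   `<prefix>_mask.nii.gz` with the voxel size recorded in the header.
#' @return `write_lesion_nifti()` returns the two paths invisibly;
#'   `read_lesion_nifti()` returns a `lesion_volume`-shaped list.
#' @export
write_lesion_nifti <- function(lesion, prefix) {
  stopifnot(inherits(lesion, "lesion_volume"))
  vol_path <- paste0(prefix, "_vol.nii.gz")
  mask_path <- paste0(prefix, "_mask.nii.gz")
  vi <- RNifti::asNifti(lesion$volume)
  mi <- RNifti::asNifti(lesion$mask)
  RNifti::pixdim(vi) <- lesion$voxel_size
  RNifti::pixdim(mi) <- lesion$voxel_size
  RNifti::writeNifti(vi, vol_path)
  RNifti::writeNifti(mi, mask_path)
  invisible(c(volume = vol_path, mask = mask_path))
}

#' @rdname write_lesion_nifti
#' @param vol_path,mask_path Paths to the NIfTI intensity volume and mask.
#' @export
read_lesion_nifti <- function(vol_path, mask_path) {
  vol <- RNifti::readNifti(vol_path)
  msk <- RNifti::readNifti(mask_path)
  vs <- RNifti::pixdim(vol)[1:3]
  if (any(!is.finite(vs)) || any(vs <= 0)) {
    stop("missing or invalid voxel-size metadata in ", vol_path)
  }
  list(volume = array(as.numeric(vol), dim = dim(vol)),
       mask = array(as.integer(msk > 0.5), dim = dim(msk)),
       voxel_size = as.numeric(vs))
}
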