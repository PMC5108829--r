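#' Voxel volumes: activity concentration and attenuation maps
#'
#' A `pet_volume` is a 3D numeric array (x, y, z) with physical voxel sizes
#' in cm attached. Two interpretations are used throughout the package:
#' activity concentration in kBq/ml, and 511 keV linear attenuation
#' coefficients (a mu-map) in 1/cm. Water has mu = 0.096/cm at 511 keV;
#' lead about 1.75/cm.
#'
#' @param values 3D numeric array, all finite.
#' @param voxel_cm numeric length-3: voxel size (dx, dy, dz) in cm.
#' @param kind `"activity"` (values must be >= 0), `"mu"` (values must lie
#'   in \[0, 2\] 1/cm), or `"image"` (a reconstructed or derived map, which
#'   may hold negative ringing).
#'
#' @return A `pet_volume` object (the array with attributes).
#' @export
pet_volume <- function(values, voxel_cm, kind = c("activity", "mu", "image")) {
  kind <- match.arg(kind)
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (!all(is.finite(values))) stop("volume values must all be finite")
  if (kind == "activity" && any(values < 0)) {
    stop("activity values must be nonnegative")
  }
  if (kind == "mu" && (any(values < 0) || any(values > 2))) {
    stop("mu values must lie in [0, 2] 1/cm")
  }
  voxel_cm <- as.numeric(voxel_cm)
  stopifnot(length(voxel_cm) == 3L, all(voxel_cm > 0))
  structure(values,
    voxel_cm = voxel_cm, kind = kind,
    class = c("pet_volume", "array")
  )
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x)
  v <- attr(x, "voxel_cm")
  cat(sprintf(
    "<pet_volume:%s> %d x %d x %d voxels (%.2f x %.2f x %.2f cm), range [%.4g, %.4g]\n",
    attr(x, "kind"), d[1], d[2], d[3], v[1], v[2], v[3], min(x), max(x)
  ))
  invisible(x)
}

#' Voxel volume in ml (= cm^3)
#' @param vol a [pet_volume()].
#' @return scalar voxel volume in cm^3.
#' @export
voxel_volume_ml <- function(vol) {
  prod(attr(vol, "voxel_cm"))
}

# voxel center coordinates (cm), origin at the grid center
.grid_axis <- function(n, d) (seq_len(n) - (n + 1) / 2) * d

#' Default image grid matched to a scanner geometry
#'
#' Square transaxial grid with voxel size equal to the radial bin width and
#' the scanner's slices on the z axis, so that projection and reconstruction
#' share one sampling convention.
#'
#' @param geometry a [scanner_geometry()].
#' @param nx,ny transaxial matrix size; defaults to `n_radial`.
#' @return list with `nx`, `ny`, `nz`, `voxel_cm`.
#' @export
default_grid <- function(geometry, nx = geometry$n_radial, ny = geometry$n_radial) {
  list(
    nx = as.integer(nx), ny = as.integer(ny), nz = geometry$n_slices,
    voxel_cm = c(
      geometry$radial_bin_cm, geometry$radial_bin_cm,
      geometry$slice_thickness_cm
    )
  )
}
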