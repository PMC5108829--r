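#' Scanner geometry for 2D-rebinned sinograms
#'
#' Describes the stack-of-2D sinogram space produced by Fourier rebinning of
#' a 3D brain PET acquisition: parallel-beam views over 180 degrees, radial
#' bins spanning the transaxial field of view, and contiguous axial slices.
#'
#' The defaults mirror a 59-slice scanner with 2.6 mm slice thickness and a
#' 128 x 128 image matrix of 2.0 mm voxels (2.0 mm radial bins, 12.8 cm
#' transaxial FOV radius).
#'
#' @param n_views number of projection angles over \[0, pi).
#' @param n_radial number of radial bins per view.
#' @param radial_bin_cm radial bin width (cm).
#' @param n_slices number of axial slices.
#' @param slice_thickness_cm axial slice thickness (cm).
#' @param fov_radius_cm transaxial field-of-view radius (cm). The radial
#'   axis must cover the FOV diameter: `n_radial * radial_bin_cm >=
#'   2 * fov_radius_cm`.
#'
#' @return An object of class `scanner_geometry`.
#' @export
#' @examples
#' g <- scanner_geometry()
#' g
scanner_geometry <- function(n_views = 96L,
                             n_radial = 128L,
                             radial_bin_cm = 0.2,
                             n_slices = 59L,
                             slice_thickness_cm = 0.26,
                             fov_radius_cm = 12.8) {
  n_views <- as.integer(n_views)
  n_radial <- as.integer(n_radial)
  n_slices <- as.integer(n_slices)
  stopifnot(
    n_views >= 1L, n_radial >= 1L, n_slices >= 1L,
    radial_bin_cm > 0, slice_thickness_cm > 0, fov_radius_cm > 0
  )
  if (n_radial * radial_bin_cm < 2 * fov_radius_cm - 1e-9) {
    stop("radial axis does not cover the FOV: need n_radial * radial_bin_cm >= 2 * fov_radius_cm")
  }
  structure(
    list(
      n_views = n_views,
      n_radial = n_radial,
      radial_bin_cm = radial_bin_cm,
      n_slices = n_slices,
      slice_thickness_cm = slice_thickness_cm,
      fov_radius_cm = fov_radius_cm
    ),
    class = "scanner_geometry"
  )
}

#' @export
print.scanner_geometry <- function(x, ...) {
  cat(sprintf(
    "<scanner_geometry> %d views x %d radial bins (%.2f cm) x %d slices (%.2f cm), FOV radius %.1f cm\n",
    x$n_views, x$n_radial, x$radial_bin_cm, x$n_slices, x$slice_thickness_cm,
    x$fov_radius_cm
  ))
  invisible(x)
}

#' Radial bin center coordinates
#'
#' Bin 1 is centered at `-fov_radius + bin/2`; bins advance by
#' `radial_bin_cm` so the axis is symmetric about the scanner center when
#' the radial extent equals the FOV diameter.
#'
#' @param geometry a [scanner_geometry()].
#' @return numeric vector of length `n_radial` (cm).
#' @export
radial_centers <- function(geometry) {
  stopifnot(inherits(geometry, "scanner_geometry"))
  -geometry$fov_radius_cm + (seq_len(geometry$n_radial) - 0.5) * geometry$radial_bin_cm
}

#' View angles in radians
#'
#' @param geometry a [scanner_geometry()].
#' @return numeric vector of length `n_views`, evenly spaced over \[0, pi).
#' @export
view_angles <- function(geometry) {
  stopifnot(inherits(geometry, "scanner_geometry"))
  (seq_len(geometry$n_views) - 1) * pi / geometry$n_views
}
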