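# Parallel-beam, slice-by-slice line-integral projector.
#
# Rebinned 2D PET data are a stack of independent transaxial sinograms, so
# projection reduces to a 2D Radon transform per slice. Rays are sampled at
# a fixed step along the line of response (LOR) and the image is read by
# bilinear interpolation (Joseph-style); all slices share the in-plane
# sample pattern of a view, so one view is projected for the whole stack at
# once with vectorized gathers.

# Per-view bilinear sampling pattern: indices and weights into the (nx, ny)
# pixel grid for every (t, s) sample point. Out-of-grid samples get zero
# weight. Returns idx/w vectors of length n_t * n_radial (t fastest).
.view_sampler <- function(geometry, nx, ny, voxel_cm, theta, step_cm) {
  s <- radial_centers(geometry)
  t_half <- geometry$fov_radius_cm
  tt <- seq(-t_half, t_half, by = step_cm)
  n_t <- length(tt)
  ct <- cos(theta); st <- sin(theta)
  # sample coords (cm): LOR direction (-sin, cos), radial direction (cos, sin)
  xs <- outer(tt, s, function(t, si) si * ct - t * st)
  ys <- outer(tt, s, function(t, si) si * st + t * ct)
  ix <- as.vector(xs) / voxel_cm[1] + (nx + 1) / 2
  iy <- as.vector(ys) / voxel_cm[2] + (ny + 1) / 2
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  i0 <- pmin(pmax(floor(ix), 1), nx - 1)
  j0 <- pmin(pmax(floor(iy), 1), ny - 1)
  fx <- ix - i0
  fy <- iy - j0
  zero <- !ok
  fx[zero] <- 0; fy[zero] <- 0
  base <- i0 + (j0 - 1) * nx
  w00 <- (1 - fx) * (1 - fy); w00[zero] <- 0
  w10 <- fx * (1 - fy);       w10[zero] <- 0
  w01 <- (1 - fx) * fy;       w01[zero] <- 0
  w11 <- fx * fy;             w11[zero] <- 0
  list(
    n_t = n_t, step = step_cm,
    id00 = base, id10 = base + 1, id01 = base + nx, id11 = base + nx + 1,
    w00 = w00, w10 = w10, w01 = w01, w11 = w11
  )
}

# line integrals for one view over all slices: returns (n_radial, n_slices)
.view_integrals <- function(sampler, amat, n_radial, n_slices) {
  p <- sampler$w00 * amat[sampler$id00, , drop = FALSE] +
    sampler$w10 * amat[sampler$id10, , drop = FALSE] +
    sampler$w01 * amat[sampler$id01, , drop = FALSE] +
    sampler$w11 * amat[sampler$id11, , drop = FALSE]
  dim(p) <- c(sampler$n_t, n_radial, n_slices)
  colSums(p) * sampler$step
}

.check_vol_geometry <- function(vol, geometry) {
  d <- dim(vol)
  if (d[3] != geometry$n_slices) {
    stop("volume has ", d[3], " slices but geometry expects ", geometry$n_slices)
  }
  vz <- attr(vol, "voxel_cm")[3]
  if (abs(vz - geometry$slice_thickness_cm) > 1e-9) {
    stop("volume slice thickness does not match the geometry")
  }
  invisible(TRUE)
}

#' Forward-project a volume into a sinogram of attenuated line integrals
#'
#' Computes, for every line of response (view angle, radial offset, slice),
#' the line integral of activity. When a mu-map is supplied the whole
#' integral is attenuated by `exp(-integral of mu)` along the same LOR, as
#' appropriate for coincidence detection (the attenuation factor of an
#' annihilation pair depends only on the total path, not on the emission
#' point).
#'
#' @param vol activity [pet_volume()] (kBq/ml).
#' @param geometry a [scanner_geometry()].
#' @param mu optional attenuation [pet_volume()] on the same grid (1/cm).
#' @param step_cm ray sampling step; defaults to half the in-plane voxel.
#' @return a `TRUES` [sinogram()]; units kBq/ml x cm per bin.
#' @export
forward_project <- function(vol, geometry, mu = NULL, step_cm = NULL) {
  stopifnot(inherits(vol, "pet_volume"), inherits(geometry, "scanner_geometry"))
  .check_vol_geometry(vol, geometry)
  if (!is.null(mu)) {
    stopifnot(inherits(mu, "pet_volume"))
    if (!identical(dim(mu), dim(vol))) stop("mu and activity grids differ")
  }
  d <- dim(vol)
  voxel <- attr(vol, "voxel_cm")
  if (is.null(step_cm)) step_cm <- voxel[1] / 2
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  amat <- matrix(as.numeric(vol), nx * ny, nz)
  mmat <- if (!is.null(mu)) matrix(as.numeric(mu), nx * ny, nz)
  out <- array(0, c(geometry$n_views, geometry$n_radial, nz))
  thetas <- view_angles(geometry)
  for (v in seq_along(thetas)) {
    sp <- .view_sampler(geometry, nx, ny, voxel, thetas[v], step_cm)
    p <- .view_integrals(sp, amat, geometry$n_radial, nz)
    if (!is.null(mmat)) {
      p <- p * exp(-.view_integrals(sp, mmat, geometry$n_radial, nz))
    }
    out[v, , ] <- p
  }
  sinogram(out, geometry, window = "TRUES")
}

#' Attenuation-correction-factor sinogram
#'
#' `ACF = exp(+ integral of mu)` along each LOR; multiplying an emission
#' sinogram by the ACF undoes photon attenuation. ACF >= 1 everywhere.
#'
#' @param mu attenuation [pet_volume()] (1/cm).
#' @param geometry a [scanner_geometry()].
#' @param step_cm ray sampling step; defaults to half the in-plane voxel.
#' @return an `ACF` [sinogram()].
#' @export
#' @examples
#' # 15 cm of water: ACF = exp(0.096 * 15) ~ 4.22
acf_sinogram <- function(mu, geometry, step_cm = NULL) {
  stopifnot(inherits(mu, "pet_volume"), inherits(geometry, "scanner_geometry"))
  .check_vol_geometry(mu, geometry)
  d <- dim(mu)
  voxel <- attr(mu, "voxel_cm")
  if (is.null(step_cm)) step_cm <- voxel[1] / 2
  mmat <- matrix(as.numeric(mu), d[1] * d[2], d[3])
  out <- array(0, c(geometry$n_views, geometry$n_radial, d[3]))
  thetas <- view_angles(geometry)
  for (v in seq_along(thetas)) {
    sp <- .view_sampler(geometry, d[1], d[2], voxel, thetas[v], step_cm)
    out[v, , ] <- exp(.view_integrals(sp, mmat, geometry$n_radial, d[3]))
  }
  sinogram(out, geometry, window = "ACF")
}

#' Mu line-integral sinogram
#'
#' The raw attenuation line integrals (the log of [acf_sinogram()]); used to
#' delimit the object's projected support when building tail masks.
#'
#' @inheritParams acf_sinogram
#' @return a [sinogram()] of integrals of mu (dimensionless).
#' @export
mu_line_integrals <- function(mu, geometry, step_cm = NULL) {
  acf <- acf_sinogram(mu, geometry, step_cm = step_cm)
  .sino_like(log(unclass(acf)), acf, window = "ACF")
}
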