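#' Build a digital phantom (activity, attenuation and tissue labels)
#'
#' Supported shapes:
#' \describe{
#'   \item{`uniform_cylinder`}{water cylinder of diameter `diameter_cm`
#'     with uniform activity — the well-counter calibration phantom.}
#'   \item{`iec_like`}{a larger elliptical (body-like) water phantom with
#'     uniform activity, standing in for an IEC body phantom.}
#'   \item{`brain`}{three nested ellipsoids: a gray-matter shell around a
#'     white-matter core, a surrounding CSF rim, and a thin bony shell
#'     (mu = 0.151/cm); default GM:WM:CSF activity 4:1:0.}
#' }
#' Water-equivalent regions get mu = 0.096/cm. Tissue labels: 0 background,
#' 1 main compartment (GM for the brain), 2 WM, 3 CSF, 4 skull.
#'
#' @param shape one of `"uniform_cylinder"`, `"iec_like"`, `"brain"`.
#' @param geometry a [scanner_geometry()]; the phantom is voxelized on
#'   [default_grid()].
#' @param activity_kbq_ml peak/main-compartment activity (kBq/ml). For the
#'   brain phantom this is the GM activity.
#' @param diameter_cm cylinder diameter (default 15 cm).
#' @param semiaxes_cm for `iec_like`: transaxial semiaxes (cm).
#' @param gm_wm_csf activity ratio triplet for the brain phantom.
#' @param axial_fraction fraction of the axial extent occupied by the object
#'   (centered); 1 fills all slices.
#' @param mu_water,mu_bone attenuation coefficients (1/cm).
#' @param supersample integer >= 1: in-plane subvoxel sampling factor for
#'   anti-aliased voxelization of activity and mu (labels always use voxel
#'   centers, so label-based contrasts stay exact at `supersample = 1`).
#'
#' @return list with `activity`, `mu` (both [pet_volume()]) and `labels`
#'   (integer array of tissue classes).
#' @export
#' @examples
#' g <- scanner_geometry(n_views = 8, n_radial = 32, radial_bin_cm = 0.8,
#'                       n_slices = 4, slice_thickness_cm = 1, fov_radius_cm = 12.8)
#' ph <- build_phantom("uniform_cylinder", g, activity_kbq_ml = 10)
#' range(ph$mu)
build_phantom <- function(shape = c("uniform_cylinder", "iec_like", "brain"),
                          geometry,
                          activity_kbq_ml = 10,
                          diameter_cm = 15,
                          semiaxes_cm = c(11, 7.5),
                          gm_wm_csf = c(4, 1, 0),
                          axial_fraction = 1,
                          mu_water = 0.096,
                          mu_bone = 0.151,
                          supersample = 1L) {
  shape <- match.arg(shape)
  stopifnot(inherits(geometry, "scanner_geometry"))
  if (activity_kbq_ml < 0) stop("activity must be nonnegative")
  if (axial_fraction <= 0 || axial_fraction > 1) stop("axial_fraction must be in (0, 1]")
  supersample <- as.integer(supersample)
  stopifnot(supersample >= 1L)

  grid <- default_grid(geometry)
  z_half <- axial_fraction * grid$nz * grid$voxel_cm[3] / 2

  paint <- function(x, y, z) {
    nx <- length(x); ny <- length(y); nz <- length(z)
    X <- array(rep(x, times = ny * nz), dim = c(nx, ny, nz))
    Y <- array(rep(rep(y, each = nx), times = nz), dim = dim(X))
    Z <- array(rep(z, each = nx * ny), dim = dim(X))
    in_axial <- abs(Z) <= z_half + 1e-12
    act <- array(0, dim = dim(X))
    mu <- array(0, dim = dim(X))
    lab <- array(0L, dim = dim(X))
    if (shape == "uniform_cylinder") {
      r <- diameter_cm / 2
      if (r > geometry$fov_radius_cm) stop("phantom larger than the FOV")
      inside <- (X^2 + Y^2 <= r^2) & in_axial
      act[inside] <- activity_kbq_ml
      mu[inside] <- mu_water
      lab[inside] <- 1L
    } else if (shape == "iec_like") {
      a <- semiaxes_cm[1]; b <- semiaxes_cm[2]
      if (max(a, b) > geometry$fov_radius_cm) stop("phantom larger than the FOV")
      inside <- ((X / a)^2 + (Y / b)^2 <= 1) & in_axial
      act[inside] <- activity_kbq_ml
      mu[inside] <- mu_water
      lab[inside] <- 1L
    } else { # brain: nested ellipsoids (skull > CSF > GM shell > WM core)
      ax_z <- max(z_half, grid$voxel_cm[3])
      skull <- c(8.6, 10.6, ax_z)
      csf   <- c(8.0, 10.0, ax_z * 0.96)
      gm    <- c(7.4, 9.4, ax_z * 0.92)
      wm    <- c(5.2, 7.0, ax_z * 0.70)
      if (max(skull[1:2]) > geometry$fov_radius_cm) stop("phantom larger than the FOV")
      inel <- function(s) (X / s[1])^2 + (Y / s[2])^2 + (Z / s[3])^2 <= 1
      lab[inel(skull)] <- 4L
      lab[inel(csf)] <- 3L
      lab[inel(gm)] <- 1L
      lab[inel(wm)] <- 2L
      ratios <- gm_wm_csf / gm_wm_csf[1]
      act[lab == 1L] <- activity_kbq_ml * ratios[1]
      act[lab == 2L] <- activity_kbq_ml * ratios[2]
      act[lab == 3L] <- activity_kbq_ml * ratios[3]
      mu[lab %in% c(1L, 2L, 3L)] <- mu_water
      mu[lab == 4L] <- mu_bone
    }
    list(act = act, mu = mu, lab = lab)
  }

  x <- .grid_axis(grid$nx, grid$voxel_cm[1])
  y <- .grid_axis(grid$ny, grid$voxel_cm[2])
  z <- .grid_axis(grid$nz, grid$voxel_cm[3])
  native <- paint(x, y, z)

  if (supersample > 1L) {
    s <- supersample
    xf <- .grid_axis(grid$nx * s, grid$voxel_cm[1] / s)
    yf <- .grid_axis(grid$ny * s, grid$voxel_cm[2] / s)
    fine <- paint(xf, yf, z)
    block_mean <- function(a) {
      # average s x s in-plane blocks
      dim(a) <- c(s, grid$nx, s, grid$ny, grid$nz)
      colMeans(aperm(a, c(1, 3, 2, 4, 5)), dims = 2)
    }
    native$act <- block_mean(fine$act)
    native$mu <- block_mean(fine$mu)
  }

  list(
    activity = pet_volume(native$act, grid$voxel_cm, "activity"),
    mu = pet_volume(native$mu, grid$voxel_cm, "mu"),
    labels = native$lab
  )
}
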