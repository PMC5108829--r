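#' Object volume from a segmented transmission image
#'
#' The scatter kernel parameters are indexed by object size; the index is
#' the volume of all voxels whose attenuation coefficient strictly exceeds
#' the segmentation threshold (0.06/cm by default, i.e. roughly "denser
#' than lung/air").
#'
#' @param mu attenuation [pet_volume()].
#' @param threshold segmentation threshold in 1/cm; strict `>`.
#' @return volume in cm^3, with attribute `empty = TRUE` (and a warning)
#'   when no voxel passes the threshold.
#' @export
object_volume <- function(mu, threshold = 0.06) {
  stopifnot(inherits(mu, "pet_volume"))
  n <- sum(mu > threshold)
  if (n == 0L) {
    warning("empty segmentation: no voxel with mu > threshold")
    return(structure(0, empty = TRUE))
  }
  structure(n * voxel_volume_ml(mu), empty = FALSE)
}

#' Calibration table of kernel parameters by object size
#'
#' Rows of (object volume, alpha, beta) obtained by tail-matching fits on
#' phantoms of different sizes; looked up by linear interpolation.
#'
#' @param volume_cm3 numeric vector of object volumes, distinct.
#' @param alpha,beta numeric vectors of kernel parameters per row.
#' @return a `calibration_table` (data.frame sorted by volume).
#' @export
calibration_table <- function(volume_cm3, alpha, beta) {
  stopifnot(
    length(volume_cm3) >= 1L,
    length(alpha) == length(volume_cm3),
    length(beta) == length(volume_cm3),
    all(is.finite(volume_cm3)), all(volume_cm3 > 0),
    all(alpha > 0), all(beta >= 0)
  )
  if (anyDuplicated(volume_cm3)) stop("duplicate object volumes in calibration table")
  o <- order(volume_cm3)
  structure(
    data.frame(
      volume_cm3 = volume_cm3[o], alpha = alpha[o], beta = beta[o]
    ),
    class = c("calibration_table", "data.frame")
  )
}

#' @export
print.calibration_table <- function(x, ...) {
  cat("<calibration_table>\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Look up kernel parameters for an object volume
#'
#' `alpha` and `beta` are interpolated linearly and independently between
#' the bracketing table rows; outside the tabulated range the nearest end
#' row is used (clamping).
#'
#' @param table a [calibration_table()].
#' @param v object volume (cm^3).
#' @return a [kernel_params()].
#' @export
params_for_volume <- function(table, v) {
  stopifnot(inherits(table, "calibration_table"), is.finite(v))
  if (nrow(table) == 0L) stop("empty calibration table")
  if (nrow(table) == 1L) {
    return(kernel_params(table$alpha[1], table$beta[1]))
  }
  a <- stats::approx(table$volume_cm3, table$alpha, xout = v, rule = 2)$y
  b <- stats::approx(table$volume_cm3, table$beta, xout = v, rule = 2)$y
  kernel_params(a, b)
}

#' Estimate scatter by per-view kernel convolution
#'
#' The deconvolution method's scatter estimate: each view angle's radial x
#' axial plane is convolved with the scatter kernel independently (no
#' cross-view coupling).
#'
#' @param sino measured (prompts) [sinogram()], nonnegative.
#' @param params a [kernel_params()].
#' @param mode convolution mode, see [scatter_convolve()].
#' @return a `SCATTER` [sinogram()] (may contain small negative ringing;
#'   it is kept as-is so count identities hold).
#' @export
dec_estimate_scatter <- function(sino, params, mode = c("zeropad", "circular")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sino, "sinogram"), inherits(params, "kernel_params"))
  geom <- .sino_geometry(sino)
  spacing <- .sino_spacing(geom)
  d <- dim(sino)
  out <- array(0, d)
  arr <- unclass(sino)
  for (v in seq_len(d[1])) {
    out[v, , ] <- scatter_convolve(arr[v, , ], params, spacing, mode = mode)
  }
  sinogram(out, geom, window = "SCATTER", corrected = TRUE)
}

#' Deconvolution (convolution-subtraction) scatter correction
#'
#' Estimates scatter by convolving the measured sinogram with the
#' object-size-appropriate kernel and subtracts it. When a
#' [calibration_table()] is given, the kernel parameters are looked up from
#' the mu-map's [object_volume()]; alternatively pass [kernel_params()]
#' directly.
#'
#' @param sino measured [sinogram()].
#' @param params_or_table [kernel_params()] or [calibration_table()].
#' @param mu attenuation [pet_volume()]; required with a table.
#' @param clamp set negative corrected bins to zero (default). The returned
#'   `scatter` and the conservation identity
#'   `sum(corrected_preclamp) = sum(sino) - sum(scatter)` always refer to
#'   pre-clamp values.
#' @param mode convolution mode, see [scatter_convolve()].
#' @return list with `corrected` and `scatter` [sinogram()]s, plus
#'   `params` (the kernel actually used) and `object_volume_cm3` (when
#'   looked up).
#' @export
dec_correct <- function(sino, params_or_table, mu = NULL, clamp = TRUE,
                        mode = c("zeropad", "circular")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sino, "sinogram"))
  vol <- NA_real_
  if (inherits(params_or_table, "calibration_table")) {
    if (is.null(mu)) stop("a mu-map is required to index the calibration table")
    vol <- as.numeric(object_volume(mu))
    params <- params_for_volume(params_or_table, vol)
  } else if (inherits(params_or_table, "kernel_params")) {
    params <- params_or_table
  } else {
    stop("params_or_table must be kernel_params or a calibration_table")
  }
  est <- dec_estimate_scatter(sino, params, mode = mode)
  corr <- array(as.numeric(sino), dim(sino)) - array(as.numeric(est), dim(est))
  if (clamp) corr <- pmax(corr, 0)
  list(
    corrected = sinogram(array(corr, dim(sino)), .sino_geometry(sino),
      window = "CORRECTED", corrected = TRUE
    ),
    scatter = est,
    params = params,
    object_volume_cm3 = vol
  )
}
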