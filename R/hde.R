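#' Estimate the window trues ratio from a calibration acquisition
#'
#' The scale `R` mapping upper-window trues to standard-window trues, from
#' a scatter-free (or scatter-corrected) calibration scan:
#' `R = sum(SEW trues) / sum(UEW trues)`. With nested windows `R >= 1`.
#'
#' @param sew_trues_cal,uew_trues_cal calibration [sinogram()]s containing
#'   trues only.
#' @return scalar of class `window_ratio`.
#' @export
estimate_window_ratio <- function(sew_trues_cal, uew_trues_cal) {
  stopifnot(inherits(sew_trues_cal, "sinogram"), inherits(uew_trues_cal, "sinogram"))
  .check_same_shape(sew_trues_cal, uew_trues_cal)
  tu <- sum(uew_trues_cal)
  if (tu <= 0) stop("UEW calibration total is zero")
  structure(sum(sew_trues_cal) / tu, class = "window_ratio")
}

#' @export
print.window_ratio <- function(x, ...) {
  cat(sprintf("<window_ratio> R = %.6g\n", unclass(x)))
  invisible(x)
}

#' Hybrid dual-energy-window scatter estimate
#'
#' The reference estimator: the upper energy window contains relatively
#' little scatter, so its trues are recovered by deconvolution correction
#' with a UEW-specific kernel, scaled to standard-window trues by `R`, and
#' subtracted from the measured SEW prompts — leaving the SEW scatter:
#' \deqn{\hat{s}_{SEW} = p_{SEW} - R\,(p_{UEW} - \mathrm{conv}(p_{UEW}))}
#' The raw estimate is optionally smoothed (total-preserving Gaussian,
#' reflective boundaries; scatter is spatially smooth while the UEW
#' subtraction is noisy) and clamped at zero.
#'
#' @param sew,uew measured [sinogram()]s of the two windows.
#' @param uew_params [kernel_params()] calibrated for the upper window.
#' @param R a `window_ratio` (or scalar).
#' @param smooth_fwhm_cm Gaussian FWHM (cm, radial and axial) applied to
#'   the estimate; 0 disables smoothing.
#' @param mode convolution mode for the UEW correction.
#' @param clamp clamp negative estimate bins to zero (default TRUE; turn
#'   off for algebraic exactness checks).
#' @return a `SCATTER` [sinogram()].
#' @export
hde_estimate_scatter <- function(sew, uew, uew_params, R,
                                 smooth_fwhm_cm = 2,
                                 mode = c("zeropad", "circular"),
                                 clamp = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(sew, "sinogram"), inherits(uew, "sinogram"))
  .check_same_shape(sew, uew)
  R <- as.numeric(R)
  stopifnot(is.finite(R), R > 0)
  geom <- .sino_geometry(sew)
  uew_corr <- dec_correct(uew, uew_params, clamp = FALSE, mode = mode)
  est <- array(as.numeric(sew), dim(sew)) -
    R * array(as.numeric(uew_corr$corrected), dim(uew))
  if (smooth_fwhm_cm > 0) {
    spacing <- .sino_spacing(geom)
    for (v in seq_len(dim(est)[1])) {
      est[v, , ] <- .blur_plane(est[v, , ], spacing,
        smooth_fwhm_cm, smooth_fwhm_cm,
        boundary = "reflect"
      )
    }
  }
  if (clamp) est <- pmax(est, 0)
  sinogram(array(est, dim(sew)), geom, window = "SCATTER", corrected = TRUE)
}

#' Hybrid dual-energy-window scatter correction
#'
#' Subtracts the [hde_estimate_scatter()] estimate from the SEW prompts.
#' As in [dec_correct()], the conservation identity and the returned
#' scatter refer to pre-clamp values.
#'
#' @inheritParams hde_estimate_scatter
#' @param clamp clamp negative corrected bins to zero (default).
#' @return list with `corrected` and `scatter` [sinogram()]s.
#' @export
hde_correct <- function(sew, uew, uew_params, R, smooth_fwhm_cm = 2,
                        mode = c("zeropad", "circular"), clamp = TRUE) {
  mode <- match.arg(mode)
  est <- hde_estimate_scatter(sew, uew, uew_params, R,
    smooth_fwhm_cm = smooth_fwhm_cm, mode = mode, clamp = clamp
  )
  corr <- array(as.numeric(sew), dim(sew)) - array(as.numeric(est), dim(est))
  if (clamp) corr <- pmax(corr, 0)
  list(
    corrected = sinogram(array(corr, dim(sew)), .sino_geometry(sew),
      window = "CORRECTED", corrected = TRUE
    ),
    scatter = est
  )
}
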