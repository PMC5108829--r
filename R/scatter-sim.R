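#' Scatter simulation configuration
#'
#' Controls the ground-truth scatter generator. Two modes:
#' \describe{
#'   \item{`broad_gaussian`}{scatter is a broad 2D Gaussian blur of the
#'     (optionally attenuation-weighted) trues in each view's radial x axial
#'     plane, renormalized so that
#'     `sum(scatter) / (sum(scatter) + sum(trues))` equals the configured
#'     scatter fraction. This deliberately does *not* follow the correction
#'     kernel's functional form, so it exercises model mismatch.}
#'   \item{`dec_self_consistent`}{prompts satisfy the convolution model
#'     exactly: `p = t + k (*) p`, solved per view in frequency space as
#'     `P(f) = T(f) / (1 - S(f))`. Deconvolution with the generating
#'     `(alpha, beta)` then recovers the trues exactly — the algebraic
#'     ground truth for exactness tests. Requires `params` (and
#'     `uew_params` for the upper window).}
#' }
#'
#' @param scatter_fraction_sew scatter fraction in the standard energy
#'   window, in \[0, 1).
#' @param scatter_fraction_uew scatter fraction in the upper energy window;
#'   must not exceed the SEW fraction (the narrower window accepts fewer
#'   scattered photons).
#' @param blur_fwhm_radial_cm,blur_fwhm_axial_cm Gaussian widths of the
#'   broad scatter distribution (cm FWHM).
#' @param attenuation_weighting if `TRUE` and a mu-map is available, the
#'   trues are weighted by `1 - exp(-integral of mu)` (the scatter
#'   probability along the LOR) before blurring.
#' @param oof_background_amplitude amplitude (counts/bin at the first
#'   slice) of an additive axial ramp emulating out-of-FOV activity;
#'   default 0.
#' @param mode `"broad_gaussian"` or `"dec_self_consistent"`.
#' @param params,uew_params [kernel_params()] used by the
#'   `dec_self_consistent` mode for the SEW and UEW scatter.
#' @return a `scatter_config` object.
#' @export
scatter_config <- function(scatter_fraction_sew = 0.35,
                           scatter_fraction_uew = 0.10,
                           blur_fwhm_radial_cm = 8,
                           blur_fwhm_axial_cm = 6,
                           attenuation_weighting = TRUE,
                           oof_background_amplitude = 0,
                           mode = c("broad_gaussian", "dec_self_consistent"),
                           params = NULL,
                           uew_params = NULL) {
  mode <- match.arg(mode)
  stopifnot(
    scatter_fraction_sew >= 0, scatter_fraction_sew < 1,
    scatter_fraction_uew >= 0, scatter_fraction_uew < 1,
    blur_fwhm_radial_cm > 0, blur_fwhm_axial_cm > 0,
    oof_background_amplitude >= 0
  )
  if (scatter_fraction_uew > scatter_fraction_sew) {
    stop("UEW scatter fraction must not exceed the SEW scatter fraction")
  }
  if (!is.null(params)) stopifnot(inherits(params, "kernel_params"))
  if (!is.null(uew_params)) stopifnot(inherits(uew_params, "kernel_params"))
  structure(
    list(
      scatter_fraction_sew = scatter_fraction_sew,
      scatter_fraction_uew = scatter_fraction_uew,
      blur_fwhm_radial_cm = blur_fwhm_radial_cm,
      blur_fwhm_axial_cm = blur_fwhm_axial_cm,
      attenuation_weighting = attenuation_weighting,
      oof_background_amplitude = oof_background_amplitude,
      mode = mode, params = params, uew_params = uew_params
    ),
    class = "scatter_config"
  )
}

#' Energy-window configuration
#'
#' True-coincidence detection efficiencies of the standard (400-624 keV)
#' and upper (512-624 keV) energy windows, relative to the emitted trues.
#' The narrower upper window necessarily collects fewer trues.
#'
#' @param sew_true_efficiency,uew_true_efficiency fractions in (0, 1\].
#' @return a `window_config` object.
#' @export
window_config <- function(sew_true_efficiency = 0.9,
                          uew_true_efficiency = 0.3) {
  stopifnot(
    sew_true_efficiency > 0, sew_true_efficiency <= 1,
    uew_true_efficiency > 0, uew_true_efficiency <= 1
  )
  if (uew_true_efficiency > sew_true_efficiency) {
    stop("UEW efficiency cannot exceed SEW efficiency")
  }
  structure(
    list(
      sew_true_efficiency = sew_true_efficiency,
      uew_true_efficiency = uew_true_efficiency
    ),
    class = "window_config"
  )
}

# 1D Gaussian blur matrix (n x n), kernel FWHM in cm on spacing d.
# boundary "zero": mass leaks past the edges (linear convolution, cropped);
# boundary "reflect": columns sum to 1, totals preserved.
.blur_matrix <- function(n, d, fwhm_cm, boundary = c("zero", "reflect")) {
  boundary <- match.arg(boundary)
  if (fwhm_cm <= 0) return(diag(n))
  sigma <- fwhm_cm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma / d))
  k <- stats::dnorm(seq(-half, half) * d, sd = sigma)
  k <- k / sum(k)
  B <- matrix(0, n, n)
  for (m in seq_along(k)) {
    off <- m - half - 1L
    src <- seq_len(n) + off
    if (boundary == "reflect") {
      src <- ifelse(src < 1L, 2L - src, src)
      src <- ifelse(src > n, 2L * n + 1L - src, src)
      valid <- rep(TRUE, n)
    } else {
      valid <- src >= 1L & src <= n
    }
    rows <- which(valid)
    B[cbind(rows, src[valid])] <- B[cbind(rows, src[valid])] + k[m]
  }
  if (boundary == "reflect") {
    # column-normalize: every source sample distributes exactly its mass,
    # so totals are preserved to machine precision
    B <- sweep(B, 2, colSums(B), "/")
  }
  B
}

# blur each (radial x slice) plane; out[i,j] = sum_k Br[i,k] P[k,l] Bz[j,l]
.blur_plane <- function(plane, spacing_cm, fwhm_r, fwhm_z, boundary = "zero") {
  Br <- .blur_matrix(nrow(plane), spacing_cm[1], fwhm_r, boundary)
  Bz <- .blur_matrix(ncol(plane), spacing_cm[2], fwhm_z, boundary)
  Br %*% plane %*% t(Bz)
}

.sino_spacing <- function(geometry) {
  c(geometry$radial_bin_cm, geometry$slice_thickness_cm)
}

# prompts of the self-consistent convolution model, per view, circular FFT
.self_consistent_prompts <- function(trues_arr, params, spacing_cm) {
  d <- dim(trues_arr)
  S <- kernel_response(params, frequency_grid(d[2:3], spacing_cm))
  if (any(S >= 1)) stop("kernel response reaches 1; prompts would diverge")
  out <- array(0, d)
  for (v in seq_len(d[1])) {
    t_plane <- trues_arr[v, , ]
    out[v, , ] <- Re(stats::fft(stats::fft(t_plane) / (1 - S), inverse = TRUE)) / prod(d[2:3])
  }
  out
}

#' Apply intrinsic detector resolution blur to a sinogram
#'
#' Radial Gaussian smoothing of each view plane (reflective,
#' total-preserving), emulating the scanner's intrinsic in-plane
#' resolution. Besides realism, giving simulated trues a finite edge width
#' keeps the self-consistent scatter generator free of Gibbs ringing at
#' the object boundary.
#'
#' @param sino a [sinogram()].
#' @param fwhm_cm radial FWHM in cm (0 = identity).
#' @return a blurred [sinogram()] with the same metadata.
#' @export
detector_blur <- function(sino, fwhm_cm = 0.7) {
  stopifnot(inherits(sino, "sinogram"), fwhm_cm >= 0)
  if (fwhm_cm == 0) return(sino)
  geom <- .sino_geometry(sino)
  arr <- array(as.numeric(sino), dim(sino))
  B <- .blur_matrix(dim(arr)[2], geom$radial_bin_cm, fwhm_cm, boundary = "reflect")
  for (v in seq_len(dim(arr)[1])) {
    arr[v, , ] <- B %*% arr[v, , ]
  }
  .sino_like(arr, sino)
}

#' Simulate ground-truth scatter for a trues sinogram
#'
#' See [scatter_config()] for the two generator modes. In `broad_gaussian`
#' mode the returned scatter totals are normalized to the configured SEW
#' scatter fraction before the optional out-of-FOV ramp is added; in
#' `dec_self_consistent` mode the scatter is `p - t` of the convolution
#' model and the configured fraction is implied by `(alpha, beta)`.
#'
#' @param trues a `TRUES` [sinogram()], nonnegative.
#' @param mu optional attenuation [pet_volume()] for attenuation weighting.
#' @param cfg a [scatter_config()].
#' @return a `SCATTER` [sinogram()].
#' @export
simulate_scatter <- function(trues, mu = NULL, cfg = scatter_config()) {
  stopifnot(inherits(trues, "sinogram"), inherits(cfg, "scatter_config"))
  geom <- .sino_geometry(trues)
  arr <- unclass(trues)
  attributes(arr) <- list(dim = dim(arr))
  spacing <- .sino_spacing(geom)

  self_consistent <- cfg$mode == "dec_self_consistent"
  if (self_consistent) {
    if (is.null(cfg$params)) stop("dec_self_consistent mode needs cfg$params")
    # p - t of the convolution model; the sharp support edge induces small
    # negative side lobes, which are retained (flagged) so the algebraic
    # identity conv(p) = p - t, and hence DEC exactness, holds bin-wise
    sc <- .self_consistent_prompts(arr, cfg$params, spacing) - arr
  } else {
    sf <- cfg$scatter_fraction_sew
    if (sf == 0) {
      sc <- array(0, dim(arr))
    } else {
      base <- arr
      if (isTRUE(cfg$attenuation_weighting) && !is.null(mu)) {
        w <- 1 - exp(-unclass(mu_line_integrals(mu, geom)))
        attributes(w) <- list(dim = dim(arr))
        base <- base * w
      }
      sc <- array(0, dim(arr))
      for (v in seq_len(dim(arr)[1])) {
        sc[v, , ] <- .blur_plane(
          base[v, , ], spacing,
          cfg$blur_fwhm_radial_cm, cfg$blur_fwhm_axial_cm
        )
      }
      tot <- sum(sc)
      if (tot <= 0) stop("cannot normalize scatter: blurred trues are empty")
      sc <- sc * (sf / (1 - sf) * sum(arr) / tot)
    }
  }

  if (cfg$oof_background_amplitude > 0) {
    nz <- dim(arr)[3]
    ramp <- cfg$oof_background_amplitude * (nz - seq_len(nz)) / max(nz - 1, 1)
    sc <- sc + rep(ramp, each = dim(arr)[1] * dim(arr)[2])
  }
  sinogram(sc, geom, window = "SCATTER", corrected = self_consistent && any(sc < 0))
}

#' Compose dual-energy-window prompts from trues and scatter
#'
#' Noiseless prompts are `efficiency * trues + scatter` per window. The UEW
#' scatter is either the self-consistent scatter of the UEW trues (when the
#' config carries `uew_params` in `dec_self_consistent` mode) or a scaled
#' copy of the SEW scatter hitting the configured UEW scatter fraction.
#' With `seed`, both windows are Poisson-sampled reproducibly (the caller's
#' RNG state is left untouched).
#'
#' @param trues `TRUES` [sinogram()].
#' @param scatter `SCATTER` [sinogram()] for the SEW (from
#'   [simulate_scatter()]).
#' @param win a [window_config()].
#' @param cfg the [scatter_config()] used to generate `scatter`.
#' @param seed integer for Poisson sampling, or `NULL` for noiseless data.
#' @return list with `sew` and `uew` prompt [sinogram()]s plus the
#'   noiseless per-window ground-truth scatter (`scatter_sew`,
#'   `scatter_uew`).
#' @export
compose_prompts <- function(trues, scatter, win = window_config(),
                            cfg = scatter_config(), seed = NULL) {
  stopifnot(
    inherits(trues, "sinogram"), inherits(scatter, "sinogram"),
    inherits(win, "window_config"), inherits(cfg, "scatter_config")
  )
  .check_same_shape(trues, scatter)
  geom <- .sino_geometry(trues)
  t_arr <- array(as.numeric(trues), dim(trues))
  s_arr <- array(as.numeric(scatter), dim(scatter))

  # in the self-consistent mode scatter is linear in the trues, so the SEW
  # scatter scales with the window efficiency (keeps sew = e*t/(1-S) on the
  # convolution model exactly)
  s_sew <- if (cfg$mode == "dec_self_consistent") win$sew_true_efficiency * s_arr else s_arr
  sew <- win$sew_true_efficiency * t_arr + s_sew

  if (cfg$mode == "dec_self_consistent" && !is.null(cfg$uew_params)) {
    uew_trues <- win$uew_true_efficiency * t_arr
    uew_sc <- .self_consistent_prompts(uew_trues, cfg$uew_params, .sino_spacing(geom)) - uew_trues
  } else {
    sf_u <- cfg$scatter_fraction_uew
    target <- if (sf_u > 0) sf_u / (1 - sf_u) * win$uew_true_efficiency * sum(t_arr) else 0
    uew_sc <- if (sum(s_arr) > 0 && target > 0) s_arr * (target / sum(s_arr)) else array(0, dim(t_arr))
  }
  uew <- win$uew_true_efficiency * t_arr + uew_sc

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
    sew <- array(as.numeric(stats::rpois(length(sew), lambda = pmax(sew, 0))), dim(sew))
    uew <- array(as.numeric(stats::rpois(length(uew), lambda = pmax(uew, 0))), dim(uew))
  }
  list(
    sew = sinogram(sew, geom, window = "SEW", corrected = any(sew < 0)),
    uew = sinogram(uew, geom, window = "UEW", corrected = any(uew < 0)),
    scatter_sew = sinogram(s_sew, geom, window = "SCATTER", corrected = any(s_sew < 0)),
    scatter_uew = sinogram(uew_sc, geom, window = "SCATTER", corrected = any(uew_sc < 0))
  )
}
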