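#' Scatter kernel parameters
#'
#' The deconvolution scatter correction models scatter as the output of a
#' low-pass filter applied to each view's radial x axial projection plane.
#' The filter's frequency response is
#' \deqn{S(f) = \frac{1}{1 + \alpha\,e^{\beta |f|^2}}}
#' with `|f|` the Euclidean spatial frequency in cycles/cm. `alpha` sets the
#' amplitude (the DC scatter gain is `1/(1+alpha)`) and `beta` (cm^2) sets
#' how fast the response rolls off — i.e. how broad the scatter tails are.
#'
#' @param alpha amplitude parameter, > 0 (dimensionless).
#' @param beta shape parameter, >= 0, in cm^2 (it multiplies `|f|^2` with
#'   `f` in cycles/cm, so the kernel transfers across bin sizes).
#' @return a `kernel_params` object.
#' @export
#' @examples
#' kp <- kernel_params(alpha = 1, beta = 0)
#' dc_gain(kp) # 0.5
kernel_params <- function(alpha, beta) {
  stopifnot(is.finite(alpha), is.finite(beta), alpha > 0, beta >= 0)
  structure(list(alpha = alpha, beta = beta), class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf(
    "<kernel_params> alpha = %.6g, beta = %.6g cm^2 (DC scatter gain %.4f)\n",
    x$alpha, x$beta, dc_gain(x)
  ))
  invisible(x)
}

#' DC gain of the scatter kernel
#'
#' The zero-frequency response `1/(1 + alpha)`: the fraction of total plane
#' counts the kernel assigns to scatter under circular convolution.
#'
#' @param params a [kernel_params()].
#' @return scalar in (0, 1).
#' @export
dc_gain <- function(params) {
  stopifnot(inherits(params, "kernel_params"))
  1 / (1 + params$alpha)
}

#' Frequency grid of a (padded) projection plane
#'
#' Standard FFT layout: frequency 0 at index (1,1), positive frequencies
#' first, then negative; Nyquist at `1/(2 * spacing)`. Frequencies are
#' physical (cycles/cm) computed from the radial bin width and slice
#' thickness, so anisotropic sampling is respected.
#'
#' @param dims integer length-2: plane size (radial bins, slices).
#' @param spacing_cm numeric length-2: (radial bin, slice thickness) in cm.
#' @return list with `fr`, `fz` (cycles/cm) and `f2` (matrix of `|f|^2`).
#' @export
frequency_grid <- function(dims, spacing_cm) {
  stopifnot(length(dims) == 2L, length(spacing_cm) == 2L, all(spacing_cm > 0))
  fft_freq <- function(n, d) {
    k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
    k / (n * d)
  }
  fr <- fft_freq(dims[1], spacing_cm[1])
  fz <- fft_freq(dims[2], spacing_cm[2])
  list(fr = fr, fz = fz, f2 = outer(fr^2, fz^2, `+`))
}

#' Kernel frequency response on a grid
#'
#' @param params a [kernel_params()].
#' @param grid a [frequency_grid()].
#' @return real matrix with values in `(0, 1/(1+alpha)]`.
#' @export
kernel_response <- function(params, grid) {
  stopifnot(inherits(params, "kernel_params"))
  # 1/(1 + exp(log(alpha) + beta*f^2)), computed stably via plogis
  stats::plogis(-(log(params$alpha) + params$beta * grid$f2))
}

# next 5-smooth size >= n (keeps FFTs fast)
.good_fft_size <- function(n) stats::nextn(n, c(2L, 3L, 5L))

#' Convolve a projection plane with the scatter kernel
#'
#' Multiplies the plane's 2D FFT by the kernel response and transforms
#' back. In `zeropad` mode each axis is padded to at least twice its size
#' before transforming and the result is cropped, approximating linear
#' convolution so scatter tails do not wrap around the FOV edge. `circular`
#' mode uses the plane as-is (cyclic convolution), for which exact count
#' identities hold: `sum(output) = dc_gain * sum(input)`.
#'
#' @param plane numeric matrix (radial bins x slices), finite.
#' @param params a [kernel_params()].
#' @param spacing_cm numeric length-2: (radial bin, slice thickness) cm.
#' @param mode `"zeropad"` (default) or `"circular"`.
#' @return real matrix of the same size as `plane`.
#' @export
scatter_convolve <- function(plane, params, spacing_cm,
                             mode = c("zeropad", "circular")) {
  mode <- match.arg(mode)
  plane <- as.matrix(plane)
  if (!all(is.finite(plane))) stop("plane must be finite")
  d <- dim(plane)
  if (mode == "zeropad") {
    dp <- c(.good_fft_size(2L * d[1]), .good_fft_size(2L * d[2]))
    padded <- matrix(0, dp[1], dp[2])
    padded[seq_len(d[1]), seq_len(d[2])] <- plane
  } else {
    dp <- d
    padded <- plane
  }
  S <- kernel_response(params, frequency_grid(dp, spacing_cm))
  out <- Re(stats::fft(stats::fft(padded) * S, inverse = TRUE)) / prod(dp)
  out[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
}

#' Spatial-domain scatter kernel
#'
#' The inverse transform of the frequency response on a given (unpadded)
#' grid — mainly useful for inspection and for checking that the kernel is
#' real, even, and sums to the DC gain.
#'
#' @inheritParams scatter_convolve
#' @param dims plane size (radial bins, slices).
#' @return real matrix, kernel centered at index (1,1) in FFT layout.
#' @export
spatial_kernel <- function(params, dims, spacing_cm) {
  S <- kernel_response(params, frequency_grid(dims, spacing_cm))
  k <- stats::fft(S, inverse = TRUE) / prod(dims)
  if (max(abs(Im(k))) > 1e-10 * max(abs(Re(k)), 1)) {
    warning("spatial kernel has a non-negligible imaginary part")
  }
  Re(k)
}
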