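#' Sinogram container
#'
#' Counts on a (view, radial, slice) grid together with the scanner geometry
#' and an energy-window label. `corrected` marks data that have been
#' scatter-corrected; only corrected sinograms may hold negative bins
#' (pre-clamp residuals of the subtraction).
#'
#' @param counts 3D numeric array, dimensions
#'   `(n_views, n_radial, n_slices)`.
#' @param geometry a [scanner_geometry()].
#' @param window one of `"SEW"`, `"UEW"`, `"TRUES"`, `"SCATTER"`,
#'   `"CORRECTED"`, `"ACF"`.
#' @param corrected logical; relaxes the nonnegativity invariant.
#'
#' @return A `sinogram` object.
#' @export
sinogram <- function(counts, geometry,
                     window = c("TRUES", "SEW", "UEW", "SCATTER", "CORRECTED", "ACF"),
                     corrected = FALSE) {
  window <- match.arg(window)
  stopifnot(inherits(geometry, "scanner_geometry"))
  counts <- as.array(counts)
  d <- dim(counts)
  if (length(d) != 3L ||
    !identical(as.integer(d), c(geometry$n_views, geometry$n_radial, geometry$n_slices))) {
    stop("counts dimensions must be (n_views, n_radial, n_slices)")
  }
  if (!all(is.finite(counts))) stop("sinogram counts must be finite")
  if (!corrected && any(counts < 0)) {
    stop("uncorrected sinogram counts must be nonnegative")
  }
  structure(counts,
    geometry = geometry, window = window, corrected = corrected,
    class = c("sinogram", "array")
  )
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<sinogram:%s%s> %d views x %d radial x %d slices, total counts %.6g\n",
    attr(x, "window"), if (isTRUE(attr(x, "corrected"))) " (corrected)" else "",
    d[1], d[2], d[3], sum(x)
  ))
  invisible(x)
}

#' @export
summary.sinogram <- function(object, ...) {
  c(
    total = sum(object), min = min(object), max = max(object),
    negatives = sum(object < 0)
  )
}

# rebuild a sinogram with new counts, keeping/overriding metadata
.sino_like <- function(counts, template, window = attr(template, "window"),
                       corrected = attr(template, "corrected")) {
  sinogram(counts, attr(template, "geometry"),
    window = window,
    corrected = corrected
  )
}

.sino_geometry <- function(s) attr(s, "geometry")

.check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("sinogram shapes do not match")
  invisible(TRUE)
}
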