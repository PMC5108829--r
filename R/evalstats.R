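#' Gray/white-matter masks by probability thresholding
#'
#' Boolean masks from tissue probability volumes at a strict `> threshold`
#' cut (a voxel with probability exactly at the threshold is excluded).
#' Warns if the thresholded masks overlap.
#'
#' @param gm_prob,wm_prob arrays of tissue probabilities in \[0, 1\].
#' @param threshold probability cut, default 0.5.
#' @return list with logical arrays `gm` and `wm`.
#' @export
tissue_masks <- function(gm_prob, wm_prob, threshold = 0.5) {
  stopifnot(identical(dim(gm_prob), dim(wm_prob)))
  if (any(gm_prob < 0 | gm_prob > 1) || any(wm_prob < 0 | wm_prob > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  gm <- gm_prob > threshold
  wm <- wm_prob > threshold
  if (any(gm & wm)) warning("GM and WM masks overlap after thresholding")
  list(gm = gm, wm = wm)
}

#' Slice-wise percent-difference profile
#'
#' For each axial slice, `100 * (mean(a) - mean(b)) / mean(b)` over the
#' masked voxels of that slice. Slices with an empty mask, or where the
#' reference mean is zero, are `NA` (undefined), not an error.
#'
#' @param img_a,img_b arrays on the same grid (e.g. DEC- and HDE-corrected
#'   reconstructions; `img_b` is the reference/denominator).
#' @param mask logical array on the same grid.
#' @return numeric vector, one percent difference per slice.
#' @export
slice_diff_profile <- function(img_a, img_b, mask) {
  stopifnot(identical(dim(img_a), dim(img_b)), identical(dim(img_a), dim(mask)))
  nz <- dim(img_a)[3]
  vapply(seq_len(nz), function(z) {
    m <- mask[, , z]
    if (!any(m)) return(NA_real_)
    mb <- mean(img_b[, , z][m])
    if (mb == 0) return(NA_real_)
    100 * (mean(img_a[, , z][m]) - mb) / mb
  }, numeric(1))
}

#' Region-of-interest specification
#'
#' Analytic ROI on the image grid: an ellipse (16 x 32 mm full axes by
#' default) or a circle (16 mm diameter), placed at a voxel center in
#' three adjacent slices, optionally mirrored into both hemispheres across
#' the mid-sagittal plane.
#'
#' @param name region name.
#' @param shape `"ellipse"` or `"circle"`.
#' @param center_vox integer length-2 (x, y) voxel of the right-hemisphere
#'   (or unilateral) center.
#' @param slices integer vector of 3 adjacent slice indices.
#' @param bilateral mirror across the mid-sagittal plane?
#' @param size_mm full axes (mm): length-2 for the ellipse, length-1
#'   diameter for the circle.
#' @return an `roi_spec` object.
#' @export
roi_spec <- function(name, shape = c("ellipse", "circle"), center_vox,
                     slices, bilateral = TRUE,
                     size_mm = if (match.arg(shape) == "ellipse") c(16, 32) else 16) {
  shape <- match.arg(shape)
  stopifnot(length(center_vox) == 2L, length(slices) == 3L, all(diff(sort(slices)) == 1))
  structure(
    list(
      name = name, shape = shape, center_vox = as.integer(center_vox),
      slices = as.integer(slices), bilateral = isTRUE(bilateral),
      size_mm = size_mm
    ),
    class = "roi_spec"
  )
}

# voxel membership of one ROI placement; voxel centers inside the shape
.roi_voxels <- function(spec, nx, ny, voxel_cm, center) {
  semi_cm <- if (spec$shape == "ellipse") spec$size_mm / 20 else rep(spec$size_mm / 20, 2)
  xs <- (seq_len(nx) - center[1]) * voxel_cm[1]
  ys <- (seq_len(ny) - center[2]) * voxel_cm[2]
  inside <- outer((xs / semi_cm[1])^2, (ys / semi_cm[2])^2, `+`) <= 1
  which(inside, arr.ind = TRUE)
}

# mirror a voxel across the mid-sagittal plane x = (nx + 1) / 2
.mirror_x <- function(ix, nx) nx + 1L - ix

#' ROI statistics: means, bilateral averages, left-to-right ratios
#'
#' Each ROI is averaged per slice and then across its three slices. For
#' bilateral ROIs the left placement is the mirror image of the right one
#' across the mid-sagittal plane; the bilateral mean is the average of the
#' two sides and the left-to-right ratio is `left / right`. Unilateral
#' (midline) ROIs report no ratio.
#'
#' @param vol a [pet_volume()] or 3D array with a `voxel_cm` attribute.
#' @param rois list of [roi_spec()].
#' @return data.frame with columns `roi`, `right`, `left`, `mean`,
#'   `lr_ratio` (`NA` for unilateral ROIs; `right`/`left` equal the single
#'   placement's mean for those).
#' @export
roi_stats <- function(vol, rois) {
  d <- dim(vol)
  voxel <- attr(vol, "voxel_cm")
  stopifnot(!is.null(voxel))
  one_side <- function(spec, center) {
    vox <- .roi_voxels(spec, d[1], d[2], voxel, center)
    if (nrow(vox) == 0L) stop("ROI '", spec$name, "' contains no voxels")
    if (any(spec$slices < 1L | spec$slices > d[3])) {
      stop("ROI '", spec$name, "' extends outside the image")
    }
    mean(vapply(spec$slices, function(z) {
      mean(vol[cbind(vox, z)])
    }, numeric(1)))
  }
  rows <- lapply(rois, function(spec) {
    right <- one_side(spec, spec$center_vox)
    if (spec$bilateral) {
      lcenter <- c(.mirror_x(spec$center_vox[1], d[1]), spec$center_vox[2])
      left <- one_side(spec, lcenter)
      data.frame(
        roi = spec$name, right = right, left = left,
        mean = (left + right) / 2,
        lr_ratio = if (right != 0) left / right else NA_real_
      )
    } else {
      data.frame(
        roi = spec$name, right = right, left = right, mean = right,
        lr_ratio = NA_real_
      )
    }
  })
  do.call(rbind, rows)
}

#' Intraclass correlation ICC(2,1)
#'
#' Absolute-agreement intraclass correlation under the two-way random
#' effects model, single measurement: with between-subject (BMS),
#' between-method (JMS) and error (EMS) mean squares,
#' \deqn{ICC = \frac{BMS - EMS}{BMS + (k-1) EMS + k (JMS - EMS)/n}}
#'
#' @param m numeric matrix, `n` subjects x `k >= 2` methods, no missing
#'   cells.
#' @return ICC value; `NA` when the total variance is zero.
#' @export
icc_2_1 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 2, k >= 2, !anyNA(m))
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  if (ss_tot == 0) return(NA_real_)
  bms <- ss_rows / (n - 1)
  jms <- ss_cols / (k - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  (bms - ems) / (bms + (k - 1) * ems + k * (jms - ems) / n)
}

#' Geometric mean (reduced major axis) regression
#'
#' Symmetric line fit: `slope = sign(cor(x, y)) * sd(y) / sd(x)`,
#' `intercept = mean(y) - slope * mean(x)`. Unlike ordinary least squares
#' it treats both variables as error-prone, which is why it is the usual
#' choice for method-comparison scatter plots.
#'
#' @param x,y numeric vectors, `length >= 2`, `sd(x) > 0`.
#' @return named numeric: `slope`, `intercept`.
#' @export
gmr_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  sx <- stats::sd(x)
  if (sx == 0) stop("sd(x) is zero; slope undefined")
  r <- stats::cor(x, y)
  s <- if (is.na(r) || r == 0) 1 else sign(r)
  slope <- s * stats::sd(y) / sx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Patient-averaged absolute-difference table
#'
#' For matched per-subject, per-ROI value tables of two methods, reports
#' the subject-averaged `100 * |a - b| / b` per ROI plus an unweighted
#' `Total` row over ROIs. Cells with a zero reference are `NA`.
#'
#' @param values_a,values_b numeric matrices, subjects x ROIs, matching
#'   dimnames (`values_b` is the reference method).
#' @return data.frame with columns `roi` and `abs_diff_pct`.
#' @export
abs_diff_table <- function(values_a, values_b) {
  values_a <- as.matrix(values_a)
  values_b <- as.matrix(values_b)
  stopifnot(identical(dim(values_a), dim(values_b)))
  pct <- 100 * abs(values_a - values_b) / values_b
  pct[values_b == 0] <- NA_real_
  per_roi <- colMeans(pct)
  out <- data.frame(
    roi = c(
      if (!is.null(colnames(values_a))) colnames(values_a) else paste0("roi", seq_len(ncol(values_a))),
      "Total"
    ),
    abs_diff_pct = c(per_roi, mean(per_roi, na.rm = TRUE))
  )
  rownames(out) <- NULL
  out
}
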