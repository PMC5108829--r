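test_that("tissue masks threshold strictly at 0.5", {
  gm <- array(c(0.5, 0.51, 0.2, 0), c(2, 2, 1))
  wm <- array(c(0.1, 0.0, 0.9, 0), c(2, 2, 1))
  m <- tissue_masks(gm, wm)
  expect_identical(as.vector(m$gm), c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(as.vector(m$wm), c(FALSE, FALSE, TRUE, FALSE))
  expect_true(all(!tissue_masks(array(0, c(2, 2, 1)), array(0, c(2, 2, 1)))$gm))
  expect_warning(tissue_masks(gm, gm), "overlap")
  expect_error(tissue_masks(gm * 3, wm), "0, 1")
})

test_that("slice difference profiles report percent differences per slice", {
  a <- array(runif(4 * 4 * 3) + 1, c(4, 4, 3))
  mask <- array(TRUE, dim(a))
  expect_equal(slice_diff_profile(a, a, mask), c(0, 0, 0))
  expect_equal(slice_diff_profile(1.05 * a, a, mask), rep(5, 3), tolerance = 1e-12)
  mask[, , 2] <- FALSE
  expect_true(is.na(slice_diff_profile(a, a, mask)[2]))
  b <- a; b[, , 3] <- 0
  expect_true(is.na(slice_diff_profile(a, b, array(TRUE, dim(a)))[3]))
})

test_that("ROI statistics average slices, mirror hemispheres, and form ratios", {
  vol <- array(3, c(40, 40, 9))
  attr(vol, "voxel_cm") <- c(0.4, 0.4, 0.6)
  rois <- list(
    roi_spec("cortex", "ellipse", c(28, 20), 4:6),
    roi_spec("midline", "circle", c(20, 28), 4:6, bilateral = FALSE)
  )
  st <- roi_stats(vol, rois)
  expect_equal(st$mean, c(3, 3))
  expect_equal(st$lr_ratio, c(1, NA))
  # scaling the left hemisphere scales the ratio
  vol2 <- vol
  vol2[1:20, , ] <- vol2[1:20, , ] * 0.8
  st2 <- roi_stats(vol2, rois)
  expect_equal(st2$lr_ratio[1], 0.8)
  expect_equal(st2$mean[1], (3 + 2.4) / 2)
  # out-of-image ROIs fail loudly
  expect_error(
    roi_stats(vol, list(roi_spec("far", "circle", c(20, 20), 8:10))),
    "outside"
  )
})

test_that("ICC(2,1) agrees with a direct two-way ANOVA computation", {
  set.seed(21)
  m <- matrix(rnorm(20), 10, 2)
  icc <- icc_2_1(m)
  # independent oracle from aov() mean squares
  d <- data.frame(
    y = as.vector(m),
    subj = factor(rep(seq_len(10), 2)),
    meth = factor(rep(1:2, each = 10))
  )
  ms <- summary(stats::aov(y ~ subj + meth, data = d))[[1]][["Mean Sq"]]
  bms <- ms[1]; jms <- ms[2]; ems <- ms[3]
  n <- 10; k <- 2
  oracle <- (bms - ems) / (bms + (k - 1) * ems + k * (jms - ems) / n)
  expect_lt(abs(icc - oracle), 1e-10)
  # perfect agreement
  expect_equal(icc_2_1(cbind(1:7, 1:7)), 1)
  # zero variance is undefined, not an error
  expect_true(is.na(icc_2_1(matrix(5, 4, 2))))
})

test_that("ICC is near zero for independent columns and shift invariant", {
  set.seed(22)
  m <- matrix(rnorm(400), 200, 2)
  expect_lt(abs(icc_2_1(m)), 0.15)
  set.seed(23)
  m2 <- matrix(rnorm(40, sd = 2), 20, 2) + rep(rnorm(20, sd = 5), 2)
  expect_lt(abs(icc_2_1(m2 + 100) - icc_2_1(m2)), 1e-12)
  expect_lt(abs(icc_2_1(m2 * 3) - icc_2_1(m2)), 1e-12)
})

test_that("geometric mean regression is symmetric and units-equivariant", {
  x <- c(1, 2, 3, 4, 5)
  y <- 2 * x + 1
  f <- gmr_fit(x, y)
  expect_equal(unname(f), c(2, 1))
  set.seed(24)
  x <- rnorm(50); y <- 1.4 * x + rnorm(50, sd = 0.3)
  s_xy <- gmr_fit(x, y)["slope"]
  s_yx <- gmr_fit(y, x)["slope"]
  expect_equal(unname(s_xy * s_yx), 1, tolerance = 1e-12)
  expect_equal(unname(gmr_fit(x, 10 * y)["slope"]), unname(10 * s_xy))
  expect_error(gmr_fit(rep(1, 5), 1:5), "sd")
})

test_that("absolute-difference tables mirror the patient-averaged report", {
  a <- matrix(c(104, 108, 52, 54), 2, 2, dimnames = list(NULL, c("r1", "r2")))
  b <- matrix(c(100, 100, 50, 50), 2, 2, dimnames = list(NULL, c("r1", "r2")))
  tb <- abs_diff_table(a, b)
  expect_equal(tb$roi, c("r1", "r2", "Total"))
  expect_equal(tb$abs_diff_pct, c(6, 6, 6))
  expect_equal(abs_diff_table(b, b)$abs_diff_pct, c(0, 0, 0))
  expect_equal(abs_diff_table(1.1 * b, b)$abs_diff_pct, rep(10, 3), tolerance = 1e-12)
  bz <- b; bz[, 2] <- 0
  expect_true(is.na(abs_diff_table(a, bz)$abs_diff_pct[2]))
})

test_that("slice profiles and difference tables agree on a single region", {
  # one ROI, one slice: |DEC-HDE|/HDE from the table equals the absolute
  # slice profile restricted to the ROI voxels
  vol_b <- array(2, c(30, 30, 3))
  vol_a <- vol_b * 1.07
  attr(vol_a, "voxel_cm") <- attr(vol_b, "voxel_cm") <- c(0.4, 0.4, 0.6)
  roi <- roi_spec("r", "circle", c(15, 15), 1:3, bilateral = FALSE)
  sa <- roi_stats(vol_a, list(roi))$mean
  sb <- roi_stats(vol_b, list(roi))$mean
  tab <- abs_diff_table(matrix(sa, 1, 1), matrix(sb, 1, 1))
  prof <- slice_diff_profile(vol_a, vol_b, array(TRUE, dim(vol_a)))
  expect_equal(tab$abs_diff_pct[1], abs(prof[1]), tolerance = 1e-9)
})
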