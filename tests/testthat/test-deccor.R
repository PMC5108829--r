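test_that("object volume of a 15 cm cylinder over the scanner's axial extent", {
  g <- scanner_geometry(
    n_views = 4, n_radial = 64, radial_bin_cm = 0.4,
    n_slices = 59, slice_thickness_cm = 0.26, fov_radius_cm = 12.8
  )
  ph <- build_phantom("uniform_cylinder", g, diameter_cm = 15)
  v <- object_volume(ph$mu)
  expected <- pi * 7.5^2 * 59 * 0.26 # ~2711 cm^3
  expect_lt(abs(as.numeric(v) - expected) / expected, 0.03)
})

test_that("segmentation is strict: voxels at the threshold are excluded", {
  mu <- array(0, c(4, 4, 2))
  mu[1, 1, 1] <- 0.06 # exactly at threshold: out
  mu[2, 1, 1] <- 0.061 # in
  muv <- pet_volume(mu, c(1, 1, 1), "mu")
  expect_equal(as.numeric(object_volume(muv)), 1)
  empty <- pet_volume(array(0, c(4, 4, 2)), c(1, 1, 1), "mu")
  expect_warning(v0 <- object_volume(empty), "empty")
  expect_equal(as.numeric(v0), 0)
  expect_true(attr(v0, "empty"))
})

test_that("calibration-table lookup interpolates linearly and clamps", {
  tab <- calibration_table(c(3000, 1000), alpha = c(0.4, 0.2), beta = c(6, 2))
  # sorted ascending regardless of input order
  expect_equal(tab$volume_cm3, c(1000, 3000))
  p <- params_for_volume(tab, 2000)
  expect_equal(p$alpha, 0.3)
  expect_equal(p$beta, 4)
  expect_equal(params_for_volume(tab, 1000)$alpha, 0.2) # row hit
  expect_equal(params_for_volume(tab, 500)$alpha, 0.2) # clamp below
  expect_equal(params_for_volume(tab, 9000)$beta, 6) # clamp above
  expect_error(calibration_table(c(1, 1), c(0.1, 0.2), c(1, 2)), "duplicate")
  one <- calibration_table(2711, 0.3, 5)
  expect_equal(params_for_volume(one, 1e9)$beta, 5)
})

test_that("the scatter estimate is the per-view kernel convolution, bitwise", {
  g <- tiny_geom(n_views = 5)
  ph <- build_phantom("uniform_cylinder", g, diameter_cm = 12)
  pr <- forward_project(ph$activity, g, mu = ph$mu)
  kp <- kernel_params(0.5, 4)
  est <- dec_estimate_scatter(pr, kp, mode = "zeropad")
  spc <- c(g$radial_bin_cm, g$slice_thickness_cm)
  for (v in seq_len(g$n_views)) {
    expect_identical(est[v, , ], scatter_convolve(pr[v, , ], kp, spc, mode = "zeropad"))
  }
  # circular total identity summed over views; zeropad never exceeds it
  est_c <- dec_estimate_scatter(pr, kp, mode = "circular")
  expect_lt(abs(sum(est_c) - dc_gain(kp) * sum(pr)), 1e-9 * sum(pr))
  expect_lte(sum(est), sum(est_c) + 1e-9)
})

test_that("correction subtracts its estimate with exact count accounting", {
  g <- tiny_geom()
  ph <- build_phantom("uniform_cylinder", g, diameter_cm = 12)
  pr <- forward_project(ph$activity, g, mu = ph$mu)
  kp <- kernel_params(0.8, 3)
  res <- dec_correct(pr, kp, clamp = FALSE)
  expect_lt(
    abs(sum(res$corrected) - (sum(pr) - sum(res$scatter))),
    1e-9 * sum(pr)
  )
  # all-zero input stays all-zero
  z <- sinogram(array(0, dim(pr)), g, window = "SEW")
  rz <- dec_correct(z, kp)
  expect_true(all(rz$corrected == 0) && all(rz$scatter == 0))
  # table-based lookup requires a mu map
  tab <- calibration_table(c(1000, 3000), c(0.2, 0.4), c(2, 6))
  expect_error(dec_correct(pr, tab), "mu-map")
  res_tab <- dec_correct(pr, tab, mu = ph$mu)
  expect_s3_class(res_tab$params, "kernel_params")
  expect_gt(res_tab$object_volume_cm3, 0)
  expect_error(dec_correct(pr, "nope"), "kernel_params")
})

test_that("self-consistent simulation is corrected exactly with the true kernel", {
  g <- tiny_geom()
  fx <- self_consistent_cylinder(g, kernel_params(1.857, 3), window_config(0.9, 0.3))
  res <- dec_correct(fx$prompts$sew, kernel_params(1.857, 3),
    clamp = FALSE, mode = "circular"
  )
  expect_lt(
    max(abs(unclass(res$corrected) - 0.9 * unclass(fx$trues))) / max(fx$trues),
    1e-6
  )
  # residual scatter in the tail is negligible with the true parameters
  mask <- tail_mask(fx$phantom$mu, g)
  expect_lt(sum(abs(unclass(res$corrected)[mask])), 1e-3 * 0.01 * sum(fx$prompts$sew))
  # 20% less alpha raises the DC gain and over-subtracts: the tail
  # residual flips negative
  res_over <- dec_correct(fx$prompts$sew, kernel_params(1.857 * 0.8, 3),
    clamp = FALSE, mode = "circular"
  )
  expect_lt(sum(unclass(res_over$corrected)[mask]), 0)
})

test_that("correction respects view independence and alpha monotonicity", {
  g <- tiny_geom(n_views = 6)
  ph <- build_phantom("uniform_cylinder", g, diameter_cm = 12)
  pr <- forward_project(ph$activity, g, mu = ph$mu)
  kp <- kernel_params(0.6, 3)
  res <- dec_correct(pr, kp)
  perm <- c(3, 1, 6, 2, 5, 4)
  pr_perm <- sinogram(unclass(pr)[perm, , ], g, window = "TRUES")
  res_perm <- dec_correct(pr_perm, kp)
  expect_equal(unclass(res_perm$corrected), unclass(res$corrected)[perm, , ],
    ignore_attr = TRUE
  )
  # corrected totals decrease as alpha decreases dc gain... i.e. increase with alpha
  totals <- vapply(c(0.3, 0.6, 1.2, 2.4), function(a) {
    sum(dec_correct(pr, kernel_params(a, 3), clamp = FALSE)$corrected)
  }, numeric(1))
  expect_true(all(diff(totals) > 0))
  # a second pass removes more counts than a single pass
  twice <- dec_correct(res$corrected, kp)
  expect_lt(sum(twice$corrected), sum(res$corrected))
})
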