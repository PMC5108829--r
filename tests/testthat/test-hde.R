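test_that("the window trues ratio is the efficiency ratio by construction", {
  g <- tiny_geom(n_views = 4)
  ph <- build_phantom("uniform_cylinder", g, diameter_cm = 12)
  trues <- forward_project(ph$activity, g, mu = ph$mu)
  win <- window_config(0.9, 0.3)
  cfg0 <- scatter_config(0, 0)
  z <- sinogram(array(0, dim(trues)), g, window = "SCATTER")
  cal <- compose_prompts(trues, z, win, cfg0)
  R <- estimate_window_ratio(cal$sew, cal$uew)
  expect_equal(as.numeric(R), 3)
  expect_equal(as.numeric(estimate_window_ratio(cal$sew, cal$sew)), 1)
  expect_error(estimate_window_ratio(cal$sew, z), "zero")
})

test_that("the ratio estimate is stable under Poisson noise at high counts", {
  g <- tiny_geom(n_views = 4, n_radial = 16, radial_bin_cm = 1.6, n_slices = 4)
  ph <- build_phantom("uniform_cylinder", g, diameter_cm = 15)
  trues <- forward_project(ph$activity, g, mu = ph$mu)
  scale <- 1e7 / sum(trues)
  trues <- sinogram(unclass(trues) * scale, g, window = "TRUES")
  win <- window_config(0.9, 0.3)
  z <- sinogram(array(0, dim(trues)), g, window = "SCATTER")
  cal <- compose_prompts(trues, z, win, scatter_config(0, 0), seed = 5)
  R <- estimate_window_ratio(cal$sew, cal$uew)
  expect_lt(abs(as.numeric(R) - 3) / 3, 0.005)
})

test_that("the hybrid estimate is algebraically exact in the idealized case", {
  g <- tiny_geom()
  win <- window_config(0.9, 0.3)
  fx <- self_consistent_cylinder(g, kernel_params(1.857, 3),
    win = win, uew_params = kernel_params(9, 3)
  )
  R <- structure(0.9 / 0.3, class = "window_ratio")
  est <- hde_estimate_scatter(fx$prompts$sew, fx$prompts$uew,
    kernel_params(9, 3), R,
    smooth_fwhm_cm = 0, mode = "circular", clamp = FALSE
  )
  truth <- unclass(fx$prompts$scatter_sew)
  expect_lt(max(abs(unclass(est) - truth)) / max(abs(truth)), 1e-6)
  corr <- hde_correct(fx$prompts$sew, fx$prompts$uew, kernel_params(9, 3), R,
    smooth_fwhm_cm = 0, mode = "circular", clamp = FALSE
  )
  expect_lt(
    max(abs(unclass(corr$corrected) - 0.9 * unclass(fx$trues))) / max(fx$trues),
    1e-6
  )
})

test_that("zero scatter in both windows gives a zero estimate", {
  g <- tiny_geom(n_views = 4)
  ph <- build_phantom("uniform_cylinder", g, diameter_cm = 12)
  trues <- forward_project(ph$activity, g, mu = ph$mu)
  win <- window_config(0.9, 0.3)
  z <- sinogram(array(0, dim(trues)), g, window = "SCATTER")
  pr <- compose_prompts(trues, z, win, scatter_config(0, 0))
  # the UEW correction must not invent scatter: use a vanishing-gain kernel
  est <- hde_estimate_scatter(pr$sew, pr$uew, kernel_params(1e6, 1), 3,
    smooth_fwhm_cm = 0, clamp = FALSE
  )
  expect_lt(max(abs(unclass(est))), 1e-5 * max(pr$sew))
})

test_that("estimate smoothing preserves totals and FWHM 0 is the identity", {
  g <- tiny_geom()
  fx <- self_consistent_cylinder(g, kernel_params(1.857, 3),
    win = window_config(0.9, 0.3), uew_params = kernel_params(9, 3)
  )
  R <- 3
  raw <- hde_estimate_scatter(fx$prompts$sew, fx$prompts$uew,
    kernel_params(9, 3), R,
    smooth_fwhm_cm = 0, mode = "circular", clamp = FALSE
  )
  sm <- hde_estimate_scatter(fx$prompts$sew, fx$prompts$uew,
    kernel_params(9, 3), R,
    smooth_fwhm_cm = 2, mode = "circular", clamp = FALSE
  )
  expect_lt(abs(sum(sm) - sum(raw)) / abs(sum(raw)), 1e-6)
  expect_false(identical(unclass(sm), unclass(raw)))
  # pre-clamp conservation identity
  corr <- hde_correct(fx$prompts$sew, fx$prompts$uew, kernel_params(9, 3), R,
    smooth_fwhm_cm = 2, mode = "circular", clamp = FALSE
  )
  expect_lt(
    abs(sum(corr$corrected) - (sum(fx$prompts$sew) - sum(corr$scatter))),
    1e-9 * sum(fx$prompts$sew)
  )
})

test_that("UEW noise propagation makes HDE noisier than DEC", {
  g <- tiny_geom(n_views = 4, n_radial = 24, radial_bin_cm = 1.1, n_slices = 4)
  win <- window_config(0.9, 0.3)
  fx <- self_consistent_cylinder(g, kernel_params(1.857, 3),
    win = win, uew_params = kernel_params(9, 3)
  )
  scale <- 5e5 / sum(fx$prompts$sew)
  trues <- sinogram(unclass(fx$trues) * scale, g, window = "TRUES")
  sc <- sinogram(unclass(fx$scatter) * scale, g,
    window = "SCATTER", corrected = TRUE
  )
  var_dec <- var_hde <- numeric(20)
  for (s in 1:20) {
    pr <- compose_prompts(trues, sc, win, fx$cfg, seed = s)
    dec <- dec_correct(pr$sew, kernel_params(1.857, 3), clamp = FALSE, mode = "circular")
    hde <- hde_correct(pr$sew, pr$uew, kernel_params(9, 3), 3,
      smooth_fwhm_cm = 0, mode = "circular", clamp = FALSE
    )
    truth <- 0.9 * scale * unclass(fx$trues)
    var_dec[s] <- mean((unclass(dec$corrected) - truth)^2)
    var_hde[s] <- mean((unclass(hde$corrected) - truth)^2)
  }
  expect_gt(mean(var_hde), mean(var_dec))
})

test_that("under kernel-model mismatch HDE estimates scatter better than DEC", {
  # broad-gaussian scatter violates the DEC kernel form; the hybrid
  # reference sees it through the (nearly scatter-free) upper window
  g <- tiny_geom(n_views = 8, n_radial = 64, radial_bin_cm = 0.4)
  ph <- build_phantom("brain", g)
  trues <- forward_project(ph$activity, g, mu = ph$mu)
  win <- window_config(0.9, 0.3)
  cfg <- scatter_config(
    scatter_fraction_sew = 0.35, scatter_fraction_uew = 0.10,
    mode = "broad_gaussian"
  )
  sc <- simulate_scatter(trues, ph$mu, cfg)
  pr <- compose_prompts(trues, sc, win, cfg)
  mask <- tail_mask(ph$mu, g, margin_bins = 1)
  gd <- c(12L, 12L)
  fit_sew <- fit_kernel_params(pr$sew, mask, grid_density = gd)
  fit_uew <- fit_kernel_params(pr$uew, mask, grid_density = gd)
  dec_est <- dec_estimate_scatter(pr$sew, fit_sew$params)
  hde_est <- hde_estimate_scatter(pr$sew, pr$uew, fit_uew$params, 3,
    smooth_fwhm_cm = 0, clamp = FALSE
  )
  truth <- unclass(pr$scatter_sew)
  err_dec <- sum(abs(unclass(dec_est) - truth))
  err_hde <- sum(abs(unclass(hde_est) - truth))
  expect_lt(err_hde, err_dec)
})
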