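test_that("broad-gaussian scatter totals hit the configured fraction exactly", {
  g <- tiny_geom()
  ph <- build_phantom("uniform_cylinder", g, diameter_cm = 15)
  trues <- forward_project(ph$activity, g, mu = ph$mu)
  for (sf in c(0.2, 0.4, 0.6)) {
    cfg <- scatter_config(scatter_fraction_sew = sf, scatter_fraction_uew = sf / 3)
    sc <- simulate_scatter(trues, ph$mu, cfg)
    expect_lt(abs(sum(sc) / (sum(sc) + sum(trues)) - sf), 1e-6)
    expect_true(all(unclass(sc) >= 0))
  }
  # zero scatter fraction -> all-zero scatter
  sc0 <- simulate_scatter(trues, ph$mu, scatter_config(0, 0))
  expect_true(all(sc0 == 0))
  # a fraction of 1 is not representable
  expect_error(scatter_config(scatter_fraction_sew = 1), "scatter_fraction")
})

test_that("scatter spills into the tail where the trues are zero", {
  g <- tiny_geom()
  ph <- build_phantom("uniform_cylinder", g, diameter_cm = 12)
  trues <- forward_project(ph$activity, g, mu = ph$mu)
  sc <- simulate_scatter(trues, ph$mu, scatter_config(0.4, 0.1))
  outside <- unclass(trues) == 0
  expect_true(any(outside))
  expect_gt(sum(unclass(sc)[outside]), 0)
})

test_that("the out-of-FOV ramp adds counts concentrated in low slices", {
  g <- tiny_geom()
  ph <- build_phantom("uniform_cylinder", g, diameter_cm = 12)
  trues <- forward_project(ph$activity, g, mu = ph$mu)
  cfg <- scatter_config(0.3, 0.1, oof_background_amplitude = 2)
  sc <- simulate_scatter(trues, ph$mu, cfg)
  sc0 <- simulate_scatter(trues, ph$mu, scatter_config(0.3, 0.1))
  added <- apply(unclass(sc) - unclass(sc0), 3, mean)
  expect_equal(added[1], 2)
  expect_equal(added[g$n_slices], 0)
  expect_true(all(diff(added) <= 1e-12))
})

test_that("prompt composition is the identity sum at unit efficiencies", {
  g <- tiny_geom()
  ph <- build_phantom("uniform_cylinder", g, diameter_cm = 12)
  trues <- forward_project(ph$activity, g, mu = ph$mu)
  cfg <- scatter_config(0.3, 0.1)
  sc <- simulate_scatter(trues, ph$mu, cfg)
  pr <- compose_prompts(trues, sc, window_config(1, 1), cfg)
  expect_equal(unclass(pr$sew), unclass(trues) + unclass(sc), ignore_attr = TRUE)
  # count conservation with efficiencies
  win <- window_config(0.9, 0.3)
  pr2 <- compose_prompts(trues, sc, win, cfg)
  expect_equal(sum(pr2$sew), 0.9 * sum(trues) + sum(pr2$scatter_sew))
  expect_equal(sum(pr2$uew), 0.3 * sum(trues) + sum(pr2$scatter_uew))
  # the UEW holds relatively less scatter than the SEW
  sf_sew <- sum(pr2$scatter_sew) / sum(pr2$sew)
  sf_uew <- sum(pr2$scatter_uew) / sum(pr2$uew)
  expect_lt(sf_uew, sf_sew)
})

test_that("window and scatter configs enforce the UEW-smaller ordering", {
  expect_error(window_config(0.3, 0.9), "exceed")
  expect_error(scatter_config(0.1, 0.3), "exceed")
  expect_error(compose_prompts(1, 2), "sinogram")
})

test_that("Poisson sampling is seed-reproducible and leaves the RNG alone", {
  g <- tiny_geom(n_views = 4, n_radial = 16, radial_bin_cm = 1.6, n_slices = 2)
  ph <- build_phantom("uniform_cylinder", g, diameter_cm = 12)
  trues <- forward_project(ph$activity, g, mu = ph$mu)
  cfg <- scatter_config(0.3, 0.1)
  sc <- simulate_scatter(trues, ph$mu, cfg)
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  a <- compose_prompts(trues, sc, window_config(), cfg, seed = 42)
  b <- compose_prompts(trues, sc, window_config(), cfg, seed = 42)
  expect_identical(unclass(a$sew), unclass(b$sew))
  expect_identical(unclass(a$uew), unclass(b$uew))
  # caller's RNG stream is restored
  expect_equal(runif(1), before)
  # different seed, different counts
  d <- compose_prompts(trues, sc, window_config(), cfg, seed = 43)
  expect_false(identical(unclass(a$sew), unclass(d$sew)))
})

test_that("Poisson bin means track the noiseless values within 5 sigma", {
  g <- tiny_geom(n_views = 3, n_radial = 12, radial_bin_cm = 2,
    n_slices = 2, fov_radius_cm = 12
  )
  ph <- build_phantom("uniform_cylinder", g, diameter_cm = 15)
  trues <- forward_project(ph$activity, g, mu = ph$mu)
  cfg <- scatter_config(0.3, 0.1)
  sc <- simulate_scatter(trues, ph$mu, cfg)
  noiseless <- compose_prompts(trues, sc, window_config(), cfg)
  n_rep <- 100
  acc <- array(0, dim(trues))
  for (s in seq_len(n_rep)) {
    acc <- acc + unclass(compose_prompts(trues, sc, window_config(), cfg, seed = s)$sew)
  }
  m <- acc / n_rep
  lam <- unclass(noiseless$sew)
  z <- (m - lam) / sqrt(pmax(lam, 1e-9) / n_rep)
  expect_lt(max(abs(z[lam > 0.5])), 5)
})

test_that("detector blur preserves totals and widens edges", {
  g <- tiny_geom()
  ph <- build_phantom("uniform_cylinder", g, diameter_cm = 12)
  trues <- forward_project(ph$activity, g, mu = ph$mu)
  bl <- detector_blur(trues, 1.6)
  expect_lt(abs(sum(bl) - sum(trues)) / sum(trues), 1e-9)
  expect_gt(sum(unclass(bl) > 1e-6 * max(bl)), sum(unclass(trues) > 1e-6 * max(trues)))
  expect_identical(unclass(detector_blur(trues, 0)), unclass(trues))
})
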